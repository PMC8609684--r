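# Section selection and probe counting on constructed fixtures.

test_that("systematic section selection is an arithmetic progression", {
  stack <- section_stack(350 * 18, 18)
  expect_equal(stack$n_sections, 350L)
  idx <- select_sections(stack, k = 30, random_start = 5)
  expect_equal(idx, seq(5, 335, by = 30))
  expect_length(idx, 12)
  # k = 1 returns every section
  expect_equal(select_sections(stack, k = 1, random_start = 0), 0:349)
})

test_that("330 sections at k = 30 give 11 sections for every start", {
  stack <- section_stack(330 * 18, 18)
  for (s0 in 0:29) {
    expect_length(select_sections(stack, k = 30, random_start = s0), 11)
  }
})

test_that("section selection validates the design and is seed-deterministic", {
  stack <- section_stack(100 * 18, 18)
  expect_error(select_sections(stack, k = 101, seed = 1), "invalid design")
  expect_error(select_sections(stack, k = 30, random_start = 30), "invalid design")
  expect_identical(select_sections(stack, 30, seed = 4),
                   select_sections(stack, 30, seed = 4))
})

test_that("point counts have the analytic expectation over random offsets", {
  # 500 x 400 um slab cross-section, 50 um grid: E[P] = 200000 / 2500 = 80
  r <- tiny_region(w = 500, y = 400, z = 540)
  stack <- section_stack(540, 18)
  des <- tiny_design()
  counts <- vapply(1:1000, function(i) {
    count_points(r, stack, 10, des, seed = i)[["DG"]]
  }, 0L)
  expect_equal(mean(counts), 80, tolerance = 0.02)
  expect_true(all(counts >= 60 & counts <= 100))
})

test_that("doubling the area per point halves the expected count", {
  r <- tiny_region(w = 500, y = 400, z = 540)
  stack <- section_stack(540, 18)
  des2 <- sampling_design(interval_k = 3, point_spacing_um = c(50, 100),
                          sphere_spacing_um = 40)
  counts <- vapply(1:600, function(i) {
    count_points(r, stack, 5, des2, seed = i)[["DG"]]
  }, 0L)
  expect_equal(mean(counts), 40, tolerance = 0.05)
})

test_that("a compartment absent from a section counts zero points", {
  # region only spans z < 540; probing a section beyond it is all zero
  r <- build_region_model(c(DG = 100, CA1 = 100), lateral_extent = c(100, 100))
  stack <- section_stack(540, 18)
  p <- count_points(r, stack, 20, tiny_design(), offset = c(1, 1))
  expect_equal(unname(p), c(0L, 0L))
})

test_that("guard zones exclude nodes near section faces", {
  # one branch node 0.5 um above a section floor (inside the guard), one at
  # mid-depth: only the latter is counted
  stack <- section_stack(540, 18)
  des <- tiny_design()
  zf <- 5 * 18  # section 5 floor
  net <- manual_network(
    list(straight_poly(c(10, 10, zf + 0.5), c(40, 10, zf + 0.5)),
         straight_poly(c(10, 20, zf + 9), c(40, 20, zf + 9))),
    kinds = list(c("branch", "endpoint"), c("branch", "endpoint"))
  )
  q <- count_saddle_points(net, stack, 5, des, offset = c(0, 0))
  expect_equal(unname(q[["DG"]]), 1L)
  # with g = 0 both are inside the disector
  des0 <- sampling_design(interval_k = 3, guard_um = 0, sphere_spacing_um = 40)
  q0 <- count_saddle_points(net, stack, 5, des0, offset = c(0, 0))
  expect_equal(unname(q0[["DG"]]), 2L)
})

test_that("tiling frames count every branch node exactly once", {
  r <- small_region()
  net <- generate_network(r, 1.8e-3, seed = 13)
  stack <- section_stack(r$extent[["z"]], 18)
  des <- sampling_design(interval_k = 1, guard_um = 0,
                         frame_um = c(60, 60), frame_spacing_um = c(60, 60),
                         sphere_spacing_um = 40)
  total <- 0L
  for (s in select_sections(stack, 1, random_start = 0)) {
    total <- total + sum(count_saddle_points(net, stack, s, des, seed = s + 1))
  }
  expect_identical(total, sum(net$truth$n_branch))
})

test_that("sparse frames respect inclusion/exclusion edges", {
  stack <- section_stack(540, 18)
  # frame [0, 60) x [0, 60) on a 120 um lattice, zero offset:
  # node on the inclusion (left) edge counts, node on the exclusion
  # (right) edge does not
  des <- sampling_design(interval_k = 3, frame_um = c(60, 60),
                         frame_spacing_um = c(120, 120),
                         sphere_spacing_um = 40)
  zmid <- 9
  net <- manual_network(
    list(straight_poly(c(0, 10, zmid), c(0, 40, zmid)),      # x = 0: include
         straight_poly(c(60, 10, zmid), c(60, 40, zmid))),   # x = 60: exclude
    kinds = list(c("branch", "endpoint"), c("branch", "endpoint"))
  )
  q <- count_saddle_points(net, stack, 0, des, offset = c(0, 0))
  expect_equal(unname(q[["DG"]]), 1L)
})

test_that("guard-zone monotonicity: larger guards never increase counts", {
  r <- small_region()
  net <- generate_network(r, 2e-3, seed = 21)
  stack <- section_stack(r$extent[["z"]], 18)
  qs <- vapply(c(0, 1, 2, 4), function(g) {
    des <- sampling_design(interval_k = 3, guard_um = g, sphere_spacing_um = 40)
    sum(count_saddle_points(net, stack, 7, des, offset = c(3, 3)))
  }, 0)
  expect_true(all(diff(qs) <= 0))
})

test_that("disector height must be positive", {
  stack <- section_stack(540, 18)
  des <- sampling_design(interval_k = 3, guard_um = 9, sphere_spacing_um = 40)
  net <- manual_network(list(straight_poly(c(1, 1, 1), c(5, 5, 5))))
  expect_error(count_saddle_points(net, stack, 0, des, offset = c(0, 0)),
               "disector height")
})
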