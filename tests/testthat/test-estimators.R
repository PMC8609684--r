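# Estimator formulas against hand-computed and analytic oracles.

test_that("Cavalieri volume follows sum(P) * a(p) * k * t", {
  expect_equal(cavalieri_volume(c(10, 12, 9, 11), 2500, 30, 18), 5.67e7)
  expect_equal(cavalieri_volume(0, 2500, 30, 18), 0)
  expect_error(cavalieri_volume(10, -1, 30, 18), "invalid")
  expect_error(cavalieri_volume(10, 2500, 0, 18), "invalid")
})

test_that("Cavalieri estimate converges to analytic box volume over designs", {
  # 500 x 400 x 540 um box, t = 18, k = 3: mean over 200 random grid
  # offsets and starts within 3% of 1.08e8 um^3
  r <- tiny_region(w = 500, y = 400, z = 540)
  stack <- section_stack(540, 18)
  des <- tiny_design()
  est <- vapply(1:200, function(i) {
    secs <- select_sections(stack, 3, seed = i)
    sp <- vapply(secs, function(s) {
      count_points(r, stack, s, des, seed = i * 1000 + s)[["DG"]]
    }, 0L)
    cavalieri_volume(sp, des$area_per_point_um2, 3, 18)
  }, 0)
  expect_equal(mean(est) / 1.08e8, 1, tolerance = 0.03)
})

test_that("Euler counts scale saddle points by the fractionator fractions", {
  e1 <- euler_counts(5, 1, 1, 1)
  expect_equal(e1$n_cap, 10)
  expect_equal(e1$n_endp, 6)
  e0 <- euler_counts(0, 1, 1, 1)
  expect_equal(e0$n_cap, 0)
  expect_equal(e0$n_endp, 1)
  e <- euler_counts(7, 1 / 30, 1 / 2, 8 / 9)
  expect_equal(e$n_cap, 945)
  expect_error(euler_counts(5, 0, 1, 1), "invalid")
})

test_that("sphere length estimator follows Lv = 2I/S and L = Lv * V", {
  out <- sphere_length(2, 4 * pi * 100, 1e6)
  expect_equal(out$l_um, 3183.1, tolerance = 1e-4)
  expect_equal(sphere_length(0, 1000, 1e6)$l_um, 0)
  expect_error(sphere_length(3, 0, 1e6), "inconsistent")
})

test_that("densities, mean length and diffusion distance derive correctly", {
  # published whole-hippocampus means: L = 75.99 m, N = 1,228,668 -> 62 um
  d <- derive_densities(46.40e9, 1228668, 622140, 75.99e6)
  expect_equal(round(d$mean_length_um), 62)
  # closed form: Lv = 1e-2 um^-2 -> r_diff = (4 pi Lv)^(-1/2) = 2.82 um
  d2 <- derive_densities(1e6, 10, 6, 1e4)
  expect_equal(d2$lv_um2, 1e-2)
  expect_equal(d2$r_diff_um, 2.8209, tolerance = 1e-4)
  # scaling law: doubling Lv divides r_diff by sqrt(2)
  d3 <- derive_densities(1e6, 10, 6, 2e4)
  expect_equal(d2$r_diff_um / d3$r_diff_um, sqrt(2), tolerance = 1e-12)
  # internal consistency to machine precision
  expect_equal(d2$lv_um2 * 1e6, 1e4)
  expect_equal(d2$nv_um3 * 1e6, 10)
  # zero capillaries: mean length flagged missing, not zero
  d4 <- derive_densities(1e6, 0, 1, 0)
  expect_true(is.na(d4$mean_length_um))
})

test_that("Gundersen CE matches the hand-evaluated constant-count case", {
  # p_i = 100 over n = 8, noise 0, smoothness 1:
  # A = 80000, B = 70000, C = 60000 -> var = 20000/240, CE = sqrt(83.33)/800
  ce <- ce_gundersen(rep(100, 8), smoothness = 1, count_type = "object")
  expect_equal(ce, sqrt(250 / 3) / 800, tolerance = 1e-12)
  expect_equal(ce, 0.0114, tolerance = 1e-2)
})

test_that("CE degenerate and error cases", {
  expect_error(ce_gundersen(c(1, 2), smoothness = 1), "insufficient")
  expect_error(ce_gundersen(rep(0, 8)), "degenerate")
  expect_error(ce_gundersen(rep(5, 8), smoothness = 2), "smoothness")
})

test_that("CE point-count mode adds the nugget noise term", {
  counts <- rep(100, 8)
  noise <- 0.0724 * 5 * sqrt(8 * 800)
  a <- sum(counts^2); b <- sum(counts[-8] * counts[-1])
  cc <- sum(counts[1:6] * counts[3:8])
  var1 <- (3 * (a - noise) - 4 * b + cc) / 240
  expect_equal(ce_gundersen(counts, smoothness = 1, count_type = "point"),
               sqrt(noise + var1) / 800, tolerance = 1e-12)
})

test_that("exhaustive disector sampling recovers node counts exactly", {
  r <- small_region()
  net <- generate_network(r, 2e-3, seed = 17)
  stack <- section_stack(r$extent[["z"]], 18)
  des <- sampling_design(interval_k = 1, guard_um = 0, sphere_spacing_um = 40)
  counts <- probe_counts(net, r, stack, des, seed = 3)
  est <- estimate_animal(counts, des, stack, r)
  tot <- est[est$compartment == "total", ]
  expect_equal(tot$n_cap / 2, sum(net$truth$n_branch))
  # per compartment too
  for (cc in net$truth$compartment) {
    expect_equal(est$n_cap[est$compartment == cc] / 2,
                 net$truth$n_branch[net$truth$compartment == cc])
  }
})

test_that("estimate table is internally consistent (Lv*V = L, Nv*V = N)", {
  r <- small_region()
  net <- generate_network(r, 2e-3, seed = 19)
  stack <- section_stack(r$extent[["z"]], 18)
  counts <- probe_counts(net, r, stack, sampling_design(interval_k = 5),
                         seed = 8)
  est <- estimate_animal(counts, sampling_design(interval_k = 5), stack, r)
  ok <- est$v_mm3 > 0
  expect_equal(est$lv_m_per_mm3[ok] * est$v_mm3[ok], est$l_m[ok],
               tolerance = 1e-12)
  expect_equal(est$nv_per_mm3[ok] * est$v_mm3[ok], est$n_cap[ok],
               tolerance = 1e-12)
  # PCL row equals the sum of its members
  pcl <- est[est$compartment == "PCL", ]
  mem <- est[est$compartment %in% c("DG", "CA1", "CA23"), ]
  expect_equal(pcl$v_mm3, sum(mem$v_mm3), tolerance = 1e-12)
  expect_equal(pcl$l_m, sum(mem$l_m), tolerance = 1e-12)
})

test_that("sphere length estimate is unbiased against truth on a small region", {
  r <- build_region_model(c(ML = 200), lateral_extent = c(200, 40 * 18))
  net <- generate_network(r, 2e-3, seed = 23)
  stack <- section_stack(r$extent[["z"]], 18)
  des <- sampling_design(interval_k = 4, sphere_spacing_um = 25)
  lv_true <- net$truth$length_um / region_volumes(r)[["ML"]]
  lv_hat <- vapply(1:150, function(i) {
    counts <- probe_counts(net, r, stack, des, seed = 100 + i)
    2 * sum(counts$sum_i) / sum(counts$s_exposed_um2)
  }, 0)
  expect_equal(mean(lv_hat) / lv_true, 1, tolerance = 0.03)
})
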