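# Nonparametric protocol: exact tests against enumeration oracles,
# percent-change arithmetic, and report construction.

# Independent brute-force oracle for the exact two-sided Mann-Whitney p:
# enumerate all group-A index sets of the pooled sample.
mw_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  ranks <- rank(pooled)
  m <- n_a * length(b)
  u_of <- function(idx) sum(ranks[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  combs <- combn(length(pooled), n_a)
  u_all <- apply(combs, 2, u_of)
  lo <- min(u_obs, m - u_obs)
  mean(pmin(u_all, m - u_all) <= lo + 1e-9)
}

test_that("exact Mann-Whitney matches hand enumeration on separated groups", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 labelings as extreme
})

test_that("identical groups give exact p = 1", {
  res <- mann_whitney(c(5, 7, 7, 9), c(5, 7, 7, 9), mode = "exact")
  expect_equal(res$p_value, 1)
})

test_that("exact Mann-Whitney equals wilcox.test and the brute-force oracle", {
  set.seed(11)
  for (i in 1:60) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(rnorm(n1), 2); b <- round(rnorm(n2, 0.5), 2)
    res <- mann_whitney(a, b, mode = "exact")
    # tie-free: stats::wilcox.test is an independent exact implementation
    if (!anyDuplicated(c(a, b))) {
      wt <- wilcox.test(a, b, exact = TRUE)
      expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
      expect_equal(res$statistic, unname(wt$statistic))
    }
    expect_equal(res$p_value, mw_oracle(a, b), tolerance = 1e-12)
  }
  # with ties the enumeration oracle still applies
  for (i in 1:40) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    a <- sample(1:4, n1, replace = TRUE); b <- sample(1:4, n2, replace = TRUE)
    res <- mann_whitney(a, b, mode = "exact")
    expect_equal(res$p_value, mw_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  # For continuous 6 vs 5 data the p-value depends only on U, so the exact
  # attainable level at alpha = 0.05 is P(p(U) <= 0.05) under the uniform
  # null over all C(11,6) labelings -- computable without simulation.
  combs <- combn(11, 6)
  ranks <- 1:11
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - 21)
  p_of_u <- vapply(u_all, function(u) {
    lo <- min(u, 30 - u)
    mean(pmin(u_all, 30 - u_all) <= lo + 1e-9)
  }, 0)
  exact_level <- mean(p_of_u <= 0.05)
  expect_gte(exact_level, 0.03)
  expect_lte(exact_level, 0.07)

  # Monte-Carlo agreement of the implementation with that exact level
  set.seed(42)
  reps <- 2000
  rej <- vapply(1:reps, function(i) {
    mann_whitney(rnorm(6), rnorm(5), mode = "exact")$p_value <= 0.05
  }, NA)
  se <- sqrt(exact_level * (1 - exact_level) / reps)
  expect_lt(abs(mean(rej) - exact_level), 4 * se)
})

test_that("asymptotic mode agrees with wilcox.test normal approximation", {
  a <- c(1.2, 3.1, 2.2, 5.5, 4.1, 2.9)
  b <- c(2.0, 4.4, 6.1, 5.0, 3.3)
  res <- mann_whitney(a, b, mode = "asymptotic")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
})

test_that("empty groups are rejected", {
  expect_error(mann_whitney(numeric(0), 1:3), "invalid input")
})

test_that("Wilcoxon signed-rank: +1 differences give one-sided p = 1/64", {
  x <- c(2, 3, 4, 5, 6, 7); y <- x - 1
  res <- wilcoxon_signed_rank(x, y, mode = "exact", alternative = "greater")
  expect_equal(res$p_value, 1 / 64, tolerance = 1e-12)
  two <- wilcoxon_signed_rank(x, y, mode = "exact")
  expect_equal(two$p_value, 2 / 64, tolerance = 1e-12)
})

test_that("exact Wilcoxon matches wilcox.test for tie-free paired data", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 3 || anyDuplicated(abs(d))) next
    res <- wilcoxon_signed_rank(d, mode = "exact")
    wt <- wilcox.test(d, exact = TRUE)
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, unname(wt$statistic))
  }
})

test_that("all-zero differences degenerate to p = 1", {
  res <- wilcoxon_signed_rank(c(3, 3, 3), c(3, 3, 3))
  expect_equal(res$p_value, 1)
})

test_that("Friedman omnibus: identical columns give statistic 0, p = 1", {
  m <- matrix(rep(c(1, 2, 3, 4, 5, 6), 3), ncol = 3)
  res <- friedman_with_posthoc(m)
  expect_equal(res$omnibus$statistic, 0)
  expect_equal(res$omnibus$p_value, 1)
  expect_null(res$posthoc)
})

test_that("a dominant condition passes the omnibus and is flagged post-hoc", {
  set.seed(9)
  base <- matrix(rnorm(12, sd = 0.1), ncol = 2)
  m <- cbind(base, rnorm(6, mean = 3, sd = 0.1))
  colnames(m) <- c("A", "B", "C")
  res <- friedman_with_posthoc(m, alpha = 0.05)
  expect_lt(res$omnibus$p_value, 0.05)
  expect_false(is.null(res$posthoc))
  withc <- res$posthoc[res$posthoc$a == "C" | res$posthoc$b == "C", ]
  expect_true(all(withc$p_value <= 0.05))
})

test_that("post-hocs run only when the omnibus passes", {
  set.seed(10)
  m <- matrix(rnorm(18), ncol = 3)
  res <- friedman_with_posthoc(m, alpha = 1e-6)
  expect_null(res$posthoc)
})

test_that("Friedman input validation", {
  expect_error(friedman_with_posthoc(matrix(1:4, ncol = 2)), ">= 3 conditions")
  m <- matrix(rnorm(9), ncol = 3); m[1, 1] <- NA
  expect_error(friedman_with_posthoc(m), "missing")
})

test_that("Spearman correlation endpoints and null behaviour", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  set.seed(2)
  rhos <- vapply(1:2000, function(i) {
    spearman_cor(rnorm(11), rnorm(11))$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.03)
})

test_that("percent change reproduces the published headline effects", {
  expect_equal(percent_change(95, 62, digits = 0), 53)
  expect_equal(percent_change(1.72, 3.40, digits = 0), -49)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(1, 0), "zero reference")
})

test_that("cohort report: summary statistics and reproducibility", {
  est <- expand.grid(animal_id = c("a1", "a2", "a3"),
                     compartment = c("DG", "total"),
                     stringsAsFactors = FALSE)
  est$group <- "nonTg"
  est$mean_len_um <- c(60, 62, 64, 60, 62, 64)
  est$v_mm3 <- c(1, 1, 1, 10, 10, 10)
  rep1 <- build_report(est)
  s <- rep1$summary
  row <- s[s$compartment == "DG" & s$parameter == "mean_len_um", ]
  expect_equal(row$mean, 62)
  expect_equal(row$sd, 2)
  # identical animals give SD 0
  est2 <- est; est2$mean_len_um <- 62
  s2 <- build_report(est2)$summary
  expect_equal(s2$sd[s2$parameter == "mean_len_um"], c(0, 0))
  # volume fractions from per-animal totals
  vf <- s[s$parameter == "vol_fraction_pct" & s$compartment == "DG", ]
  expect_equal(vf$mean, 10)
  # byte-identical reports from identical input
  stem1 <- tempfile(); stem2 <- tempfile()
  write_report(rep1, stem1); write_report(build_report(est), stem2)
  expect_identical(readLines(paste0(stem1, "_summary.csv")),
                   readLines(paste0(stem2, "_summary.csv")))
})

test_that("single-animal groups flag SD as unavailable", {
  est <- data.frame(animal_id = "a1", group = "Tg", compartment = "DG",
                    mean_len_um = 60, stringsAsFactors = FALSE)
  s <- build_report(est)$summary
  expect_true(is.na(s$sd))
})
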