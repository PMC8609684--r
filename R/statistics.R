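# Nonparametric comparison protocol for per-animal stereological estimates:
# exact Mann-Whitney U between groups, Friedman omnibus with exact Wilcoxon
# signed-rank post-hocs within groups, Spearman correlation, percent-change
# effect sizes and a publication-style summary report.
#
# Exact Mann-Whitney and Wilcoxon p-values are computed by full enumeration
# (which, unlike stats::wilcox.test, stays exact under ties: mid-ranks with
# the permutation distribution of the tied data). Two-sided p-values use the
# symmetry of the null distribution: p = P(min(T, M - T) <= observed min).

.mw_u_stat <- function(ranks, idx_a, n_a) {
  sum(ranks[idx_a]) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' @param group_a,group_b numeric samples (non-empty)
#' @param mode `"exact"` enumerates all group labelings of the pooled data
#'   (feasible up to ~12 per group); `"asymptotic"` uses the tie-corrected
#'   normal approximation of [stats::wilcox.test()].
#' @return list of class `comparison_result`: test, statistic (U of group A),
#'   p_value, n per group, medians and means
#' @export
mann_whitney <- function(group_a, group_b, mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b)) {
    stopf("invalid input: both groups must be non-empty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled)
  u_obs <- .mw_u_stat(ranks, seq_len(n_a), n_a)
  m <- n_a * n_b

  if (mode == "exact") {
    n_comb <- choose(n_a + n_b, n_a)
    if (n_comb > 5e5) {
      stopf("exact mode infeasible for %d x %d (use asymptotic)", n_a, n_b)
    }
    combs <- utils::combn(n_a + n_b, n_a)
    u_all <- colSums(matrix(ranks[combs], nrow = n_a)) - n_a * (n_a + 1) / 2
    lo <- min(u_obs, m - u_obs)
    p <- mean(pmin(u_all, m - u_all) <= lo + 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)$p.value
    )
  }
  structure(
    list(test = paste0("Mann-Whitney U (", mode, ")"),
         statistic = u_obs, p_value = min(p, 1),
         n = c(length(group_a), length(group_b)),
         medians = c(stats::median(group_a), stats::median(group_b)),
         means = c(mean(group_a), mean(group_b))),
    class = "comparison_result"
  )
}

#' Wilcoxon signed-rank test for paired samples (exact by sign enumeration)
#'
#' Zero differences are discarded (Wilcoxon convention); tied absolute
#' differences receive mid-ranks and the exact distribution is enumerated
#' over all 2^m sign assignments.
#'
#' @param x,y paired numeric samples, or `y = NULL` with `x` the differences
#' @param mode `"exact"` (feasible to m ~ 15 non-zero pairs) or
#'   `"asymptotic"`
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`
#' @return `comparison_result` with V (sum of positive ranks) and p
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("exact", "asymptotic"),
                                 alternative = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  if (!length(d)) stopf("invalid input: no pairs")
  d <- d[d != 0]
  if (!length(d)) {
    return(structure(
      list(test = "Wilcoxon signed-rank (degenerate)", statistic = 0,
           p_value = 1, n = length(x), medians = NA, means = NA),
      class = "comparison_result"
    ))
  }
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  tot <- m * (m + 1) / 2

  if (mode == "exact") {
    if (m > 20) stopf("exact mode infeasible for %d non-zero pairs", m)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    v_all <- as.vector(signs %*% r)
    p <- switch(alternative,
      two.sided = mean(pmin(v_all, tot - v_all) <=
                         min(v_obs, tot - v_obs) + 1e-9),
      greater = mean(v_all >= v_obs - 1e-9),
      less = mean(v_all <= v_obs + 1e-9)
    )
  } else {
    mu <- tot / 2
    ties <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_obs - mu) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
  }
  structure(
    list(test = paste0("Wilcoxon signed-rank (", mode, ")"),
         statistic = v_obs, p_value = min(p, 1), n = m,
         medians = stats::median(d), means = mean(d)),
    class = "comparison_result"
  )
}

#' Friedman omnibus test with Wilcoxon signed-rank post-hocs
#'
#' Runs the Friedman rank ANOVA over subjects x conditions; when the omnibus
#' p-value passes `alpha`, all pairwise exact Wilcoxon signed-rank tests are
#' run (mirroring the within-group protocol of stereological cohort
#' studies). Post-hoc p-values are uncorrected by default; `p_adjust` accepts
#' any [stats::p.adjust()] method (e.g. `"holm"`).
#'
#' @param mat numeric matrix, subjects in rows, >= 3 conditions in columns
#' @param alpha omnibus significance level gating the post-hocs
#' @param p_adjust multiplicity correction for the post-hoc p-values
#' @return list with `omnibus` (`comparison_result`) and `posthoc`
#'   (data.frame of pairwise results, or NULL when the omnibus fails)
#' @export
friedman_with_posthoc <- function(mat, alpha = 0.05, p_adjust = "none") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stopf("invalid input: need >= 3 conditions")
  if (anyNA(mat)) stopf("invalid input: missing cells")
  ft <- stats::friedman.test(mat)
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (!is.finite(stat)) {
    # every subject fully tied across conditions: no evidence of any effect
    rank_var <- apply(mat, 1, function(row) stats::var(rank(row)))
    if (all(rank_var == 0)) {
      stat <- 0
      pval <- 1
    }
  }
  omnibus <- structure(
    list(test = "Friedman rank ANOVA", statistic = stat,
         p_value = pval, n = nrow(mat),
         medians = apply(mat, 2, stats::median), means = colMeans(mat)),
    class = "comparison_result"
  )
  posthoc <- NULL
  if (!is.na(ft$p.value) && ft$p.value <= alpha) {
    cn <- colnames(mat)
    if (is.null(cn)) cn <- paste0("C", seq_len(ncol(mat)))
    pairs <- utils::combn(ncol(mat), 2)
    res <- apply(pairs, 2, function(pp) {
      w <- wilcoxon_signed_rank(mat[, pp[1]], mat[, pp[2]], mode = "exact")
      data.frame(a = cn[pp[1]], b = cn[pp[2]],
                 statistic = w$statistic, p_value = w$p_value,
                 stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, res)
    posthoc$p_adjusted <- stats::p.adjust(posthoc$p_value, method = p_adjust)
  }
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Spearman rank correlation
#'
#' Wraps [stats::cor.test()]; p-values are exact for small tie-free samples
#' and asymptotic otherwise. Constant input has no defined rank correlation
#' and raises an error.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list with `rho` and `p_value`
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("invalid input: need equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("undefined correlation: constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Percent change of a test mean relative to a reference mean
#'
#' @param test_mean,reference_mean group means (reference non-zero)
#' @param digits rounding for reporting; `NULL` returns the raw value
#' @return percent change, `100 * (test - reference) / reference`
#' @export
percent_change <- function(test_mean, reference_mean, digits = NULL) {
  if (any(reference_mean == 0)) stopf("division error: zero reference mean")
  pc <- 100 * (test_mean - reference_mean) / reference_mean
  if (!is.null(digits)) pc <- round(pc, digits)
  pc
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Build a publication-style cohort report
#'
#' From stacked per-animal estimates (rows per animal x compartment, as
#' produced by [estimate_animal()]), computes per (group, compartment)
#' means and SDs of every parameter plus per-animal volume fractions, exact
#' Mann-Whitney between-group tests with percent changes, and within-group
#' Friedman + Wilcoxon post-hocs across the principal cell layers for the
#' density-type parameters.
#'
#' @param estimates data.frame of per-animal estimates with `animal_id`,
#'   `group`, `compartment` and parameter columns
#' @param reference_group group label used as the percent-change reference
#' @param alpha significance level for flags and the post-hoc gate
#' @return list of class `stereo_report`: `summary`, `between_group`,
#'   `within_group`
#' @export
build_report <- function(estimates, reference_group = "nonTg", alpha = 0.05) {
  need <- c("animal_id", "group", "compartment")
  if (!all(need %in% names(estimates))) {
    stopf("invalid input: estimates need columns %s", paste(need, collapse = ", "))
  }
  # per-animal volume fractions (compartment V over that animal's total V)
  if ("v_mm3" %in% names(estimates) && "total" %in% estimates$compartment) {
    tot <- estimates[estimates$compartment == "total", c("animal_id", "v_mm3")]
    estimates$vol_fraction_pct <- 100 * estimates$v_mm3 /
      tot$v_mm3[match(estimates$animal_id, tot$animal_id)]
  }
  long <- .cohort_long_all(estimates)

  key <- interaction(long$group, long$compartment, long$parameter, drop = TRUE)
  summ <- do.call(rbind, lapply(split(long, key), function(s) {
    data.frame(group = s$group[1], compartment = s$compartment[1],
               parameter = s$parameter[1], n = nrow(s),
               mean = mean(s$value, na.rm = TRUE),
               sd = if (nrow(s) > 1) stats::sd(s$value, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  groups <- unique(long$group)
  between <- NULL
  if (length(groups) == 2 && reference_group %in% groups) {
    test_group <- setdiff(groups, reference_group)
    combos <- unique(long[, c("compartment", "parameter")])
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      cc <- combos$compartment[i]
      pp <- combos$parameter[i]
      a <- long$value[long$group == test_group & long$compartment == cc &
                        long$parameter == pp]
      b <- long$value[long$group == reference_group & long$compartment == cc &
                        long$parameter == pp]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      mw <- mann_whitney(a, b, mode = "exact")
      pch <- if (mean(b) != 0) {
        percent_change(mean(a), mean(b), digits = 0)
      } else NA_real_
      data.frame(compartment = cc, parameter = pp,
                 mean_test = mean(a), mean_ref = mean(b),
                 percent_change = pch,
                 u = mw$statistic, p_value = mw$p_value,
                 significant = mw$p_value <= alpha,
                 stringsAsFactors = FALSE)
    })
    between <- do.call(rbind, rows)
    rownames(between) <- NULL
  }

  pcl <- intersect(PCL_MEMBERS, unique(long$compartment))
  within <- NULL
  if (length(pcl) >= 3) {
    within_params <- intersect(c("nv_per_mm3", "lv_m_per_mm3", "rdiff_um"),
                               unique(long$parameter))
    rows <- list()
    for (g in groups) {
      for (pp in within_params) {
        sub <- long[long$group == g & long$parameter == pp &
                      long$compartment %in% pcl, ]
        mat <- stats::reshape(sub[, c("animal_id", "compartment", "value")],
                              idvar = "animal_id", timevar = "compartment",
                              direction = "wide")
        m <- as.matrix(mat[, -1, drop = FALSE])
        colnames(m) <- sub("^value\\.", "", colnames(m))
        if (anyNA(m) || nrow(m) < 3) next
        fr <- friedman_with_posthoc(m, alpha = alpha)
        rows[[paste(g, pp)]] <- data.frame(
          group = g, parameter = pp,
          friedman_chisq = fr$omnibus$statistic,
          friedman_p = fr$omnibus$p_value,
          posthoc = I(list(fr$posthoc)),
          stringsAsFactors = FALSE
        )
      }
    }
    within <- do.call(rbind, rows)
    if (!is.null(within)) rownames(within) <- NULL
  }

  structure(list(summary = summ, between_group = between,
                 within_group = within, alpha = alpha,
                 reference_group = reference_group),
            class = "stereo_report")
}

# long format including the derived volume-fraction column when present
.cohort_long_all <- function(estimates) {
  params <- c("v_mm3", "vol_fraction_pct", "n_cap", "n_endp", "nv_per_mm3",
              "nvendp_per_mm3", "l_m", "lv_m_per_mm3", "mean_len_um",
              "rdiff_um")
  params <- intersect(params, names(estimates))
  out <- do.call(rbind, lapply(params, function(pp) {
    data.frame(animal_id = estimates$animal_id, group = estimates$group,
               compartment = estimates$compartment, parameter = pp,
               value = estimates[[pp]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.stereo_report <- function(x, ...) {
  cat("Stereological cohort report\n")
  cat(sprintf("  groups: %s (reference: %s), alpha = %g\n",
              paste(unique(x$summary$group), collapse = ", "),
              x$reference_group, x$alpha))
  if (!is.null(x$between_group)) {
    sig <- x$between_group[x$between_group$significant, ]
    cat(sprintf("  %d between-group comparisons, %d significant\n",
                nrow(x$between_group), nrow(sig)))
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("    %s %s: %+d%% (p = %.3g)\n", sig$compartment[i],
                    sig$parameter[i], sig$percent_change[i], sig$p_value[i]))
      }
    }
  }
  invisible(x)
}

#' Write a cohort report to CSV (summary, comparisons) and JSON (everything)
#'
#' @param report a `stereo_report`
#' @param stem output path stem (writes `<stem>_summary.csv`,
#'   `<stem>_between_group.csv`, `<stem>.json`)
#' @export
write_report <- function(report, stem) {
  utils::write.csv(report$summary, paste0(stem, "_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$between_group)) {
    utils::write.csv(report$between_group, paste0(stem, "_between_group.csv"),
                     row.names = FALSE)
  }
  within <- report$within_group
  within_json <- NULL
  if (!is.null(within)) {
    within_json <- lapply(seq_len(nrow(within)), function(i) {
      list(group = within$group[i], parameter = within$parameter[i],
           friedman_chisq = within$friedman_chisq[i],
           friedman_p = within$friedman_p[i],
           posthoc = within$posthoc[[i]])
    })
  }
  jsonlite::write_json(
    list(summary = report$summary, between_group = report$between_group,
         within_group = within_json, alpha = report$alpha,
         reference_group = report$reference_group),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(stem)
}
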