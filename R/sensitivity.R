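# Sensitivity battery: heterogeneity (Cochran Q), directional pleiotropy
# (Egger intercept), outlier detection and correction (MR-PRESSO), and
# leave-one-out influence diagnostics.

#' Cochran heterogeneity test
#'
#' `Q = sum(((beta_out_j - fitted_j) / se_out_j)^2)` across instruments,
#' where fitted values come from the zero-intercept IVW fit (df = J - 1) or
#' the Egger regression (df = J - 2). Under homogeneity Q is chi-square on
#' its degrees of freedom; the p-value is the upper tail.
#'
#' @param pairs Harmonized pair table.
#' @param method `"ivw"` or `"egger"`.
#' @return A list with `method`, `q`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(pairs, method = c("ivw", "egger")) {
  method <- match.arg(method)
  fit <- if (method == "ivw") mr_ivw(pairs, "fixed") else mr_egger(pairs)
  structure(list(method = toupper(method), q = fit$q, q_df = fit$q_df,
                 q_pval = fit$q_pval),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran Q (%s): Q = %s on %d df, p = %s\n",
              x$method, fmt_num(x$q), x$q_df, fmt_num(x$q_pval, 3)))
  invisible(x)
}

#' Egger-intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; an intercept
#' distinguishable from zero indicates directional pleiotropy. The p-value
#' is two-sided normal on `intercept / se`.
#'
#' @param pairs Harmonized pair table (>= 3 instruments).
#' @return A list with `egger_intercept`, `intercept_se`, `intercept_pval`.
#' @export
egger_intercept_test <- function(pairs) {
  fit <- mr_egger(pairs)
  structure(list(egger_intercept = fit$intercept,
                 intercept_se = fit$intercept_se,
                 intercept_pval = fit$intercept_pval),
            class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept = %s (SE %s), p = %s\n",
              fmt_num(x$egger_intercept), fmt_num(x$intercept_se),
              fmt_num(x$intercept_pval, 3)))
  invisible(x)
}

# Leave-one-out IVW slopes from running sums; O(J) for all J slopes.
loo_slopes <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based outlier machinery in three parts. The global test
#' compares the observed residual sum of squares of leave-one-out IVW
#' predictions (residuals standardized by `se_out`) against its parametric
#' null distribution, obtained by redrawing exposure and outcome betas about
#' their no-pleiotropy expectations. The per-SNP outlier test compares each
#' observed squared residual with its simulated distribution
#' (Bonferroni-adjusted empirical p, `(r+1)/(n+1)` convention). When the
#' global test is significant and outliers are found, the distortion test
#' compares the raw against the outlier-corrected IVW estimate, referencing
#' the distortion expected from removing equally many random SNPs.
#'
#' @param pairs Harmonized pair table (>= 4 instruments).
#' @param n_sim Simulated datasets for the null distributions (default 1000).
#' @param outlier_alpha Level for the Bonferroni-adjusted per-SNP test
#'   (default 0.05).
#' @param global_alpha Level below which the global test triggers outlier
#'   reporting (default 0.05).
#' @param seed Simulation seed.
#' @return A list with `global_rss`, `global_pval`, `outlier_ids`,
#'   `outlier_pvals` (adjusted, all SNPs), `distortion_pval` (`NA` unless
#'   outliers are found), `beta_raw` and `beta_corrected` (`mr_result`s;
#'   corrected is `NULL` without outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05,
                      global_alpha = 0.05, seed = NULL) {
  pairs <- check_pairs(pairs, 4, "MR-PRESSO")
  j <- nrow(pairs)
  bx <- pairs$beta_exp; by <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  w <- 1 / sy^2

  b_loo <- loo_slopes(bx, by, w)
  res_obs <- (by - b_loo * bx) / sy
  rss_obs <- sum(res_obs^2)

  sim <- with_seed(seed, {
    bx_s <- matrix(stats::rnorm(j * n_sim, bx, sx), nrow = j)
    # outcome betas drawn about the no-pleiotropy predictions at the
    # simulated exposure betas
    by_s <- matrix(stats::rnorm(j * n_sim, b_loo * bx_s, sy), nrow = j)
    list(bx = bx_s, by = by_s)
  })
  # Recompute the statistic on each simulated dataset (weights fixed at 1/sy^2).
  s1 <- colSums(w * sim$bx * sim$by)
  s2 <- colSums(w * sim$bx^2)
  b_loo_s <- (rep(s1, each = j) - w * sim$bx * sim$by) /
    (rep(s2, each = j) - w * sim$bx^2)
  res_s <- (sim$by - b_loo_s * sim$bx) / sy
  rss_s <- colSums(res_s^2)

  global_pval <- (sum(rss_s >= rss_obs) + 1) / (n_sim + 1)
  p_raw <- (rowSums(res_s^2 >= res_obs^2) + 1) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  ids <- if ("variant_id" %in% names(pairs)) pairs$variant_id else as.character(seq_len(j))

  is_outlier <- global_pval < global_alpha & p_adj < outlier_alpha
  outlier_ids <- ids[is_outlier]

  beta_raw <- mr_ivw(pairs, "fixed")
  beta_corrected <- NULL
  distortion_pval <- NA_real_
  if (any(is_outlier) && sum(!is_outlier) >= 2) {
    keep <- pairs[!is_outlier, , drop = FALSE]
    beta_corrected <- mr_ivw(keep, "fixed")
    n_out <- sum(is_outlier)
    d_obs <- 100 * (beta_raw$beta - beta_corrected$beta) / abs(beta_corrected$beta)
    d_sim <- with_seed(seed, vapply(seq_len(n_sim), function(s) {
      drop_idx <- sample.int(j, n_out)
      kk <- pairs[-drop_idx, , drop = FALSE]
      bb <- sum((1 / kk$se_out^2) * kk$beta_exp * kk$beta_out) /
        sum((1 / kk$se_out^2) * kk$beta_exp^2)
      100 * (beta_raw$beta - bb) / abs(bb)
    }, numeric(1)))
    distortion_pval <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
  }

  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_ids = outlier_ids,
                 outlier_pvals = stats::setNames(p_adj, ids),
                 distortion_pval = distortion_pval,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %s, p = %s (%d simulations)\n",
              fmt_num(x$global_rss), fmt_num(x$global_pval, 3), x$n_sim))
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    cat(sprintf("  distortion test p = %s\n", fmt_num(x$distortion_pval, 3)))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Refits the fixed-effects IVW estimate with each instrument omitted in
#' turn, exposing SNPs whose removal materially changes the causal estimate.
#'
#' @param pairs Harmonized pair table (>= 3 instruments).
#' @return A data.frame with one row per omitted SNP: `left_out`, `n_snp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`; the full-data estimate is in
#'   attribute `full`.
#' @export
leave_one_out <- function(pairs) {
  pairs <- check_pairs(pairs, 3, "leave-one-out")
  ids <- if ("variant_id" %in% names(pairs)) pairs$variant_id else as.character(seq_len(nrow(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fit <- mr_ivw(pairs[-i, , drop = FALSE], "fixed")
    data.frame(left_out = ids[i], n_snp = fit$n_snp, beta = fit$beta,
               se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- mr_ivw(pairs, "fixed")
  out
}

#' Sensitivity summary table
#'
#' One compact report per exposure-outcome pair: Cochran Q from the Egger
#' and IVW fits, the Egger intercept with its SE and p-value, and the
#' MR-PRESSO global p-value, with a `pass` flag marking tests whose p-value
#' exceeds `alpha` (no detected heterogeneity/pleiotropy).
#'
#' @param pairs Harmonized pair table (>= 4 instruments for the PRESSO row;
#'   with 3 the PRESSO row is `NA`).
#' @param n_sim MR-PRESSO simulations.
#' @param alpha Level used for the pass/fail flags (default 0.05).
#' @param seed Simulation seed.
#' @return A data.frame with rows `MR Egger`, `IVW`, `MR-PRESSO` and columns
#'   `method`, `q`, `q_df`, `q_pval`, `egger_intercept`, `intercept_se`,
#'   `intercept_pval`, `presso_global_pval`, `pass`.
#' @export
sensitivity_table <- function(pairs, n_sim = 1000, alpha = 0.05, seed = NULL) {
  pairs <- check_pairs(pairs, 3, "sensitivity battery")
  qe <- cochran_q(pairs, "egger")
  qi <- cochran_q(pairs, "ivw")
  pl <- egger_intercept_test(pairs)
  presso_p <- if (nrow(pairs) >= 4) {
    mr_presso(pairs, n_sim = n_sim, seed = seed)$global_pval
  } else {
    NA_real_
  }
  out <- data.frame(
    method = c("MR Egger", "IVW", "MR-PRESSO"),
    q = c(qe$q, qi$q, NA),
    q_df = c(qe$q_df, qi$q_df, NA),
    q_pval = c(qe$q_pval, qi$q_pval, NA),
    egger_intercept = c(pl$egger_intercept, NA, NA),
    intercept_se = c(pl$intercept_se, NA, NA),
    intercept_pval = c(pl$intercept_pval, NA, NA),
    presso_global_pval = c(NA, NA, presso_p),
    stringsAsFactors = FALSE
  )
  ps <- cbind(out$q_pval, out$intercept_pval, out$presso_global_pval)
  out$pass <- apply(ps, 1, function(p) all(p[!is.na(p)] > alpha))
  out
}
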