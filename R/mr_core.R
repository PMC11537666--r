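# Two-sample MR estimators operating on harmonized per-SNP effect pairs.
#
# A "pairs" table needs columns beta_exp, se_exp, beta_out, se_out (one row
# per instrument); harmonize() output is filtered to its analyzable subset
# automatically.

mr_result <- function(method, beta, se, n_snp, pval = NULL, conf_level = 0.95,
                      df = NULL, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  if (is.null(pval)) {
    stat <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(stat)) else 2 * stats::pt(-abs(stat), df)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 odds_ratio = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high), n_snp = n_snp, ...),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %s (SE %s), 95%% CI [%s, %s], p = %s\n",
              fmt_num(x$beta), fmt_num(x$se), fmt_num(x$ci_low),
              fmt_num(x$ci_high), fmt_num(x$pval, 3)))
  cat(sprintf("  OR = %s, 95%% CI [%s, %s]\n",
              fmt_num(x$odds_ratio), fmt_num(x$or_ci_low), fmt_num(x$or_ci_high)))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             odds_ratio = x$odds_ratio, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, stringsAsFactors = FALSE)
}

check_pairs <- function(pairs, min_n, method) {
  pairs <- analyzable(pairs)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) config_error(sprintf("pairs lack column(s): %s",
                                         paste(miss, collapse = ", ")))
  if (nrow(pairs) < min_n) {
    insufficient_instruments(sprintf("%s requires at least %d instruments, got %d",
                                     method, min_n, nrow(pairs)))
  }
  pairs
}

#' Inverse-variance-weighted MR estimate
#'
#' Zero-intercept weighted regression of outcome on exposure betas with
#' weights `1/se_out^2`: `beta = sum(w bx by) / sum(w bx^2)`. The
#' fixed-effects SE is `(sum(w bx^2))^(-1/2)`; the multiplicative
#' random-effects SE inflates it by `max(1, sqrt(Q/(J-1)))` where Q is the
#' Cochran heterogeneity statistic. P-values are two-sided normal.
#'
#' @param pairs Harmonized pair table (>= 2 instruments; use
#'   [mr_wald_ratio()] for a single SNP).
#' @param mode `"fixed"` or `"random"` (multiplicative random effects).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `mr_result` with extra fields `q`, `q_df`, `q_pval`.
#' @export
mr_ivw <- function(pairs, mode = c("fixed", "random"), conf_level = 0.95) {
  mode <- match.arg(mode)
  pairs <- check_pairs(pairs, 2, "IVW")
  j <- nrow(pairs)
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = pairs, weights = w)
  beta <- unname(stats::coef(fit)[1])
  # known-variance (inverse-variance) SE, not lm's residual-scaled one
  se_fixed <- 1 / sqrt(sum(w * pairs$beta_exp^2))
  q <- sum(w * stats::resid(fit)^2)
  q_df <- j - 1L
  se <- if (mode == "random") se_fixed * max(1, sqrt(q / q_df)) else se_fixed
  mr_result(paste0("IVW_", mode), beta, se, j, conf_level = conf_level,
            q = q, q_df = q_df, q_pval = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' Wald ratio for a single instrument
#'
#' First-order ratio estimate `beta_out / beta_exp` with SE
#' `se_out / |beta_exp|`; the fallback when instrument selection leaves one
#' SNP.
#'
#' @param pairs Pair table with exactly one analyzable row.
#' @param conf_level Confidence level.
#' @return An `mr_result` with method `"Wald_ratio"`.
#' @export
mr_wald_ratio <- function(pairs, conf_level = 0.95) {
  pairs <- check_pairs(pairs, 1, "Wald ratio")
  if (nrow(pairs) != 1L) data_error("mr_wald_ratio expects exactly one instrument")
  if (pairs$beta_exp == 0) domain_error("Wald ratio undefined for beta_exp = 0")
  mr_result("Wald_ratio", pairs$beta_out / pairs$beta_exp,
            pairs$se_out / abs(pairs$beta_exp), 1L, conf_level = conf_level)
}

orient_positive <- function(pairs) {
  neg <- pairs$beta_exp < 0
  pairs$beta_out[neg] <- -pairs$beta_out[neg]
  pairs$beta_exp[neg] <- -pairs$beta_exp[neg]
  pairs
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas with a free intercept
#' (weights `1/se_out^2`), after orienting all pairs to non-negative exposure
#' effects. The slope is the causal estimate; a nonzero intercept signals
#' directional pleiotropy. Slope SEs use a multiplicative random-effects
#' scale `max(1, sigma)` and t-based p-values on J - 2 degrees of freedom;
#' the intercept p-value is two-sided normal (see
#' [egger_intercept_test()]).
#'
#' @param pairs Harmonized pair table (>= 3 instruments).
#' @param conf_level Confidence level.
#' @return An `mr_result` with extra fields `intercept`, `intercept_se`,
#'   `intercept_pval`, `q`, `q_df`, `q_pval`.
#' @export
mr_egger <- function(pairs, conf_level = 0.95) {
  pairs <- check_pairs(pairs, 3, "MR-Egger")
  pairs <- orient_positive(pairs)
  j <- nrow(pairs)
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(beta_out ~ beta_exp, data = pairs, weights = w)
  q <- sum(w * stats::resid(fit)^2)
  q_df <- j - 2L
  # known-variance SEs from the unscaled covariance, inflated by the
  # multiplicative overdispersion factor when the fit is underdispersed
  cu <- chol2inv(qr.R(fit$qr))
  scale <- max(1, sqrt(q / q_df))
  beta <- unname(stats::coef(fit)["beta_exp"])
  se <- sqrt(cu[2, 2]) * scale
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  intercept_se <- sqrt(cu[1, 1]) * scale
  mr_result("Egger", beta, se, j, conf_level = conf_level,
            pval = 2 * stats::pt(-abs(beta / se), q_df),
            intercept = intercept, intercept_se = intercept_se,
            intercept_pval = 2 * stats::pnorm(-abs(intercept / intercept_se)),
            q = q, q_df = q_df,
            q_pval = stats::pchisq(q, q_df, lower.tail = FALSE))
}

# Linearly interpolated weighted percentile of ratio estimates, the median
# rule shared by the estimator and its bootstrap.
weighted_percentile <- function(values, weights, prob = 0.5) {
  ord <- order(values)
  values <- values[ord]
  weights <- weights[ord] / sum(weights)
  cw <- cumsum(weights) - weights / 2
  if (prob <= cw[1]) return(values[1])
  if (prob >= cw[length(cw)]) return(values[length(values)])
  stats::approx(cw, values, xout = prob, ties = "ordered")$y
}

ratio_inputs <- function(pairs, method) {
  zero <- pairs$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("%s: %d pair(s) with beta_exp = 0 excluded", method, sum(zero)),
            call. = FALSE)
    pairs <- pairs[!zero, , drop = FALSE]
  }
  pairs
}

#' Weighted median MR estimate
#'
#' The weighted 50th percentile of per-SNP ratio estimates
#' `beta_out/beta_exp` with weights proportional to `beta_exp^2/se_out^2`,
#' consistent when at least half the weight comes from valid instruments.
#' The SE comes from a parametric bootstrap perturbing exposure and outcome
#' betas by their SEs.
#'
#' @param pairs Harmonized pair table (>= 3 instruments).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap; results are deterministic given a
#'   seed.
#' @param conf_level Confidence level.
#' @return An `mr_result` (two-sided normal p).
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = NULL,
                               conf_level = 0.95) {
  pairs <- check_pairs(pairs, 3, "weighted median")
  pairs <- ratio_inputs(pairs, "weighted median")
  b <- pairs$beta_out / pairs$beta_exp
  w <- pairs$beta_exp^2 / pairs$se_out^2
  est <- weighted_percentile(b, w)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(pairs), pairs$beta_exp, pairs$se_exp)
    by <- stats::rnorm(nrow(pairs), pairs$beta_out, pairs$se_out)
    ok <- bx != 0
    weighted_percentile(by[ok] / bx[ok], bx[ok]^2 / pairs$se_out[ok]^2)
  }, numeric(1)))
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se, nrow(pairs), conf_level = conf_level,
            seed = seed)
}

mode_bandwidth <- function(b, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(b), stats::mad(b)) * length(b)^(-1 / 5)
  s * bandwidth_factor
}

mode_point <- function(b, w, bw) {
  if (bw <= 0 || stats::sd(b) < 1e-12) return(stats::median(b))
  d <- stats::density(b, weights = w / sum(w), bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Mode-based MR estimators
#'
#' The mode of the smoothed empirical density of per-SNP ratio estimates,
#' consistent when the largest group of instruments sharing the same causal
#' effect is valid. `kind = "simple"` weights each ratio equally;
#' `kind = "weighted"` uses inverse-variance weights
#' `beta_exp^2/se_out^2`. The density uses a Gaussian kernel with bandwidth
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 * min(sd, mad) * J^(-1/5)` on the ratios. SE by parametric
#' bootstrap.
#'
#' @param pairs Harmonized pair table (>= 3 instruments).
#' @param kind `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the bandwidth rule (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return An `mr_result`.
#' @export
mr_mode <- function(pairs, kind = c("simple", "weighted"), bandwidth_factor = 1,
                    n_boot = 1000, seed = NULL, conf_level = 0.95) {
  kind <- match.arg(kind)
  pairs <- check_pairs(pairs, 3, "mode estimator")
  pairs <- ratio_inputs(pairs, "mode estimator")
  j <- nrow(pairs)
  b <- pairs$beta_out / pairs$beta_exp
  w <- if (kind == "weighted") pairs$beta_exp^2 / pairs$se_out^2 else rep(1, j)
  est <- mode_point(b, w, mode_bandwidth(b, bandwidth_factor))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(j, pairs$beta_exp, pairs$se_exp)
    by <- stats::rnorm(j, pairs$beta_out, pairs$se_out)
    ok <- bx != 0
    bb <- by[ok] / bx[ok]
    wb <- if (kind == "weighted") bx[ok]^2 / pairs$se_out[ok]^2 else rep(1, sum(ok))
    mode_point(bb, wb, mode_bandwidth(bb, bandwidth_factor))
  }, numeric(1)))
  se <- stats::sd(boots)
  mr_result(paste0(kind, "_mode"), est, se, j, conf_level = conf_level,
            seed = seed)
}

#' Run a battery of MR methods
#'
#' @param pairs Harmonized pair table.
#' @param methods Character vector from `ivw_fixed`, `ivw_random`, `egger`,
#'   `weighted_median`, `simple_mode`, `weighted_mode`, `bwmr`. A single
#'   analyzable SNP is routed to the Wald ratio regardless of `methods`.
#' @param n_boot Bootstrap replicates for bootstrap-based SEs.
#' @param seed Seed controlling all stochastic methods.
#' @return A data.frame with one row per method (columns as
#'   `as.data.frame.mr_result`).
#' @export
run_mr_methods <- function(pairs,
                           methods = c("ivw_fixed", "ivw_random", "egger",
                                       "weighted_median", "simple_mode",
                                       "weighted_mode"),
                           n_boot = 1000, seed = NULL) {
  pairs <- analyzable(pairs)
  if (nrow(pairs) == 0L) insufficient_instruments("no analyzable pairs")
  if (nrow(pairs) == 1L) return(as.data.frame(mr_wald_ratio(pairs)))
  seeds <- derive_seeds(seed, length(methods))
  rows <- lapply(seq_along(methods), function(i) {
    m <- methods[i]
    res <- tryCatch(switch(m,
      ivw_fixed = mr_ivw(pairs, "fixed"),
      ivw_random = mr_ivw(pairs, "random"),
      egger = mr_egger(pairs),
      weighted_median = mr_weighted_median(pairs, n_boot = n_boot, seed = seeds[[i]]),
      simple_mode = mr_mode(pairs, "simple", n_boot = n_boot, seed = seeds[[i]]),
      weighted_mode = mr_mode(pairs, "weighted", n_boot = n_boot, seed = seeds[[i]]),
      bwmr = bwmr_fit(pairs, seed = seeds[[i]]),
      config_error(sprintf("unknown MR method: %s", m))
    ), mrmediate_insufficient_instruments = function(e) NULL)
    if (is.null(res)) NULL else as.data.frame(res)
  })
  do.call(rbind, rows)
}
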