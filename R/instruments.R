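# Instrument selection and strength: p-value thresholding, greedy LD
# clumping, variance explained (R^2), F statistics, and study power.

#' Select SNPs by association p-value
#'
#' @param records Summary-statistic data.frame.
#' @param threshold Keep records with `pval < threshold` (strict), input
#'   order preserved. Conventional choices: 1e-5 for a permissive forward
#'   screen, 5e-8 (genome-wide significance) for reverse analyses.
#' @return The selected records.
#' @export
select_by_pvalue <- function(records, threshold) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    config_error("threshold must be a single number in (0, 1]")
  }
  out <- records[records$pval < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Prunes SNPs so the retained instruments are approximately independent:
#' SNPs are visited in order of ascending p-value (ties broken by
#' `variant_id`) and a SNP is accepted only if it is compatible with every
#' SNP already accepted. With a pairwise r-squared lookup (`ld`), a candidate
#' is rejected when its r-squared with an accepted SNP on the same chromosome
#' within `window_kb` is `>= r2_threshold`; pairs absent from the lookup are
#' treated as independent. Without a lookup (`distance_only`), a candidate is
#' rejected when any accepted SNP lies within `window_kb` on the same
#' chromosome.
#'
#' @param records Summary-statistic data.frame; must carry `chrom`/`pos` in
#'   distance-only mode.
#' @param r2_threshold Pairwise r-squared above which SNPs are considered
#'   linked (default 0.001).
#' @param window_kb Window in kilobases within which linkage is assessed
#'   (default 10000).
#' @param ld Optional symmetric numeric matrix of pairwise r-squared values
#'   with `variant_id` dimnames, or a function `(id1, id2) -> r2`.
#' @return The retained records, in the input's original order.
#' @export
clump_instruments <- function(records, r2_threshold = 0.001, window_kb = 10000,
                              ld = NULL) {
  if (!is_scalar_number(r2_threshold) || r2_threshold <= 0 || r2_threshold >= 1) {
    config_error("r2_threshold must be in (0, 1)")
  }
  if (!is_scalar_number(window_kb) || window_kb <= 0) {
    config_error("window_kb must be positive")
  }
  n <- nrow(records)
  if (n <= 1L) return(records)

  have_pos <- all(c("chrom", "pos") %in% names(records)) &&
    !anyNA(records$chrom) && !anyNA(records$pos)
  if (is.null(ld) && !have_pos) {
    data_error("distance-only clumping requires chrom and pos for every record")
  }

  lookup_r2 <- if (is.null(ld)) {
    NULL
  } else if (is.function(ld)) {
    ld
  } else {
    function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
    }
  }

  ord <- order(records$pval, records$variant_id)
  accepted <- integer(0)
  window_bp <- window_kb * 1000

  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      near <- if (have_pos) {
        records$chrom[i] == records$chrom[j] &&
          abs(records$pos[i] - records$pos[j]) <= window_bp
      } else {
        TRUE  # no coordinates: treat every accepted SNP as within range
      }
      if (!near) next
      if (is.null(lookup_r2)) {
        ok <- FALSE; break
      }
      r2 <- lookup_r2(records$variant_id[i], records$variant_id[j])
      if (!is.na(r2) && r2 >= r2_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- records[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of exposure variance explained by a SNP
#'
#' Computes `R^2 = beta^2 * eaf * (1 - eaf) / (se^2 * n)` per record, the
#' standard summary-statistic approximation for a standardized trait.
#'
#' @param records Summary-statistic data.frame (uses `beta`, `eaf`, `se`, `n`).
#' @return Numeric vector of per-SNP R^2 values, clipped into `[0, 1)` with a
#'   warning if the formula exceeds 1.
#' @export
compute_r2 <- function(records) {
  r2 <- records$beta^2 * records$eaf * (1 - records$eaf) / (records$se^2 * records$n)
  hi <- r2 >= 1
  if (any(hi)) {
    warning(sprintf("%d R^2 value(s) >= 1 clipped; check beta/se/n units", sum(hi)),
            call. = FALSE)
    r2[hi] <- 1 - 1e-12
  }
  r2
}

#' Instrument-strength F statistic
#'
#' `F = ((N - K - 1) / K) * (R^2 / (1 - R^2))` for a set of K instruments
#' jointly explaining `r2_total` of the exposure variance in a GWAS of N
#' individuals. Values above 10 conventionally indicate adequate strength.
#'
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @param r2_total Total variance explained, in `[0, 1)`.
#' @return The F statistic.
#' @export
compute_f <- function(n, k, r2_total) {
  if (any(n <= k + 1)) domain_error("compute_f requires n > k + 1")
  if (any(r2_total < 0 | r2_total >= 1)) domain_error("r2_total must be in [0, 1)")
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Per-SNP strength metrics
#'
#' @param records Summary-statistic data.frame.
#' @return `records` with columns `r2` (per-SNP variance explained) and
#'   `f_stat` (per-SNP F, computed with K = 1).
#' @export
instrument_strength <- function(records) {
  records$r2 <- compute_r2(records)
  records$f_stat <- compute_f(records$n, 1, records$r2)
  records
}

#' Remove weak instruments
#'
#' Keeps records whose per-SNP F statistic (K = 1) is strictly greater than
#' `f_min`; an instrument at exactly `f_min` is removed.
#'
#' @param records Summary-statistic data.frame.
#' @param f_min Strength threshold (default 10).
#' @param f Optional precomputed per-SNP F values; by default computed via
#'   [instrument_strength()].
#' @return The retained records.
#' @export
filter_weak_instruments <- function(records, f_min = 10, f = NULL) {
  if (is.null(f)) f <- instrument_strength(records)$f_stat
  if (length(f) != nrow(records)) config_error("length(f) must equal nrow(records)")
  out <- records[f > f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Power of a two-sample MR study with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio with a binary
#' outcome, following the summary-statistic MR power calculator methodology.
#' With case fraction v, the approximate effect on the observed scale is
#' `b = v * (OR / (1 + v*(OR - 1)) - 1)` with variance
#' `(v*(1 - v) - b^2) / (n * r2_total)`, giving non-centrality
#' `ncp = n * r2_total * b^2 / (v*(1 - v) - b^2)` and two-sided power
#' `pnorm(sqrt(ncp) - z) + pnorm(-sqrt(ncp) - z)` at `z = qnorm(1 - alpha/2)`.
#'
#' @param n Outcome GWAS sample size.
#' @param case_fraction Proportion of cases among outcome samples, in (0, 1).
#' @param r2_total Variance of the exposure explained by the instruments.
#' @param odds_ratio Causal odds ratio per SD of exposure to detect.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`; equals `alpha` when `odds_ratio = 1` or
#'   `r2_total = 0`.
#' @export
power_binary_outcome <- function(n, case_fraction, r2_total, odds_ratio,
                                 alpha = 0.05) {
  if (any(case_fraction <= 0 | case_fraction >= 1)) {
    domain_error("case_fraction must be in (0, 1)")
  }
  if (any(odds_ratio <= 0)) domain_error("odds_ratio must be positive")
  if (any(r2_total < 0 | r2_total >= 1)) domain_error("r2_total must be in [0, 1)")
  if (any(alpha <= 0 | alpha >= 1)) domain_error("alpha must be in (0, 1)")
  v <- case_fraction
  b <- v * (odds_ratio / (1 + v * (odds_ratio - 1)) - 1)
  ncp <- n * r2_total * b^2 / (v * (1 - v) - b^2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}
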