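# Synthetic GWAS summary statistics with known ground truth, emulating the
# structure of many-trait immune-phenotype screens, a mediator protein
# panel, and case-control (log-odds) outcome statistics.

#' Configuration for a simulated exposure-mediator-outcome triplet
#'
#' Defaults emulate the source-data structure: a modest immunophenotype
#' GWAS (n = 3757), a larger protein GWAS (n = 14,824), and a case-control
#' outcome GWAS (n = 160,589 with 1388 cases). Instrument effects are
#' scaled so that the exposure instruments jointly explain `r2_exposure`
#' of the exposure variance (and mediator instruments `r2_mediator` of the
#' mediator's).
#'
#' @param n_snps_exposure True exposure instruments (default 20).
#' @param n_snps_mediator True mediator instruments (default 20); these
#'   affect the outcome only through the mediator and are null for the
#'   exposure.
#' @param n_null_snps Background SNPs with no effect on any trait
#'   (default 100), so p-value thresholding is exercised.
#' @param maf_range Minor-allele-frequency range (default `c(0.05, 0.5)`).
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param case_fraction Case proportion of the binary outcome GWAS.
#' @param r2_exposure,r2_mediator Total variance explained by the
#'   instruments of each trait (defaults 0.5 and 0.2: cell-surface
#'   immunophenotypes and protein levels are strongly cis-regulated, and
#'   these values reproduce the typical 10-25 instruments surviving the
#'   p < 1e-5 / F > 10 screen at the default sample sizes).
#' @param theta1 Causal effect of exposure on mediator (default 0.2).
#' @param theta2 Causal effect of mediator on outcome, log-odds per unit
#'   (default 0.5).
#' @param theta_direct Direct exposure->outcome effect, log-odds
#'   (default 0.1).
#' @param pleiotropy List with `fraction` of invalid exposure instruments
#'   and the `mean`/`sd` of their additive pleiotropic outcome effects
#'   (directional when `mean != 0`); default no pleiotropy.
#' @param include_palindromic Fraction of SNPs given A/T or C/G alleles
#'   (default 0.15), to exercise harmonization.
#' @param seed Simulation seed.
#' @return A validated `triplet_config` list; the implied total effect
#'   `theta_direct + theta1 * theta2` is stored as `total_effect`.
#' @export
triplet_config <- function(n_snps_exposure = 20, n_snps_mediator = 20,
                           n_null_snps = 100, maf_range = c(0.05, 0.5),
                           n_exp = 3757, n_med = 14824, n_out = 160589,
                           case_fraction = 1388 / 160589,
                           r2_exposure = 0.5, r2_mediator = 0.2,
                           theta1 = 0.2, theta2 = 0.5, theta_direct = 0.1,
                           pleiotropy = list(fraction = 0, mean = 0, sd = 0.1),
                           include_palindromic = 0.15, seed = NULL) {
  cfg <- list(n_snps_exposure = n_snps_exposure,
              n_snps_mediator = n_snps_mediator, n_null_snps = n_null_snps,
              maf_range = maf_range, n_exp = n_exp, n_med = n_med,
              n_out = n_out, case_fraction = case_fraction,
              r2_exposure = r2_exposure, r2_mediator = r2_mediator,
              theta1 = theta1, theta2 = theta2, theta_direct = theta_direct,
              pleiotropy = utils::modifyList(list(fraction = 0, mean = 0, sd = 0.1),
                                             pleiotropy),
              include_palindromic = include_palindromic, seed = seed)
  with(cfg, {
    if (n_snps_exposure < 1 || n_exp <= 1 || n_med <= 1 || n_out <= 1) {
      config_error("SNP counts and sample sizes must be positive")
    }
    if (case_fraction <= 0 || case_fraction >= 1) {
      config_error("case_fraction must be in (0, 1)")
    }
    if (r2_exposure <= 0 || r2_exposure >= 1 || r2_mediator <= 0 || r2_mediator >= 1) {
      config_error("instrument R^2 must be in (0, 1): infeasible variance explained")
    }
    if (pleiotropy$fraction < 0 || pleiotropy$fraction > 1 ||
        include_palindromic < 0 || include_palindromic > 1) {
      config_error("fractions must lie in [0, 1]")
    }
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] >= maf_range[2]) {
      config_error("maf_range must satisfy 0 < low < high <= 0.5")
    }
  })
  cfg$total_effect <- cfg$theta_direct + cfg$theta1 * cfg$theta2
  structure(cfg, class = "triplet_config")
}

# Random allele pairs; the first n_pal variants are palindromic (A/T or C/G).
draw_alleles <- function(n, n_pal) {
  pal_choices <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  idx_p <- sample.int(nrow(pal_choices), n_pal, replace = TRUE)
  idx_n <- sample.int(nrow(nonpal), n - n_pal, replace = TRUE)
  ea <- c(pal_choices[idx_p, 1], nonpal[idx_n, 1])
  oa <- c(pal_choices[idx_p, 2], nonpal[idx_n, 2])
  ord <- sample.int(n)  # shuffle so palindromes are interspersed
  list(ea = ea[ord], oa = oa[ord])
}

# Observed summary statistics for one trait given per-SNP true effects.
# SEs use the standardized-trait approximation 1/sqrt(2 p (1-p) n), with an
# additional effective-sample-size factor v(1-v) for a case-control trait on
# the log-odds scale.
observe_gwas <- function(variants, true_beta, n, case_fraction = NULL) {
  eff <- if (is.null(case_fraction)) n else n * case_fraction * (1 - case_fraction)
  se <- 1 / sqrt(2 * variants$eaf * (1 - variants$eaf) * eff)
  beta <- stats::rnorm(nrow(variants), true_beta, se)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  pval <- pmax(pval, .Machine$double.xmin)  # keep within (0, 1]
  out <- data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
                    pos = variants$pos, effect_allele = variants$effect_allele,
                    other_allele = variants$other_allele, eaf = variants$eaf,
                    beta = beta, se = se, pval = pval, n = n,
                    stringsAsFactors = FALSE)
  structure(out, class = c("sumstats", "data.frame"))
}

# Scale raw effect draws so Sum 2 p (1-p) beta^2 equals the target R^2.
scale_to_r2 <- function(raw, eaf, r2_target) {
  raw * sqrt(r2_target / sum(2 * eaf * (1 - eaf) * raw^2))
}

#' Simulate an exposure-mediator-outcome summary-statistic triplet
#'
#' Generates three GWAS summary-statistic tables over a shared SNP panel
#' under the linear structural model `M = theta1 * X + e` and
#' `Y = theta2 * M + theta_direct * X + e` (outcome effects on the log-odds
#' scale, with case-control sampling entering through the effective-sample
#' -size SE). Exposure instruments draw effects from a normal scaled to the
#' target variance explained; mediator instruments affect the outcome only
#' through the mediator; invalid exposure instruments (the configured
#' pleiotropy fraction) receive additive pleiotropic outcome effects; a
#' configured fraction of SNPs is palindromic. P-values are computed from
#' the generated beta/SE, so threshold-based selection is exercised
#' end-to-end.
#'
#' @param config A [triplet_config()].
#' @return An `mr_triplet` list: `exposure`, `mediator`, `outcome`
#'   (summary-statistic data.frames) and `truth` (per-SNP true effects,
#'   invalid-instrument ids, the generative parameters, and the implied
#'   total effect).
#' @export
simulate_triplet <- function(config = triplet_config()) {
  stopifnot(inherits(config, "triplet_config"))
  with_seed(config$seed, {
    n_x <- config$n_snps_exposure
    n_m <- config$n_snps_mediator
    n_0 <- config$n_null_snps
    n_all <- n_x + n_m + n_0
    n_pal <- round(config$include_palindromic * n_all)

    al <- draw_alleles(n_all, n_pal)
    maf <- stats::runif(n_all, config$maf_range[1], config$maf_range[2])
    eaf <- ifelse(stats::runif(n_all) < 0.5, maf, 1 - maf)
    variants <- data.frame(
      variant_id = sprintf("rs%06d", seq_len(n_all)),
      chrom = as.character(sample.int(22, n_all, replace = TRUE)),
      pos = sample.int(2.4e8, n_all),
      effect_allele = al$ea, other_allele = al$oa, eaf = eaf,
      stringsAsFactors = FALSE
    )

    role <- c(rep("exposure_iv", n_x), rep("mediator_iv", n_m), rep("null", n_0))
    gamma <- delta <- alpha <- numeric(n_all)
    gamma[role == "exposure_iv"] <-
      scale_to_r2(stats::rnorm(n_x), eaf[role == "exposure_iv"], config$r2_exposure)
    delta[role == "mediator_iv"] <-
      scale_to_r2(stats::rnorm(n_m), eaf[role == "mediator_iv"], config$r2_mediator)

    n_invalid <- round(config$pleiotropy$fraction * n_x)
    invalid_idx <- which(role == "exposure_iv")[seq_len(n_invalid)]
    alpha[invalid_idx] <- stats::rnorm(n_invalid, config$pleiotropy$mean,
                                       config$pleiotropy$sd)

    beta_x <- gamma
    beta_m <- config$theta1 * gamma + delta
    beta_y <- config$theta_direct * gamma + config$theta2 * beta_m + alpha

    exposure <- observe_gwas(variants, beta_x, config$n_exp)
    mediator <- observe_gwas(variants, beta_m, config$n_med)
    outcome <- observe_gwas(variants, beta_y, config$n_out, config$case_fraction)

    truth <- list(variant_id = variants$variant_id, role = role,
                  gamma = gamma, delta = delta, alpha = alpha,
                  invalid_ids = variants$variant_id[invalid_idx],
                  theta1 = config$theta1, theta2 = config$theta2,
                  theta_direct = config$theta_direct,
                  total_effect = config$total_effect, config = unclass(config))
    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, truth = truth),
              class = "mr_triplet")
  })
}

#' Write a simulated triplet to disk
#'
#' Writes the three summary-statistic tables as TSV plus the ground truth
#' as JSON.
#'
#' @param triplet An `mr_triplet`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_triplet <- function(triplet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("exposure", "mediator", "outcome")) {
    write_summary_stats(triplet[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(triplet$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a many-exposure screening panel
#'
#' Generates `n_exposures` exposure GWAS datasets sharing one case-control
#' outcome, emulating a many-trait screen at reduced scale. The first
#' `n_causal` exposures have a true effect on the outcome equal to the
#' template's `total_effect`; the rest are null. Each exposure has its own
#' instruments; the outcome table stacks all SNPs.
#'
#' @param n_exposures Number of exposure datasets.
#' @param n_causal Number with a true causal effect (`<= n_exposures`).
#' @param config Template [triplet_config()]; per-exposure instrument count,
#'   sample sizes, `r2_exposure`, pleiotropy and palindromic fractions are
#'   taken from it. Seeds propagate hierarchically from `config$seed`.
#' @return A list with `exposures` (named list of summary-stat tables),
#'   `outcome`, and `truth` (data.frame with `exposure`, `causal`,
#'   `effect`).
#' @export
simulate_screen_panel <- function(n_exposures, n_causal,
                                  config = triplet_config()) {
  if (n_causal > n_exposures) config_error("n_causal must be <= n_exposures")
  seeds <- derive_seeds(config$seed, n_exposures)
  effects <- c(rep(config$total_effect, n_causal),
               rep(0, n_exposures - n_causal))
  names_e <- sprintf("exposure_%03d", seq_len(n_exposures))

  pieces <- lapply(seq_len(n_exposures), function(i) {
    cfg_i <- config
    cfg_i$seed <- seeds[[i]]
    cfg_i$theta_direct <- effects[i]
    cfg_i$theta1 <- 0          # no mediator structure in the screen panel
    cfg_i$theta2 <- 0
    cfg_i$n_snps_mediator <- 1
    cfg_i$total_effect <- effects[i]
    tr <- simulate_triplet(cfg_i)
    exp_i <- tr$exposure
    out_i <- tr$outcome
    prefix <- sprintf("e%03d_", i)
    exp_i$variant_id <- paste0(prefix, exp_i$variant_id)
    out_i$variant_id <- paste0(prefix, out_i$variant_id)
    list(exposure = exp_i, outcome = out_i)
  })

  outcome <- do.call(rbind, lapply(pieces, `[[`, "outcome"))
  rownames(outcome) <- NULL
  exposures <- stats::setNames(lapply(pieces, `[[`, "exposure"), names_e)
  truth <- data.frame(exposure = names_e,
                      causal = effects != 0, effect = effects,
                      stringsAsFactors = FALSE)
  list(exposures = exposures, outcome = outcome, truth = truth)
}
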