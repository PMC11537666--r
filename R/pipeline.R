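# End-to-end workflow: forward screen over many exposures, multi-cohort
# validation, reverse MR, sensitivity battery, and mediation, with a
# structured config and a line-oriented run log.

#' Default pipeline configuration
#'
#' @param ... Named overrides of the defaults: `p_forward` (1e-5),
#'   `p_reverse` (5e-8), `clump_r2` (0.001), `clump_kb` (10000), `ld`
#'   (optional r-squared lookup), `f_min` (10), `alpha` (0.05),
#'   `power_min` (0.8), `drop_all_palindromic` (TRUE), `methods`,
#'   `n_boot` (1000), `presso_nsim` (1000), `run_sensitivity` (TRUE),
#'   `seed` (NULL).
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    p_forward = 1e-5, p_reverse = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
    ld = NULL, f_min = 10, alpha = 0.05, power_min = 0.8,
    drop_all_palindromic = TRUE,
    methods = c("ivw_fixed", "ivw_random", "egger", "weighted_median",
                "simple_mode", "weighted_mode"),
    n_boot = 1000, presso_nsim = 1000, run_sensitivity = TRUE, seed = NULL
  )
  utils::modifyList(defaults, list(...))
}

# Instrument selection for one exposure: p-threshold, clump, strength filter.
select_instruments <- function(records, p_threshold, config) {
  iv <- select_by_pvalue(records, p_threshold)
  if (nrow(iv) == 0L) return(iv)
  iv <- clump_instruments(iv, r2_threshold = config$clump_r2,
                          window_kb = config$clump_kb, ld = config$ld)
  filter_weak_instruments(iv, f_min = config$f_min)
}

# Analyse one exposure against one outcome: returns method results, the
# headline estimate (fixed-effects IVW unless Cochran Q signals
# heterogeneity at alpha), and optionally the sensitivity battery.
analyze_exposure <- function(exposure, outcome, config, p_threshold, seed) {
  iv <- select_instruments(exposure, p_threshold, config)
  if (nrow(iv) == 0L) {
    return(list(status = "untestable", n_snp = 0L, results = NULL,
                headline = NULL, sensitivity = NULL))
  }
  pairs <- analyzable(harmonize(iv, outcome,
                                drop_all_palindromic = config$drop_all_palindromic))
  if (nrow(pairs) == 0L) {
    return(list(status = "untestable", n_snp = 0L, results = NULL,
                headline = NULL, sensitivity = NULL))
  }
  if (nrow(pairs) == 1L) {
    wr <- mr_wald_ratio(pairs)
    return(list(status = "wald_fallback", n_snp = 1L,
                results = as.data.frame(wr), headline = wr,
                sensitivity = NULL))
  }
  results <- run_mr_methods(pairs, methods = config$methods,
                            n_boot = config$n_boot, seed = seed)
  fixed <- mr_ivw(pairs, "fixed")
  headline <- if (fixed$q_pval > config$alpha) fixed else mr_ivw(pairs, "random")
  sens <- if (config$run_sensitivity && nrow(pairs) >= 3) {
    sensitivity_table(pairs, n_sim = config$presso_nsim, alpha = config$alpha,
                      seed = seed)
  } else {
    NULL
  }
  list(status = "ok", n_snp = nrow(pairs), results = results,
       headline = headline, sensitivity = sens, pairs = pairs)
}

#' Forward screen of many exposures against one outcome
#'
#' For each exposure: select instruments (p < `p_forward`, clump, F >
#' `f_min`), harmonize against the outcome, run the configured MR methods,
#' and (optionally) the sensitivity battery. An exposure is flagged when
#' its headline IVW p-value falls below `alpha` and every sensitivity test
#' passes. Per-exposure failures are logged and skipped, not fatal.
#' Benjamini-Hochberg q-values over the headline p-values are reported for
#' transparency but not used for flagging.
#'
#' @param exposures Named list of exposure summary-stat tables.
#' @param outcome Outcome summary-stat table.
#' @param config A [pipeline_config()].
#' @return A `screen_report` list: `summary` (one row per exposure:
#'   `exposure`, `status`, `n_snp`, `beta`, `se`, `pval`, `qval`,
#'   `odds_ratio`, `sensitivity_pass`, `flagged`) and `detail` (per-exposure
#'   result lists).
#' @export
forward_screen <- function(exposures, outcome, config = pipeline_config()) {
  if (length(exposures) == 0L) {
    warning("empty exposure collection; returning empty report", call. = FALSE)
    return(structure(list(summary = data.frame(), detail = list()),
                     class = "screen_report"))
  }
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- sprintf("exposure_%03d", seq_along(exposures))
  }
  seeds <- derive_seeds(config$seed, length(exposures))
  detail <- vector("list", length(exposures))
  names(detail) <- names(exposures)
  rows <- vector("list", length(exposures))

  for (i in seq_along(exposures)) {
    nm <- names(exposures)[i]
    res <- tryCatch(
      analyze_exposure(exposures[[i]], outcome, config, config$p_forward,
                       seeds[[i]]),
      error = function(e) list(status = paste("error:", conditionMessage(e)),
                               n_snp = 0L, results = NULL, headline = NULL,
                               sensitivity = NULL)
    )
    detail[[i]] <- res
    hl <- res$headline
    sens_pass <- if (is.null(res$sensitivity)) NA else all(res$sensitivity$pass)
    rows[[i]] <- data.frame(
      exposure = nm, status = res$status, n_snp = res$n_snp,
      beta = hl$beta %||% NA_real_, se = hl$se %||% NA_real_,
      pval = hl$pval %||% NA_real_, odds_ratio = hl$odds_ratio %||% NA_real_,
      sensitivity_pass = sens_pass, stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  summary$qval <- NA_real_
  ok <- !is.na(summary$pval)
  summary$qval[ok] <- stats::p.adjust(summary$pval[ok], method = "BH")
  summary$flagged <- ok & summary$pval < config$alpha &
    (is.na(summary$sensitivity_pass) | summary$sensitivity_pass)
  summary <- summary[, c("exposure", "status", "n_snp", "beta", "se", "pval",
                         "qval", "odds_ratio", "sensitivity_pass", "flagged")]
  structure(list(summary = summary, detail = detail), class = "screen_report")
}

#' Reverse MR of the outcome on previously screened traits
#'
#' Treats the outcome as exposure, selecting instruments at the stringent
#' genome-wide threshold `p_reverse`. An outcome with no SNP below the
#' threshold is reported as untestable rather than an error.
#'
#' @param outcome Outcome summary-stat table (acting as exposure).
#' @param traits Named list of trait summary-stat tables (acting as
#'   outcomes).
#' @param config A [pipeline_config()].
#' @return A list with `summary` (one row per trait: `trait`, `status`,
#'   `n_snp`, `beta`, `se`, `pval`) and `detail`.
#' @export
reverse_mr <- function(outcome, traits, config = pipeline_config()) {
  iv <- select_instruments(outcome, config$p_reverse, config)
  if (nrow(iv) == 0L) {
    return(list(summary = data.frame(
      trait = names(traits) %||% character(0),
      status = rep("untestable", length(traits)),
      n_snp = rep(0L, length(traits)), beta = NA_real_, se = NA_real_,
      pval = NA_real_, stringsAsFactors = FALSE
    ), detail = list(), n_instruments = 0L))
  }
  seeds <- derive_seeds(config$seed, length(traits))
  rows <- detail <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    pairs <- analyzable(harmonize(iv, traits[[i]],
                                  drop_all_palindromic = config$drop_all_palindromic))
    res <- if (nrow(pairs) == 0L) {
      list(status = "untestable", n_snp = 0L, headline = NULL)
    } else if (nrow(pairs) == 1L) {
      wr <- mr_wald_ratio(pairs)
      list(status = "wald_fallback", n_snp = 1L, headline = wr)
    } else {
      fixed <- mr_ivw(pairs, "fixed")
      hl <- if (fixed$q_pval > config$alpha) fixed else mr_ivw(pairs, "random")
      list(status = "ok", n_snp = nrow(pairs), headline = hl)
    }
    detail[[i]] <- res
    hl <- res$headline
    rows[[i]] <- data.frame(trait = names(traits)[i] %||% as.character(i),
                            status = res$status, n_snp = res$n_snp,
                            beta = hl$beta %||% NA_real_,
                            se = hl$se %||% NA_real_,
                            pval = hl$pval %||% NA_real_,
                            stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows), detail = detail,
       n_instruments = nrow(iv))
}

#' Validate flagged exposures in additional cohorts
#'
#' An exposure is validated when its discovery IVW p-value is below `alpha`
#' and every validation cohort gives a direction-consistent IVW estimate
#' (same sign) with p below `alpha`.
#'
#' @param screen A `screen_report` from [forward_screen()].
#' @param exposures The exposure tables used in the screen.
#' @param validation_outcomes Named list of validation-cohort outcome
#'   tables.
#' @param config A [pipeline_config()].
#' @return `screen$summary` augmented with per-cohort `beta`/`pval` columns
#'   and a logical `validated` column.
#' @export
validate_screen <- function(screen, exposures, validation_outcomes,
                            config = pipeline_config()) {
  summary <- screen$summary
  summary$validated <- summary$flagged
  for (cohort in names(validation_outcomes)) {
    bcol <- paste0("beta_", cohort); pcol <- paste0("pval_", cohort)
    summary[[bcol]] <- NA_real_; summary[[pcol]] <- NA_real_
    for (i in which(summary$flagged)) {
      nm <- summary$exposure[i]
      res <- tryCatch(
        analyze_exposure(exposures[[nm]], validation_outcomes[[cohort]],
                         config, config$p_forward, config$seed),
        error = function(e) NULL
      )
      hl <- res$headline
      if (is.null(hl)) { summary$validated[i] <- FALSE; next }
      summary[[bcol]][i] <- hl$beta
      summary[[pcol]][i] <- hl$pval
      consistent <- sign(hl$beta) == sign(summary$beta[i]) &&
        hl$pval < config$alpha
      summary$validated[i] <- summary$validated[i] && consistent
    }
  }
  summary
}

log_line <- function(con, ...) {
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", sprintf(...), "\n",
      sep = "", file = con, append = TRUE)
}

#' Run the full screening-validation-reverse-mediation workflow
#'
#' Executes, in order: forward screen of every exposure against the
#' discovery outcome; validation of flagged exposures in any validation
#' cohorts; reverse MR of the discovery outcome on the flagged exposures;
#' and, when mediator datasets are supplied, two-step mediation for every
#' flagged exposure x mediator pair whose two legs are both significant at
#' `alpha`. Results are returned and, when `out_dir` is given, written as
#' TSV tables (screen summary, sensitivity battery, mediation table) with a
#' line-oriented run log recording thresholds and seeds.
#'
#' @param datasets A list with elements `exposures` (named list),
#'   `outcome`, and optionally `mediators` (named list) and
#'   `validation_outcomes` (named list). Elements may be data.frames or
#'   file paths readable by [read_summary_stats()].
#' @param config A [pipeline_config()], or a path to a YAML file of
#'   overrides.
#' @param out_dir Optional output directory for TSV artifacts and the run
#'   log.
#' @return A list with `screen`, `validation`, `reverse`, `mediation`
#'   (data.frame, possibly absent when no mediators are given), and
#'   `config`.
#' @export
run_full <- function(datasets, config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  load_ds <- function(x) if (is.character(x)) read_summary_stats(x) else x
  exposures <- lapply(datasets$exposures, load_ds)
  outcome <- load_ds(datasets$outcome)
  mediators <- lapply(datasets$mediators %||% list(), load_ds)
  validation <- lapply(datasets$validation_outcomes %||% list(), load_ds)

  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(out_dir, "run.log")
    cat("", file = logf)
    log_line(logf, "run_full start: %d exposure(s), %d mediator(s), %d validation cohort(s)",
             length(exposures), length(mediators), length(validation))
    log_line(logf, "thresholds: p_forward=%g p_reverse=%g clump_r2=%g clump_kb=%g f_min=%g alpha=%g",
             config$p_forward, config$p_reverse, config$clump_r2,
             config$clump_kb, config$f_min, config$alpha)
    log_line(logf, "seed=%s presso_nsim=%d n_boot=%d",
             ifelse(is.null(config$seed), "NULL", as.character(config$seed)),
             config$presso_nsim, config$n_boot)
  }

  screen <- forward_screen(exposures, outcome, config)
  summary <- if (length(validation)) {
    validate_screen(screen, exposures, validation, config)
  } else {
    cbind(screen$summary, validated = screen$summary$flagged)
  }
  if (!is.null(logf)) {
    log_line(logf, "screen: %d/%d exposures flagged, %d validated",
             sum(summary$flagged), nrow(summary), sum(summary$validated))
  }

  flagged <- summary$exposure[summary$validated]
  reverse <- reverse_mr(outcome, exposures[flagged], config)
  if (!is.null(logf)) {
    log_line(logf, "reverse MR: %d instrument(s) at p < %g",
             reverse$n_instruments, config$p_reverse)
  }

  mediation <- NULL
  if (length(mediators)) {
    med_cfg <- list(p_threshold = config$p_forward, clump_r2 = config$clump_r2,
                    clump_kb = config$clump_kb, ld = config$ld,
                    f_min = config$f_min,
                    drop_all_palindromic = config$drop_all_palindromic)
    rows <- list()
    for (ex in flagged) {
      for (md in names(mediators)) {
        res <- tryCatch(
          mediation_pipeline(exposures[[ex]], mediators[[md]], outcome, med_cfg),
          mrmediate_error = function(e) NULL
        )
        if (is.null(res)) next
        legs <- attr(res, "legs")
        if (legs$step1$pval >= config$alpha || legs$step2$pval >= config$alpha) next
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(exposure = ex, mediator = md,
                           stringsAsFactors = FALSE),
                as.data.frame(res))
      }
    }
    mediation <- if (length(rows)) do.call(rbind, rows) else data.frame()
    if (!is.null(logf)) {
      log_line(logf, "mediation: %d qualifying exposure-mediator pair(s)",
               nrow(mediation))
    }
  }

  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "screen_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sens <- do.call(rbind, lapply(names(screen$detail), function(nm) {
      st <- screen$detail[[nm]]$sensitivity
      if (is.null(st)) return(NULL)
      cbind(data.frame(exposure = nm, stringsAsFactors = FALSE), st)
    }))
    if (!is.null(sens)) {
      utils::write.table(sens, file.path(out_dir, "sensitivity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(reverse$summary, file.path(out_dir, "reverse_mr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mediation) && nrow(mediation)) {
      utils::write.table(mediation, file.path(out_dir, "mediation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(logf)) log_line(logf, "run_full complete")
  }

  list(screen = list(summary = summary, detail = screen$detail),
       validation = if (length(validation)) summary else NULL,
       reverse = reverse, mediation = mediation, config = config)
}
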