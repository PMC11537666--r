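# Two-step MR mediation: decompose the exposure->outcome total effect into
# the component transmitted through a mediator (indirect = beta1 * beta2)
# and the residual direct effect, with first-order delta-method uncertainty
# for the product of coefficients.

#' Two-step mediation decomposition
#'
#' Given the total exposure->outcome effect, the exposure->mediator effect
#' (`beta1`) and the mediator->outcome effect (`beta2`), all on a consistent
#' (log-odds or linear) scale, computes the indirect effect
#' `beta1 * beta2`, the direct effect `total - indirect`, and the mediation
#' proportion `100 * indirect / total`. The indirect-effect variance uses
#' the first-order delta method,
#' `Var = beta1^2 * se2^2 + beta2^2 * se1^2` (optionally adding the
#' second-order term `se1^2 * se2^2`); the proportion interval propagates
#' the total effect's SE through the ratio, also by the delta method.
#'
#' @param total,total_se Total effect estimate and SE (exposure -> outcome).
#' @param beta1,se1 Exposure -> mediator estimate and SE.
#' @param beta2,se2 Mediator -> outcome estimate and SE.
#' @param second_order Include the `se1^2 * se2^2` variance term
#'   (default `FALSE`, the standard product-of-coefficients delta method).
#' @param conf_level Confidence level (default 0.95).
#' @return A `mediation_result` list: `total_effect`, `total_se`, `beta1`,
#'   `se1`, `beta2`, `se2`, `indirect`, `se_indirect`, `ci_indirect`,
#'   `direct`, `proportion` (percent; `NA` with a warning when `total` is
#'   zero), `se_proportion`, `ci_proportion`.
#' @export
two_step_mediation <- function(total, total_se = NA_real_, beta1, se1,
                               beta2, se2, second_order = FALSE,
                               conf_level = 0.95) {
  indirect <- beta1 * beta2
  var_ind <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) var_ind <- var_ind + se1^2 * se2^2
  se_ind <- sqrt(var_ind)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  direct <- total - indirect

  if (total == 0) {
    warning("total effect is zero; mediation proportion undefined", call. = FALSE)
    proportion <- se_prop <- NA_real_
    ci_prop <- c(NA_real_, NA_real_)
  } else {
    proportion <- 100 * indirect / total
    # Delta method on the ratio indirect/total, treating the two estimates
    # as independent (an interpretation: the legs come from separate fits).
    var_ratio <- var_ind / total^2 +
      if (is.na(total_se)) 0 else indirect^2 * total_se^2 / total^4
    se_prop <- 100 * sqrt(var_ratio)
    ci_prop <- proportion + c(-1, 1) * z * se_prop
  }

  structure(list(total_effect = total, total_se = total_se,
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 indirect = indirect, se_indirect = se_ind,
                 ci_indirect = indirect + c(-1, 1) * z * se_ind,
                 direct = direct, proportion = proportion,
                 se_proportion = se_prop, ci_proportion = ci_prop),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  total effect    = %s\n", fmt_num(x$total_effect)))
  cat(sprintf("  beta1 (exp->med) = %s (SE %s)\n", fmt_num(x$beta1), fmt_num(x$se1)))
  cat(sprintf("  beta2 (med->out) = %s (SE %s)\n", fmt_num(x$beta2), fmt_num(x$se2)))
  cat(sprintf("  indirect = %s, 95%% CI [%s, %s]\n", fmt_num(x$indirect),
              fmt_num(x$ci_indirect[1]), fmt_num(x$ci_indirect[2])))
  cat(sprintf("  direct   = %s\n", fmt_num(x$direct)))
  cat(sprintf("  mediation proportion = %s%%\n", fmt_num(x$proportion)))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(total_effect = x$total_effect, beta1 = x$beta1, se1 = x$se1,
             beta2 = x$beta2, se2 = x$se2, indirect = x$indirect,
             se_indirect = x$se_indirect, ci_indirect_low = x$ci_indirect[1],
             ci_indirect_high = x$ci_indirect[2], direct = x$direct,
             proportion = x$proportion,
             ci_proportion_low = x$ci_proportion[1],
             ci_proportion_high = x$ci_proportion[2],
             stringsAsFactors = FALSE)
}

# One MR leg of the mediation pipeline: instrument selection from the
# first dataset, harmonization against the second, IVW (Wald fallback).
mr_leg <- function(from, to, leg_name, config) {
  iv <- select_by_pvalue(from, config$p_threshold)
  iv <- clump_instruments(iv, r2_threshold = config$clump_r2,
                          window_kb = config$clump_kb, ld = config$ld)
  iv <- filter_weak_instruments(iv, f_min = config$f_min)
  pairs <- analyzable(harmonize(iv, to,
                                drop_all_palindromic = config$drop_all_palindromic))
  if (nrow(pairs) == 0L) {
    insufficient_instruments(sprintf("no instruments survive selection for the %s leg",
                                     leg_name))
  }
  fit <- if (nrow(pairs) == 1L) {
    mr_wald_ratio(pairs)
  } else if (config$ivw_mode == "auto") {
    f <- mr_ivw(pairs, "fixed")
    if (f$q_pval > 0.05) f else mr_ivw(pairs, "random")
  } else {
    mr_ivw(pairs, config$ivw_mode)
  }
  fit
}

mediation_config <- function(config = list()) {
  defaults <- list(p_threshold = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
                   ld = NULL, f_min = 10, drop_all_palindromic = TRUE,
                   ivw_mode = "auto", second_order = FALSE)
  utils::modifyList(defaults, config)
}

#' Full two-step MR mediation pipeline
#'
#' Runs three two-sample MR analyses -- exposure -> outcome (total effect),
#' exposure -> mediator (`beta1`), mediator -> outcome (`beta2`) -- each
#' with p-value instrument selection, LD clumping, weak-instrument
#' filtering, and harmonization, then applies [two_step_mediation()]. The
#' total effect is re-estimated from its own leg, not reconstructed as
#' direct + indirect.
#'
#' @param exposure,mediator,outcome Summary-statistic data.frames.
#' @param config Named list overriding defaults: `p_threshold` (1e-5),
#'   `clump_r2` (0.001), `clump_kb` (10000), `ld`, `f_min` (10),
#'   `drop_all_palindromic` (TRUE), `ivw_mode` (`"auto"`: fixed effects
#'   unless the Cochran Q p-value falls below .05), `second_order` (FALSE).
#' @return A `mediation_result` with the three leg `mr_result`s in
#'   attribute `legs`.
#' @export
mediation_pipeline <- function(exposure, mediator, outcome, config = list()) {
  config <- mediation_config(config)
  legs <- list(
    total = mr_leg(exposure, outcome, "exposure->outcome (total)", config),
    step1 = mr_leg(exposure, mediator, "exposure->mediator (beta1)", config),
    step2 = mr_leg(mediator, outcome, "mediator->outcome (beta2)", config)
  )
  res <- two_step_mediation(
    total = legs$total$beta, total_se = legs$total$se,
    beta1 = legs$step1$beta, se1 = legs$step1$se,
    beta2 = legs$step2$beta, se2 = legs$step2$se,
    second_order = config$second_order
  )
  attr(res, "legs") <- legs
  res
}
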