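# Reading, validating, writing, and harmonizing GWAS summary statistics.
#
# A summary-statistic table has one row per SNP-trait association with the
# canonical columns: variant_id, chrom, pos, effect_allele, other_allele,
# eaf, beta, se, pval, n. For binary traits beta is on the log-odds scale.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
SUMSTATS_REQUIRED <- setdiff(SUMSTATS_COLS, c("chrom", "pos"))

BASES <- c("A", "C", "G", "T")

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated file with a header row, maps columns onto
#' the canonical schema, and validates every row. Rows failing validation are
#' not silently dropped: they are returned in the `rejects` attribute with the
#' offending line number and a reason, and a message reports the count.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, optionally `chrom`, `pos`) to the file's column names.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `data.frame` of validated records in canonical column order with
#'   attribute `rejects` (a `data.frame` with columns `line`, `variant_id`,
#'   `reason`) and attribute `warnings` (rows whose reported p-value disagrees
#'   with the normal approximation from beta/se by more than a factor of 10 —
#'   flagged, not rejected).
#' @seealso [write_summary_stats()], [harmonize()]
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", check.names = FALSE)
  as_summary_stats(raw, column_map = column_map)
}

#' Coerce a data frame to validated summary statistics
#'
#' @param x A data.frame holding one row per SNP.
#' @param column_map As in [read_summary_stats()].
#' @return As [read_summary_stats()].
#' @export
as_summary_stats <- function(x, column_map = NULL) {
  nm <- names(x)
  resolve <- function(canonical) {
    col <- if (!is.null(column_map) && canonical %in% names(column_map)) {
      column_map[[canonical]]
    } else {
      canonical
    }
    if (col %in% nm) col else NA_character_
  }
  cols <- vapply(SUMSTATS_COLS, resolve, character(1))
  missing_req <- SUMSTATS_REQUIRED[is.na(cols[SUMSTATS_REQUIRED])]
  if (length(missing_req)) {
    config_error(sprintf("missing required column(s): %s",
                         paste(missing_req, collapse = ", ")))
  }

  n_row <- nrow(x)
  out <- data.frame(
    variant_id = as.character(x[[cols[["variant_id"]]]]),
    chrom = if (!is.na(cols[["chrom"]])) as.character(x[[cols[["chrom"]]]]) else NA_character_,
    pos = if (!is.na(cols[["pos"]])) suppressWarnings(as.integer(x[[cols[["pos"]]]])) else NA_integer_,
    effect_allele = toupper(as.character(x[[cols[["effect_allele"]]]])),
    other_allele = toupper(as.character(x[[cols[["other_allele"]]]])),
    eaf = suppressWarnings(as.numeric(x[[cols[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(x[[cols[["beta"]]]])),
    se = suppressWarnings(as.numeric(x[[cols[["se"]]]])),
    pval = suppressWarnings(as.numeric(x[[cols[["pval"]]]])),
    n = suppressWarnings(as.numeric(x[[cols[["n"]]]])),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n_row)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  num_cols <- c("eaf", "beta", "se", "pval", "n")
  unparsable <- Reduce(`|`, lapply(num_cols, function(cc) is.na(out[[cc]])))
  flag(unparsable, "unparsable numeric field")
  flag(!(out$effect_allele %in% BASES) | !(out$other_allele %in% BASES),
       "allele not a single A/C/G/T base")
  flag(out$effect_allele == out$other_allele, "effect and other allele identical")
  flag(!(out$eaf > 0 & out$eaf < 1), "eaf out of range")
  flag(!(out$se > 0), "se not positive")
  flag(!(out$pval > 0 & out$pval <= 1), "pval out of range")
  flag(!(out$n > 0), "n not positive")

  bad <- !is.na(reason)
  rejects <- data.frame(line = which(bad) + 1L,  # +1 for the header row
                        variant_id = out$variant_id[bad],
                        reason = reason[bad],
                        stringsAsFactors = FALSE)
  records <- out[!bad, , drop = FALSE]
  rownames(records) <- NULL

  # Consistency check (warning only): reported p against 2*pnorm(-|beta/se|).
  p_implied <- 2 * stats::pnorm(-abs(records$beta / records$se))
  checkable <- p_implied > 1e-290 & records$pval > 1e-290
  off <- checkable & abs(log10(records$pval) - log10(p_implied)) > 1
  warn_df <- data.frame(variant_id = records$variant_id[off],
                        pval = records$pval[off],
                        pval_implied = p_implied[off],
                        stringsAsFactors = FALSE)
  if (nrow(warn_df)) {
    warning(sprintf("%d record(s) have p-values inconsistent with beta/se by >10x; see attr(, 'warnings')",
                    nrow(warn_df)), call. = FALSE)
  }
  if (nrow(rejects)) {
    message(sprintf("%d row(s) rejected during validation; see attr(, 'rejects')",
                    nrow(rejects)))
  }
  structure(records, rejects = rejects, warnings = warn_df,
            class = c("sumstats", "data.frame"))
}

#' Write summary statistics in canonical column order
#'
#' @param records A summary-statistic data.frame.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path, sep = "\t") {
  cols <- intersect(SUMSTATS_COLS, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retrieve rejected rows from a read/validation step
#'
#' @param records Output of [read_summary_stats()] or [as_summary_stats()].
#' @return A data.frame with columns `line`, `variant_id`, `reason`.
#' @export
validation_rejects <- function(records) {
  attr(records, "rejects") %||%
    data.frame(line = integer(), variant_id = character(), reason = character())
}

#' Write the rejects report as TSV
#'
#' @inheritParams validation_rejects
#' @param path Output file path.
#' @export
write_rejects <- function(records, path) {
  utils::write.table(validation_rejects(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns, for every exposure SNP, the outcome association onto the exposure's
#' effect allele. Outcome records whose allele pair matches in the same
#' orientation are kept; a swapped pair has its effect sign inverted and its
#' effect-allele frequency reflected (`flipped`); strand-complement matches
#' are resolved by complementing the outcome alleles before comparison.
#' Palindromic SNPs (A/T or C/G), whose strand cannot be inferred from the
#' alleles, are dropped by default. Irreconcilable allele sets and exposure
#' SNPs absent from the outcome are dropped with the corresponding reason.
#'
#' @param exposure,outcome Summary-statistic data.frames (canonical columns),
#'   each with unique `variant_id`s.
#' @param drop_all_palindromic Drop every palindromic SNP (default `TRUE`).
#'   When `FALSE`, palindromic SNPs are aligned using allele frequencies and
#'   dropped only when either frequency falls inside `palindromic_eaf_window`
#'   (the strand-ambiguous zone).
#' @param palindromic_eaf_window Frequency window treated as ambiguous when
#'   `drop_all_palindromic = FALSE`.
#' @return A `data.frame` with one row per exposure SNP: `variant_id`,
#'   `effect_allele`, `other_allele` (the common, post-alignment pair),
#'   `chrom`, `pos`, exposure and outcome `beta`/`se`/`eaf`, `action`
#'   (`kept`, `flipped`, or `dropped`) and `drop_reason` (`palindromic`,
#'   `incompatible_alleles`, or `missing_in_outcome`; `NA` otherwise).
#' @seealso [analyzable()]
#' @export
harmonize <- function(exposure, outcome, drop_all_palindromic = TRUE,
                      palindromic_eaf_window = c(0.42, 0.58)) {
  for (what in c("exposure", "outcome")) {
    ids <- get(what)$variant_id
    if (anyDuplicated(ids)) {
      data_error(sprintf("duplicate variant_id in %s: %s", what,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
  }
  m <- match(exposure$variant_id, outcome$variant_id)
  has_chrom <- "chrom" %in% names(exposure)
  n <- nrow(exposure)

  out <- data.frame(
    variant_id = exposure$variant_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    chrom = if (has_chrom) exposure$chrom else rep(NA_character_, n),
    pos = if ("pos" %in% names(exposure)) exposure$pos else rep(NA_integer_, n),
    beta_exp = exposure$beta, se_exp = exposure$se, eaf_exp = exposure$eaf,
    pval_exp = exposure$pval, n_exp = exposure$n,
    beta_out = outcome$beta[m], se_out = outcome$se[m], eaf_out = outcome$eaf[m],
    pval_out = outcome$pval[m], n_out = outcome$n[m],
    action = rep(NA_character_, n), drop_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )

  ea_o <- outcome$effect_allele[m]
  oa_o <- outcome$other_allele[m]

  for (i in seq_len(nrow(out))) {
    if (is.na(m[i])) {
      out$action[i] <- "dropped"; out$drop_reason[i] <- "missing_in_outcome"
      next
    }
    ea_e <- out$effect_allele[i]; oa_e <- out$other_allele[i]
    eo <- ea_o[i]; oo <- oa_o[i]
    pal <- is_palindromic(ea_e, oa_e)

    if (pal && drop_all_palindromic) {
      out$action[i] <- "dropped"; out$drop_reason[i] <- "palindromic"
      next
    }

    # Resolve orientation: direct match, swapped match, then strand complement.
    flip <- NA
    if (eo == ea_e && oo == oa_e) {
      flip <- FALSE
    } else if (eo == oa_e && oo == ea_e) {
      flip <- TRUE
    } else if (!pal) {
      eoc <- complement_allele(eo); ooc <- complement_allele(oo)
      if (eoc == ea_e && ooc == oa_e) flip <- FALSE
      else if (eoc == oa_e && ooc == ea_e) flip <- TRUE
    }
    if (is.na(flip)) {
      out$action[i] <- "dropped"; out$drop_reason[i] <- "incompatible_alleles"
      next
    }

    if (flip) {
      out$beta_out[i] <- -out$beta_out[i]
      out$eaf_out[i] <- 1 - out$eaf_out[i]
    }

    if (pal) {
      # Frequency-based strand resolution for unambiguous palindromic SNPs.
      w <- palindromic_eaf_window
      ambiguous <- (out$eaf_exp[i] >= w[1] & out$eaf_exp[i] <= w[2]) ||
        (out$eaf_out[i] >= w[1] & out$eaf_out[i] <= w[2])
      if (ambiguous) {
        out$action[i] <- "dropped"; out$drop_reason[i] <- "palindromic"
        next
      }
      if ((out$eaf_exp[i] - 0.5) * (out$eaf_out[i] - 0.5) < 0) {
        # Outcome reported on the opposite strand: reverse the alignment.
        out$beta_out[i] <- -out$beta_out[i]
        out$eaf_out[i] <- 1 - out$eaf_out[i]
        flip <- !flip
      }
    }

    out$action[i] <- if (flip) "flipped" else "kept"
  }

  structure(out, class = c("harmonized", "data.frame"))
}

#' Analyzable subset of a harmonized table
#'
#' @param pairs Output of [harmonize()].
#' @return The rows with `action` `kept` or `flipped` (those usable by the MR
#'   estimators); also accepts an already-filtered pair table.
#' @export
analyzable <- function(pairs) {
  if ("action" %in% names(pairs)) {
    pairs <- pairs[pairs$action %in% c("kept", "flipped"), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}
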