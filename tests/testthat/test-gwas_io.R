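test_that("summary statistics round-trip through write/read, with column mapping", {
  df <- tiny_sumstats_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(as_summary_stats(df), path)
  back <- read_summary_stats(path)
  expect_equal(nrow(back), 3L)
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    expect_equal(back[[col]], df[[col]], tolerance = 1e-12)
  }
  expect_identical(back$variant_id, df$variant_id)
  expect_identical(back$effect_allele, df$effect_allele)

  # GWAS-catalog-style headers resolved through column_map; comma-separated.
  df2 <- df
  names(df2) <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE, quote = FALSE)
  back2 <- read_summary_stats(path2, column_map = c(
    variant_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pval = "P", n = "N"
  ))
  expect_equal(back2$beta, df$beta, tolerance = 1e-12)
})

test_that("invalid rows are rejected with reasons and line numbers, not dropped silently", {
  df <- tiny_sumstats_df()
  df$eaf[2] <- 1.2
  df$se[3] <- "oops"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(res <- read_summary_stats(path), "2 row\\(s\\) rejected")
  rej <- validation_rejects(res)
  expect_equal(nrow(res), 1L)
  expect_setequal(rej$reason, c("eaf out of range", "unparsable numeric field"))
  expect_equal(rej$line[rej$variant_id == "rs2"], 3L)  # header is line 1

  rej_path <- withr::local_tempfile(fileext = ".tsv")
  write_rejects(res, rej_path)
  expect_equal(read.delim(rej_path)$reason, rej$reason)
})

test_that("a missing required column is a configuration error naming the column", {
  df <- tiny_sumstats_df()
  df$se <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "se",
               class = "mrmediate_config_error")
})

test_that("p-values inconsistent with beta/se are flagged as warnings, not rejected", {
  df <- tiny_sumstats_df()
  df$pval[1] <- 0.5  # |z| = 5 implies p ~ 6e-7
  expect_warning(res <- as_summary_stats(df), "inconsistent")
  expect_equal(nrow(res), 3L)
  expect_equal(attr(res, "warnings")$variant_id, "rs1")
})

test_that("generator output round-trips with the generated SNP count and no rejects", {
  tr <- simulate_triplet(triplet_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tr$exposure, path)
  back <- read_summary_stats(path)
  n_expected <- with(tr$truth$config, n_snps_exposure + n_snps_mediator + n_null_snps)
  expect_equal(nrow(back), n_expected)
  expect_equal(nrow(validation_rejects(back)), 0L)
})

test_that("harmonization aligns swapped alleles by sign and frequency reflection", {
  expo <- data.frame(variant_id = "rs1", effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.5, se = 0.1, pval = 1e-8, n = 1000)
  outc <- data.frame(variant_id = "rs1", effect_allele = "G", other_allele = "A",
                     eaf = 0.72, beta = -0.2, se = 0.05, pval = 1e-4, n = 2000)
  h <- harmonize(expo, outc)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, 0.2)
  expect_equal(h$eaf_out, 1 - 0.72)
  expect_equal(h$effect_allele, "A")
})

test_that("harmonization drops palindromic, incompatible, and missing SNPs with reasons", {
  expo <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "A", "T"), other_allele = c("T", "G", "G", "C"),
    eaf = c(0.3, 0.3, 0.3, 0.3), beta = 0.1, se = 0.05, pval = 1e-6, n = 1000
  )
  outc <- data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "A"), other_allele = c("T", "G", "C"),
    eaf = c(0.3, 0.3, 0.3), beta = 0.1, se = 0.05, pval = 0.1, n = 1000
  )
  h <- harmonize(expo, outc)
  expect_equal(h$action, rep("dropped", 4))
  expect_equal(h$drop_reason,
               c("palindromic", "palindromic", "incompatible_alleles",
                 "missing_in_outcome"))
})

test_that("strand-complement outcome records are resolved before declaring incompatibility", {
  expo <- data.frame(variant_id = c("rs1", "rs2"),
                     effect_allele = c("A", "A"), other_allele = c("G", "G"),
                     eaf = 0.3, beta = 0.1, se = 0.05, pval = 1e-6, n = 1000)
  # rs1 reported on the other strand (T/C ~ A/G); rs2 other strand and swapped.
  outc <- data.frame(variant_id = c("rs1", "rs2"),
                     effect_allele = c("T", "C"), other_allele = c("C", "T"),
                     eaf = c(0.31, 0.69), beta = c(0.2, 0.2), se = 0.05,
                     pval = 0.1, n = 1000)
  h <- harmonize(expo, outc)
  expect_equal(h$action, c("kept", "flipped"))
  expect_equal(h$beta_out, c(0.2, -0.2))
})

test_that("palindromic SNPs outside the ambiguity window can be aligned by frequency", {
  expo <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                     effect_allele = "A", other_allele = "T",
                     eaf = c(0.2, 0.2, 0.5), beta = 0.1, se = 0.05,
                     pval = 1e-6, n = 1000)
  outc <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                     effect_allele = "A", other_allele = "T",
                     eaf = c(0.21, 0.78, 0.5), beta = c(0.3, 0.3, 0.3),
                     se = 0.05, pval = 0.1, n = 1000)
  h <- harmonize(expo, outc, drop_all_palindromic = FALSE)
  # rs1: frequencies concordant -> kept as-is; rs2: outcome frequency on the
  # other strand -> realigned; rs3: ambiguous (eaf = .5) -> dropped.
  expect_equal(h$action, c("kept", "flipped", "dropped"))
  expect_equal(h$beta_out, c(0.3, -0.3, 0.3))
  expect_equal(h$eaf_out[2], 1 - 0.78)
  expect_equal(h$drop_reason[3], "palindromic")
})

test_that("duplicate variant ids are a data error", {
  expo <- tiny_sumstats_df()
  expo$variant_id[2] <- "rs1"
  expect_error(harmonize(expo, tiny_sumstats_df()),
               class = "mrmediate_data_error")
})

test_that("allele swap is an involution and counts are conserved", {
  swap <- function(d) {
    tmp <- d$effect_allele
    d$effect_allele <- d$other_allele
    d$other_allele <- tmp
    d$beta <- -d$beta
    d$eaf <- 1 - d$eaf
    d
  }
  withr::with_seed(11, {
    for (rep in 1:5) {
      tr <- simulate_triplet(triplet_config(seed = 100 + rep, n_null_snps = 20))
      expo <- tr$exposure
      outc <- tr$outcome
      expect_equal(swap(swap(outc)), outc)

      h0 <- harmonize(expo, outc)
      expect_equal(nrow(h0), nrow(expo))  # count conservation
      expect_setequal(unique(h0$action), intersect(unique(h0$action),
                                                   c("kept", "flipped", "dropped")))
      expect_true(all(xor(h0$action == "dropped", is.na(h0$drop_reason))))

      # Swapping the whole outcome flips every analyzable pair's orientation
      # but leaves the aligned outcome effects identical.
      h1 <- harmonize(expo, swap(outc))
      a0 <- analyzable(h0); a1 <- analyzable(h1)
      expect_equal(a1$beta_out, a0$beta_out)
      expect_equal(a1$eaf_out, a0$eaf_out)
    }
  })
})

test_that("harmonizing an already-harmonized pair set is the identity", {
  tr <- simulate_triplet(triplet_config(seed = 5))
  h <- analyzable(harmonize(tr$exposure, tr$outcome))
  expo2 <- data.frame(variant_id = h$variant_id, effect_allele = h$effect_allele,
                      other_allele = h$other_allele, eaf = h$eaf_exp,
                      beta = h$beta_exp, se = h$se_exp, pval = h$pval_exp,
                      n = h$n_exp, stringsAsFactors = FALSE)
  outc2 <- data.frame(variant_id = h$variant_id, effect_allele = h$effect_allele,
                      other_allele = h$other_allele, eaf = h$eaf_out,
                      beta = h$beta_out, se = h$se_out, pval = h$pval_out,
                      n = h$n_out, stringsAsFactors = FALSE)
  h2 <- harmonize(expo2, outc2, drop_all_palindromic = FALSE)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_out, h$beta_out)
  expect_equal(h2$eaf_out, h$eaf_out)
})
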