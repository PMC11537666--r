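# Shared fixtures and independent oracles. Oracles deliberately re-derive
# each quantity through a different route (explicit matrix algebra, naive
# search, direct summation) than the package implementation.

# Harmonized-style instrument pairs from a linear model by = beta * gamma +
# pleiotropy + noise, with strong instruments by default.
sim_pairs <- function(j, beta = 0.3, sx = 0.01, sy = 0.05,
                      gamma_range = c(0.1, 0.3), pleio = rep(0, j),
                      positive_gamma = FALSE, seed = NULL) {
  draw <- function() {
    sgn <- if (positive_gamma) rep(1, j) else sample(c(-1, 1), j, replace = TRUE)
    gamma <- sgn * runif(j, gamma_range[1], gamma_range[2])
    data.frame(
      variant_id = sprintf("s%03d", seq_len(j)),
      beta_exp = gamma + rnorm(j, 0, sx), se_exp = rep(sx, j),
      beta_out = beta * gamma + pleio + rnorm(j, 0, sy), se_out = rep(sy, j),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Weighted least squares by explicit normal equations.
oracle_wls <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  W <- diag(w)
  xtwx_inv <- solve(t(X) %*% W %*% X)
  coefs <- xtwx_inv %*% t(X) %*% W %*% y
  resid <- y - X %*% coefs
  df <- length(y) - ncol(X)
  sigma2 <- as.numeric(t(resid) %*% W %*% resid) / df
  list(coef = as.numeric(coefs),
       se_unit = unname(sqrt(diag(xtwx_inv))),         # known-variance SE
       se_wls = unname(sqrt(sigma2 * diag(xtwx_inv))), # residual-scaled SE
       sigma = sqrt(sigma2),
       q = as.numeric(t(resid) %*% W %*% resid))
}

# Weighted 50th percentile by naive cumulative-weight search with linear
# interpolation between bracketing order statistics.
oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - 0.5 * w
  if (0.5 <= cum[1]) return(v[1])
  if (0.5 >= cum[length(cum)]) return(v[length(v)])
  k <- max(which(cum < 0.5))
  v[k] + (v[k + 1] - v[k]) * (0.5 - cum[k]) / (cum[k + 1] - cum[k])
}

# Cochran Q by direct summation around a supplied fitted line.
oracle_q <- function(bx, by, sy, slope, intercept = 0) {
  sum(((by - intercept - slope * bx) / sy)^2)
}

# Naive greedy clump: re-apply the acceptance rule by scanning all
# previously accepted SNPs, O(n^2), written independently of the package.
oracle_clump <- function(records, r2_threshold, window_kb, ld_matrix) {
  ord <- order(records$pval, records$variant_id)
  acc <- c()
  for (i in ord) {
    reject <- FALSE
    for (k in acc) {
      same_chr <- records$chrom[i] == records$chrom[k]
      near <- same_chr && abs(records$pos[i] - records$pos[k]) <= window_kb * 1000
      if (!near) next
      a <- records$variant_id[i]; b <- records$variant_id[k]
      r2 <- if (a %in% rownames(ld_matrix) && b %in% colnames(ld_matrix)) {
        ld_matrix[a, b]
      } else 0
      if (r2 >= r2_threshold) { reject <- TRUE; break }
    }
    if (!reject) acc <- c(acc, i)
  }
  sort(records$variant_id[sort(acc)])
}

# Mode by brute-force density-grid argmax over a fine grid of candidate
# effect values (direct kernel sum, no FFT binning).
oracle_mode_grid <- function(b, w, bw, n_grid = 4001) {
  grid <- seq(min(b) - 3 * bw, max(b) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w / sum(w) * dnorm(g, b, bw)), numeric(1))
  grid[which.max(dens)]
}

# A small crafted summary-stat table used by the IO tests.
tiny_sumstats_df <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "3"), pos = c(1000L, 2000L, 3000L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.25, 0.4, 0.1), beta = c(0.1, -0.05, 0.02),
    se = c(0.02, 0.01, 0.015),
    pval = c(2 * pnorm(-5), 2 * pnorm(-5), 2 * pnorm(-4 / 3)),
    n = c(1000, 1000, 1000), stringsAsFactors = FALSE
  )
}
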