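#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers can distinguish configuration problems, bad
# data, and analyses that are undefined for the supplied instrument count.
stop_mr <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mrmediate_error", "error", "condition")))
}

config_error <- function(msg) stop_mr(msg, "mrmediate_config_error")
data_error <- function(msg) stop_mr(msg, "mrmediate_data_error")
domain_error <- function(msg) stop_mr(msg, "mrmediate_domain_error")
insufficient_instruments <- function(msg) stop_mr(msg, "mrmediate_insufficient_instruments")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    config_error("seed must be a single finite number")
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Child seeds derived from a parent seed, kept within 32-bit integer range.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
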