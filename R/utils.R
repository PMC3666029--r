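# Internal helpers shared across modules.

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_dim <- function(...) {
  stop(structure(class = c("nwayfusion_dim_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("nwayfusion_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_precondition <- function(...) {
  stop(structure(class = c("nwayfusion_precondition_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x^2))

# Excess kurtosis of a numeric vector.
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 <= 0) return(NA_real_)
  mean(x^4) / m2^2 - 3
}

# Pearson correlation matrix between columns of a and columns of b,
# tolerating no NA and assuming n rows match.
cross_cor <- function(a, b) {
  stats::cor(a, b)
}

# Column-wise matched absolute correlations between two matrices with the
# same column count (column i of a vs column i of b).
matched_col_cor <- function(a, b) {
  vapply(seq_len(ncol(a)), function(i) stats::cor(a[, i], b[, i]),
         numeric(1))
}
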