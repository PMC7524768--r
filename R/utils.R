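# Internal helpers shared across the pipeline.

PROB_COLS <- paste0("p", 1:5)
SIMPLEX_TOL <- 1e-6

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Extract the probability matrix from a forecast table
#'
#' Forecast-like tables store probabilities in fixed-width columns `p1..p5`
#' with `NA` beyond a question's number of options.  This returns the dense
#' numeric matrix (one row per forecast, `NA` padding retained).
#'
#' @param df A data frame with columns `p1..p5`.
#' @return A numeric matrix with `nrow(df)` rows and 5 columns.
#' @keywords internal
prob_matrix <- function(df) {
  missing_cols <- setdiff(PROB_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing probability columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hf_validation_error")
  }
  as.matrix(df[PROB_COLS])
}

# Drop NA padding from a single stored probability row.
prob_vector <- function(row, n_options) {
  p <- as.numeric(row[seq_len(n_options)])
  p
}

# Pack a list/matrix of probability vectors into p1..p5 columns.
pack_probs <- function(pmat) {
  out <- matrix(NA_real_, nrow = nrow(pmat), ncol = 5,
                dimnames = list(NULL, PROB_COLS))
  out[, seq_len(ncol(pmat))] <- pmat
  as_tibble(out)
}

is_simplex <- function(p, tol = SIMPLEX_TOL) {
  all(p >= -tol) && abs(sum(p) - 1) <= tol
}

# One-hot vector of length n with mass on `idx`.
one_hot <- function(idx, n) {
  o <- numeric(n)
  o[idx] <- 1
  o
}

# Polynomial product (coefficient vectors, ascending powers).
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
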