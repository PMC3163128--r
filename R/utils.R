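# Internal numerical helpers.

#' Row-wise log-sum-exp
#'
#' Numerically stable `log(rowSums(exp(L)))` for a dense matrix of
#' log-density terms.  Rows whose entries are all `-Inf` return `-Inf`.
#'
#' @param L numeric matrix (rows = data, columns = mixture components).
#' @return numeric vector of length `nrow(L)`.
#' @keywords internal
#' @noRd
row_logsumexp <- function(L) {
  if (!is.matrix(L)) L <- as.matrix(L)
  m <- ncol(L)
  if (m == 1L) return(as.numeric(L[, 1L]))
  mx <- L[, 1L]
  for (j in 2L:m) mx <- pmax(mx, L[, j])
  out <- mx + log(rowSums(exp(L - mx)))
  bad <- !is.finite(mx)
  out[bad] <- mx[bad]
  out
}

# Shannon entropy (nats) of each row of a responsibility matrix.
row_entropy <- function(f) {
  p <- pmax(f, 0)
  h <- ifelse(p > 0, -p * log(p), 0)
  rowSums(h)
}

# Deterministic derived seed for the i-th sub-run of a seeded experiment.
# Kept well below 2^31 so it is always a valid integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000L + i) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
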