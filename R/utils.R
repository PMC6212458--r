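# internal numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise log-sum-exp of a matrix; -Inf columns stay -Inf
col_logsumexp <- function(M) {
  im <- max.col(t(M), ties.method = "first")
  mx <- M[cbind(im, seq_len(ncol(M)))]
  out <- mx + log(colSums(exp(M - rep(mx, each = nrow(M)))))
  out[!is.finite(mx)] <- -Inf
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
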