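# Internal helpers shared across modules.

# Deterministic child-seed derivation: one global seed fans out to per-stage
# streams so stages can be rerun independently with identical output.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-major lower-triangle index pairs of a k x k symmetric matrix:
# (1,1), (2,1), (2,2), (3,1), ...
lower_tri_pairs <- function(k) {
  i <- rep(seq_len(k), times = seq_len(k))
  j <- unlist(lapply(seq_len(k), seq_len))
  cbind(row = i, col = j)
}

# Extract distinct elements of a symmetric matrix in the canonical order.
vech <- function(S) {
  idx <- lower_tri_pairs(nrow(S))
  S[idx]
}

# Inverse of vech(): rebuild the symmetric matrix.
unvech <- function(s, k) {
  S <- matrix(0, k, k)
  idx <- lower_tri_pairs(k)
  S[idx] <- s
  S[idx[, c(2, 1)]] <- s
  S
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer scalar", name), call. = FALSE)
  }
}
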