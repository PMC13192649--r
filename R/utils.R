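# shared numerical helpers

# Euclidean projection of each row of a matrix onto the probability simplex
# (Condat / Duchi sort-based algorithm), vectorized across rows. Rows of
# length 1 map to 1.
project_rows_simplex <- function(W) {
  n <- nrow(W)
  k <- ncol(W)
  if (k == 1L) return(matrix(1, n, 1L, dimnames = dimnames(W)))
  # row-wise descending sort without apply()
  U <- matrix(W[order(row(W), -W)], n, k, byrow = TRUE)
  css <- U
  for (i in 2:k) css[, i] <- css[, i - 1L] + U[, i]
  cond <- U + (1 - css) / rep(seq_len(k), each = n) > 0
  rho <- rowSums(cond)  # condition holds exactly for columns 1..rho
  theta <- (css[cbind(seq_len(n), rho)] - 1) / rho
  out <- pmax(W - theta, 0)
  dimnames(out) <- dimnames(W)
  out
}

soft_threshold <- function(x, lambda) {
  if (!is.finite(lambda)) return(x * 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

# derive stage-level seeds from one master seed; offsets keep stages
# reproducible when rerun in isolation
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

# squared Euclidean cross-distance between rows of two matrices
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
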