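# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the code paths (and base helpers) used by
# the implementation: ranks are assigned by explicit sorting, least squares
# is solved by Gaussian elimination on the normal equations.

# Average ranks by explicit position lookup in the sorted vector.
oracle_avg_ranks <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(s == v)), numeric(1))
}

# Spearman rho as the covariance of average ranks over the product of their
# standard deviations.
oracle_spearman <- function(x, y) {
  xr <- oracle_avg_ranks(x)
  yr <- oracle_avg_ranks(y)
  cxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  cxy / sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
}

# Least squares via Gaussian elimination with partial pivoting on the
# normal equations X'X b = X'y (full-rank systems only).
oracle_ols <- function(X, y) {
  A <- t(X) %*% X
  b <- t(X) %*% y
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    for (i in (k + 1):n) {
      f <- M[i, k] / M[k, k]
      M[i, ] <- M[i, ] - f * M[k, ]
    }
  }
  out <- numeric(n)
  for (i in n:1) {
    out[i] <- (M[i, n + 1] - sum(M[i, seq_len(n)[-seq_len(i)]] *
                                   out[seq_len(n)[-seq_len(i)]])) / M[i, i]
  }
  out
}

# A small expression matrix with named genes and deterministic values.
toy_matrix <- function(n_cells = 12, genes = c("g1", "g2", "g3"),
                       seed = 42, scale = "log") {
  set.seed(seed)
  vals <- matrix(round(runif(n_cells * length(genes), 0, 5), 3),
                 n_cells, length(genes))
  expression_matrix(vals, genes, sprintf("c%02d", seq_len(n_cells)),
                    scale = scale)
}

# A toy raw-scale matrix carrying the three caspase markers plus extras.
toy_marker_matrix <- function(combined = c(2, 4, 8), extra_genes = 2,
                              seed = 7) {
  set.seed(seed)
  n <- length(combined)
  w <- matrix(runif(n * 3), n, 3)
  w <- w / rowSums(w)
  mk <- combined * w
  colnames(mk) <- c("CASP3", "CASP6", "CASP7")
  ex <- matrix(runif(n * extra_genes, 0, 10), n, extra_genes)
  colnames(ex) <- paste0("x", seq_len(extra_genes))
  vals <- cbind(mk, ex)
  expression_matrix(vals, colnames(vals), sprintf("c%02d", seq_len(n)))
}
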