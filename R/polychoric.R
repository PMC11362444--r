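# Polychoric correlation of a two-way contingency table (counts or
# probabilities). Two-step estimator: thresholds from the marginals, latent
# correlation by maximum likelihood over bivariate-normal cell probabilities.
# Cell rectangle probabilities are evaluated by Gauss-Legendre quadrature of
# the conditional normal, which is fast and accurate to ~1e-9 and keeps the
# whole computation vectorized.

polychoric <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab / sum(tab)
  rmar <- rowSums(tab); cmar <- colSums(tab)
  keep_r <- rmar > 0; keep_c <- cmar > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  clamp <- function(p) pmin(pmax(p, 1e-10), 1 - 1e-10)
  tr <- qnorm(clamp(cumsum(rowSums(tab))[-nrow(tab)]))
  tc <- qnorm(clamp(cumsum(colSums(tab))[-ncol(tab)]))
  nll <- function(z) {
    p <- binorm_cells(tr, tc, tanh(z))
    -sum(tab * log(pmax(p, 1e-12)))
  }
  opt <- optimize(nll, c(-6, 6))
  tanh(opt$minimum)
}

# matrix of P(a_{i-1} < X <= a_i, b_{j-1} < Y <= b_j) for standard bivariate
# normal with correlation rho; a, b are the interior thresholds
binorm_cells <- function(a, b, rho) {
  gl <- gauss_legendre(24L)
  lo <- c(-8, a); hi <- c(a, 8)
  nr <- length(lo); nc <- length(b) + 1L
  blo <- c(-Inf, b); bhi <- c(b, Inf)
  s <- sqrt(max(1 - rho^2, 1e-12))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    # nodes on (lo[i], hi[i])
    mid <- (hi[i] + lo[i]) / 2; half <- (hi[i] - lo[i]) / 2
    x <- mid + half * gl$nodes
    w <- half * gl$weights * dnorm(x)
    cnd <- outer(x, bhi, function(xx, bb) pnorm((bb - rho * xx) / s)) -
           outer(x, blo, function(xx, bb) pnorm((bb - rho * xx) / s))
    out[i, ] <- colSums(w * cnd)
  }
  out
}

gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # Golub-Welsch via symmetric tridiagonal eigen decomposition
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    Tm <- diag(0, n)
    Tm[cbind(k, k + 1)] <- beta
    Tm[cbind(k + 1, k)] <- beta
    e <- eigen(Tm, symmetric = TRUE)
    res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
    cache[[key]] <<- res
    res
  }
})
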