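# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (rolling sums, vectorized codings) and apply the rules
# marker-by-marker or window-by-window.

# differentiated-SNP criteria applied literally to each marker
bf_diff_snps <- function(gi, gj, min_i = 17L, min_j = 21L) {
  keep <- logical(ncol(gi))
  for (j in seq_len(ncol(gi))) {
    ci <- table(factor(gi[, j], levels = 0:2))
    cj <- table(factor(gj[, j], levels = 0:2))
    fi <- (ci[["1"]] + 2 * ci[["2"]]) / (2 * sum(ci))
    fj <- (cj[["1"]] + 2 * cj[["2"]]) / (2 * sum(cj))
    if (sum(ci) == 0 || sum(cj) == 0) next
    maj_i <- if (fi > 0.5) 2L else if (fi < 0.5) 0L else NA_integer_
    maj_j <- if (fj > 0.5) 2L else if (fj < 0.5) 0L else NA_integer_
    keep[j] <- max(ci) >= min_i && max(cj) >= min_j &&
      !is.na(maj_i) && !is.na(maj_j) && maj_i != maj_j
  }
  which(keep)
}

# exhaustive all-window enumeration of the introgression scan on a single
# chromosome's label vector; returns covered-SNP logical vectors per state
bf_scan_cover <- function(labels, window = 199L, min_hits = 120L) {
  k <- length(labels)
  cov_jj <- integer(k)
  cov_ij <- integer(k)
  if (k >= window) {
    for (s in seq_len(k - window + 1L)) {
      win <- labels[s:(s + window - 1L)]
      span <- s:(s + window - 1L)
      if (sum(win == "JJ") >= min_hits) cov_jj[span] <- cov_jj[span] + 1L
      if (sum(win == "IJ") >= min_hits) cov_ij[span] <- cov_ij[span] + 1L
    }
  }
  list(hom = cov_jj > 0 & cov_jj > cov_ij,
       het = cov_ij > 0 & cov_ij >= cov_jj)
}

# turn a coverage logical into (start_idx, end_idx) half-open runs
bf_runs <- function(covered) {
  r <- rle(covered)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  cbind(start = s[r$values] - 1L, end = e[r$values])
}

# naive double-loop A and D matrices from the printed formulas
bf_relationship <- function(g) {
  n <- nrow(g)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(g)
  w <- matrix(0, n, m)
  h <- matrix(0, n, m)
  for (j in seq_len(m)) {
    w[, j] <- (g[, j] - 1) - mean(g[, j] - 1)
    h[, j] <- (g[, j] == 1) - mean(g[, j] == 1)
  }
  denom <- 2 * sum(p * (1 - p))
  A <- matrix(0, n, n)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (l in seq_len(n)) {
      A[i, l] <- sum(w[i, ] * w[l, ]) / denom
      D[i, l] <- sum(h[i, ] * h[l, ]) / denom
    }
  list(A = A, D = D)
}

# direct grid maximization of the restricted log-likelihood for one kernel
# plus residual, on the (sigma2_g, sigma2_e) plane
bf_reml_grid <- function(y, X, K, grid = seq(0.01, 3, by = 0.01)) {
  n <- length(y)
  ll <- function(s2g, s2e) {
    V <- s2g * K + diag(s2e, n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              drop(t(y) %*% P %*% y))
  }
  best <- c(NA, NA, -Inf)
  for (a in grid) for (b in grid) {
    v <- ll(a, b)
    if (v > best[3]) best <- c(a, b, v)
  }
  list(sigma2 = best[1:2], loglik = best[3])
}

# small shared founder fixture (memoised per test run)
fixture_founders <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_founders(sim_config(n_chromosomes = 2L,
                                             markers_per_chromosome = 400L,
                                             diff_fraction = 0.75, seed = 42L))
    cache
  }
})
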