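#' Multi-kernel REML for Gaussian mixed models
#'
#' Fits y = X b + sum_i u_i + e with u_i ~ N(0, K_i s2_i) and
#' e ~ N(0, I s2_e) by restricted maximum likelihood. Updates use
#' average-information steps with a fixed-point (expectation-style)
#' fallback whenever an AI step would leave the parameter space or reduce
#' the restricted likelihood; components are truncated at a small
#' non-negative floor (boundary REML). Convergence is declared when the
#' relative change in restricted log-likelihood falls below `tol`.
#'
#' With a single kernel the model is rotated through the eigendecomposition
#' of K, which diagonalizes every iteration and makes n ~ 1000 fits cheap.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix (default intercept only).
#' @param K list of n x n PSD covariance (relationship) matrices.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum iterations.
#' @param jitter diagonal jitter added to any kernel whose smallest
#'   eigenvalue is negative due to rounding.
#' @return list of class `reml_fit`: `sigma2` (length(K)+1; residual last),
#'   `beta`, `blup` (list of BLUP vectors per kernel), `loglik`,
#'   `converged`, `iterations`.
#' @export
fit_reml <- function(y, X = NULL, K, tol = 1e-6, max_iter = 200L,
                     jitter = 1e-6) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  if (stats::var(y) == 0) stop("constant response")
  if (!is.list(K)) K <- list(K)
  K <- lapply(K, function(k) {
    k <- as.matrix(k)
    stopifnot(nrow(k) == n, ncol(k) == n)
    ev_min <- min(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0) k <- k + diag(jitter - ev_min, n)
    k
  })
  if (length(K) == 1L) reml_one_kernel(y, X, K[[1]], tol, max_iter)
  else reml_ai(y, X, K, tol, max_iter)
}

# General AI-REML with fixed-point fallback.
reml_ai <- function(y, X, K, tol, max_iter) {
  n <- length(y)
  q <- length(K)
  vy <- stats::var(y)
  floor_s2 <- 1e-8 * vy
  s2 <- rep(vy / (q + 1), q + 1)  # kernels first, residual last

  restricted_ll <- function(s2) {
    V <- diag(s2[q + 1], n)
    for (i in seq_len(q)) V <- V + s2[i] * K[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    chx <- chol(XtViX)
    P <- Vi - t(XtVi) %*% chol2inv(chx) %*% XtVi
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vi = Vi)
  }

  st <- restricted_ll(s2)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(K, function(k) k %*% Py)
    KPy[[q + 1]] <- Py
    Kfull <- c(K, list(diag(1, n)))
    grad <- numeric(q + 1)
    trPK <- numeric(q + 1)
    yPKPy <- numeric(q + 1)
    for (i in seq_len(q + 1)) {
      trPK[i] <- sum(P * Kfull[[i]])   # tr(P K_i) (both symmetric)
      yPKPy[i] <- sum(Py * KPy[[i]])
      grad[i] <- -0.5 * (trPK[i] - yPKPy[i])
    }
    AI <- matrix(0, q + 1, q + 1)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (i in seq_len(q + 1))
      for (j in i:(q + 1))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    s2_new <- if (is.null(step)) NULL else s2 + step
    ok <- !is.null(s2_new) && all(s2_new > -0.1 * vy)
    if (ok) {
      s2_new <- pmax(s2_new, floor_s2)
      st_new <- restricted_ll(s2_new)
      ok <- st_new$ll >= st$ll - 1e-10
    }
    if (!ok) {
      # fixed-point update keeps positivity and climbs the likelihood slowly
      s2_new <- pmax(s2 * sqrt(yPKPy / pmax(trPK, 1e-12)), floor_s2)
      st_new <- restricted_ll(s2_new)
      if (st_new$ll < st$ll) break  # no admissible improvement
    }
    rel <- abs(st_new$ll - st$ll) / (abs(st$ll) + 1)
    s2 <- s2_new
    st <- st_new
    if (rel < tol) { converged <- TRUE; break }
  }
  finish_reml(y, X, K, s2, st, converged, it)
}

finish_reml <- function(y, X, K, s2, st, converged, it) {
  q <- length(K)
  Vi <- st$Vi
  XtVi <- crossprod(X, Vi)
  beta <- drop(solve(XtVi %*% X, XtVi %*% y))
  Py <- st$Py
  blup <- lapply(seq_len(q), function(i) drop(s2[i] * (K[[i]] %*% Py)))
  structure(list(sigma2 = s2, beta = beta, blup = blup, loglik = st$ll,
                 converged = converged, iterations = it),
            class = "reml_fit")
}

# Single-kernel REML via eigendecomposition of K: after rotating by the
# eigenvectors, V is diagonal and each likelihood evaluation is O(n).
reml_one_kernel <- function(y, X, K, tol, max_iter) {
  n <- length(y)
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors
  lam <- pmax(e$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)
  vy <- stats::var(y)
  floor_s2 <- 1e-8 * vy

  ll_fun <- function(s2g, s2e) {
    dv <- s2g * lam + s2e
    if (any(dv <= 0)) return(-Inf)
    w <- 1 / dv
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    chx <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(chx)) return(-Inf)
    beta <- backsolve(chx, forwardsolve(t(chx), XtWy))
    r <- ys - Xs %*% beta
    -0.5 * (sum(log(dv)) + 2 * sum(log(diag(chx))) + sum(r^2 * w))
  }
  # profile out total variance: optimize the ratio h = s2g / (s2g + s2e)
  obj <- function(h) {
    s2 <- total_var_hat(h)
    ll_fun(h * s2, (1 - h) * s2)
  }
  total_var_hat <- function(h) {
    # GLS residual variance estimate at ratio h (unit total variance shape)
    dv <- h * lam + (1 - h)
    w <- 1 / dv
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    sum(r^2 * w) / (n - p)
  }
  opt <- stats::optimize(function(h) -obj(h), c(1e-9, 1 - 1e-9), tol = 1e-9)
  h <- opt$minimum
  s2tot <- total_var_hat(h)
  s2 <- c(max(h * s2tot, floor_s2), max((1 - h) * s2tot, floor_s2))
  # recover P y and V inverse in the original basis for BLUPs
  dv <- s2[1] * lam + s2[2]
  w <- 1 / dv
  XtWX <- crossprod(Xs, Xs * w)
  beta <- drop(solve(XtWX, crossprod(Xs, ys * w)))
  r <- ys - Xs %*% beta
  Py_rot <- r * w
  Py <- U %*% Py_rot
  Vi <- U %*% (t(U) * w)
  st <- list(ll = ll_fun(s2[1], s2[2]), P = NULL, Py = Py, Vi = Vi)
  finish_reml(y, X, list(K), s2, st, TRUE, 1L)
}
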