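# PLS1 core. All routines work in cross-product space: given the centered
# Gram matrix XtX = Xc'Xc (p x p) and covariance vector Xty = Xc'y, the
# kernel form of the NIPALS sequence yields, component by component, the
# weights w, loadings p, y-loadings q and the regression-coefficient path
# B_a = W (P'W)^-1 q. For a single response this is algebraically
# identical to NIPALS on the data matrix, but its cost per component is
# O(p^2) regardless of n — which is what makes the Random-frog chain
# (thousands of small submodel fits) affordable.

# Coefficient path in centered scale. Returns list(coefficients = p x A
# matrix (column a = coefficients using a components), ncomp = number of
# components actually extracted (may be < ncomp for rank-deficient or
# degenerate input; trailing columns are padded with the last valid
# solution), plus the weight/loading structure for the latent form.
.pls_path <- function(XtX, Xty, ncomp, tol = 1e-12) {
  p <- length(Xty)
  ncomp <- min(ncomp, p)
  B <- matrix(0, p, ncomp)
  W <- matrix(0, p, ncomp)   # NIPALS weights
  P <- matrix(0, p, ncomp)   # x-loadings
  Rm <- matrix(0, p, ncomp)  # W (P'W)^-1, built incrementally
  q <- numeric(ncomp)        # y-loadings
  S <- Xty
  ref <- max(sqrt(sum(Xty * Xty)), 1)
  tr0 <- max(sum(diag(XtX)), 1)
  b <- numeric(p)
  a <- 0L
  for (k in seq_len(ncomp)) {
    nw <- sqrt(sum(S * S))
    if (!is.finite(nw) || nw <= tol * ref) break
    w <- S / nw
    u <- drop(XtX %*% w)
    tt <- sum(w * u)
    if (!is.finite(tt) || tt <= tol * tr0) break
    pa <- u / tt
    qa <- nw / tt  # = (S'w)/tt since S'w = ||S||
    r <- if (k == 1L) w else
      w - drop(Rm[, 1:(k - 1L), drop = FALSE] %*%
                 crossprod(P[, 1:(k - 1L), drop = FALSE], w))
    b <- b + r * qa
    W[, k] <- w; P[, k] <- pa; Rm[, k] <- r; q[k] <- qa
    B[, k] <- b
    S <- S - pa * (tt * qa)
    XtX <- XtX - tcrossprod(pa) * tt
    a <- k
  }
  if (a < ncomp && a > 0L) for (k in (a + 1L):ncomp) B[, k] <- B[, a]
  list(coefficients = B, ncomp = a,
       weights = W[, seq_len(max(a, 1L)), drop = FALSE],
       loadings = P[, seq_len(max(a, 1L)), drop = FALSE],
       projection = Rm[, seq_len(max(a, 1L)), drop = FALSE],
       y_loadings = q[seq_len(max(a, 1L))])
}

# Centered cross-products from raw data.
.center_xprod <- function(x, y) {
  n <- nrow(x)
  xbar <- colMeans(x)
  ybar <- mean(y)
  xc <- sweep(x, 2L, xbar)
  list(XtX = crossprod(xc), Xty = drop(crossprod(xc, y - ybar)),
       xbar = xbar, ybar = ybar, n = n)
}

# Precomputed k-fold CV context over a fixed variable universe, shared by
# all submodel evaluations of a Random-frog run. Per fold we keep the
# uncentered training cross-products so that any variable subset V costs
# only a [V, V] slice plus centering.
.cv_context <- function(x, y, n_folds, fold_id) {
  n <- nrow(x)
  folds <- lapply(seq_len(n_folds), function(f) which(fold_id == f))
  ctx <- lapply(folds, function(test) {
    train <- setdiff(seq_len(n), test)
    xt <- x[train, , drop = FALSE]
    list(
      Sxx = crossprod(xt), sxy = drop(crossprod(xt, y[train])),
      xsum = colSums(xt), ysum = sum(y[train]), n_train = length(train),
      x_test = x[test, , drop = FALSE], y_test = y[test]
    )
  })
  list(folds = ctx, n = n)
}

# k-fold CV RMSE of the PLS submodel on variable subset `vars`.
.cv_rmse <- function(ctx, vars, max_lvs) {
  sse <- 0
  for (f in ctx$folds) {
    nt <- f$n_train
    xbar <- f$xsum[vars] / nt
    ybar <- f$ysum / nt
    XtX <- f$Sxx[vars, vars, drop = FALSE] - nt * tcrossprod(xbar)
    Xty <- f$sxy[vars] - nt * xbar * ybar
    a <- max(1L, min(length(vars), max_lvs, nt - 1L))
    path <- .pls_path(XtX, Xty, a)
    beta <- path$coefficients[, a]
    pred <- ybar + drop(sweep(f$x_test[, vars, drop = FALSE], 2L, xbar) %*% beta)
    sse <- sse + sum((f$y_test - pred)^2)
  }
  sqrt(sse / ctx$n)
}
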