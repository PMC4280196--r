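# Small fixtures and independent brute-force oracles used across tests.

tiny_scene <- function(seed = 1, n_leaf = 6, n_stem = 6, n_root = 4,
                       n_bands = 32, shape = c(8, 8), ...) {
  scene_config(rng_seed = seed, n_leaf = n_leaf, n_stem = n_stem,
               n_root = n_root, n_bands = n_bands, image_shape = shape, ...)
}

random_table <- function(n, p, seed = 1, wl = seq(420, 1000, length.out = p)) {
  set.seed(seed)
  x <- matrix(runif(n * p, 0.1, 0.9), n)
  spectra_table(x, runif(n, 0.5, 5), wl, sprintf("s%03d", seq_len(n)),
                organ = sample(c("leaf", "stem", "root"), n, replace = TRUE))
}

# A table with a few informative wavelengths among pure-noise bands.
planted_table <- function(n = 100, p = 100, planted = c(10, 30, 50, 70, 90),
                          effect = 1, band_noise = 0.05, seed = 1) {
  set.seed(seed)
  y <- runif(n, 1, 5)
  x <- matrix(rnorm(n * p), n)
  for (j in planted) x[, j] <- effect * (y - mean(y)) + rnorm(n, sd = band_noise)
  x <- x - min(x) + 0.01  # keep reflectance-like positivity
  wl <- seq(420, 1000, length.out = p)
  list(table = spectra_table(x, y, wl, sprintf("s%03d", seq_len(n))),
       planted = planted, wavelengths = wl)
}

# Brute-force joint x-y distance matrix (explicit double loop).
oracle_joint_distances <- function(x, y) {
  n <- nrow(x)
  dx <- dy <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dx[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
      dy[i, j] <- abs(y[i] - y[j])
    }
  }
  if (max(dx) > 0) dx <- dx / max(dx)
  if (max(dy) > 0) dy <- dy / max(dy)
  dx + dy
}

# Naive Kennard-Stone sequence on a distance matrix, recomputing the
# min-distance-to-selected from scratch at every step.
oracle_ks_sequence <- function(d, n_select) {
  n <- nrow(d)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand_best <- NA_integer_; cand_val <- -Inf
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mi <- min(d[i, sel])
      if (mi > cand_val) { cand_val <- mi; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Independent PLS1 oracle: textbook NIPALS on the data matrix with
# X-deflation, nothing shared with the package's kernel-space path.
oracle_nipals <- function(x, y, a) {
  xbar <- colMeans(x); ybar <- mean(y)
  X <- sweep(x, 2, xbar); yc <- y - ybar
  W <- NULL; P <- NULL; q <- numeric(0)
  for (k in seq_len(a)) {
    w <- drop(crossprod(X, yc))
    w <- w / sqrt(sum(w^2))
    tt_vec <- drop(X %*% w)
    tt <- sum(tt_vec^2)
    p_load <- drop(crossprod(X, tt_vec)) / tt
    q <- c(q, sum(yc * tt_vec) / tt)
    X <- X - tcrossprod(tt_vec, p_load)
    W <- cbind(W, w); P <- cbind(P, p_load)
  }
  beta <- drop(W %*% solve(crossprod(P, W), q))
  list(beta = beta, intercept = ybar - sum(beta * xbar))
}

# Hand-rolled leave-one-out RMSECV via the NIPALS oracle.
oracle_loocv_rmsecv <- function(x, y, a) {
  n <- nrow(x)
  err <- numeric(n)
  for (i in seq_len(n)) {
    fit <- oracle_nipals(x[-i, , drop = FALSE], y[-i], a)
    err[i] <- y[i] - (fit$intercept + sum(fit$beta * x[i, ]))
  }
  sqrt(mean(err^2))
}
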