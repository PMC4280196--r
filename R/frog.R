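#' Random-frog configuration
#'
#' Tuning parameters for the Random-frog chain: a reversible-jump
#' MCMC-like walk over wavelength subsets with an embedded PLS submodel.
#' The defaults are the standard settings for Vis/NIR work: 10,000
#' iterations, an initial subset of 50 variables, proposal-spread control
#' `theta = 0.3`, candidate-pool multiplier `omega = 3`, acceptance upper
#' bound `eta = 0.1`, and 50 independent repetitions whose selection
#' probabilities are averaged.
#'
#' @param iterations chain length T per run.
#' @param q initial subset size Q (clipped to the number of variables,
#'   with a warning, if larger).
#' @param theta proposal-size spread: the candidate size is drawn from
#'   `Normal(Q_t, theta * Q_t)`, rounded, and clipped to `[1, p]`.
#' @param omega candidate-pool multiplier: a growing proposal pools
#'   `omega * (Q* - Q_t)` fresh variables before trimming back.
#' @param eta upper bound on the probability of accepting a worse subset.
#' @param n_runs independent repetitions averaged into the final
#'   selection probability.
#' @param rng_seed master seed; one seeded stream drives all runs.
#' @param submodel_max_lvs latent-variable cap of the embedded PLS
#'   submodel.
#' @param cv_folds folds of the submodel's cross-validated RMSE.
#' @return Object of class `"frog_config"`.
#' @export
frog_config <- function(iterations = 10000L, q = 50L, theta = 0.3, omega = 3,
                        eta = 0.1, n_runs = 50L, rng_seed = 1L,
                        submodel_max_lvs = 10L, cv_folds = 5L) {
  .assert_scalar_number(iterations, "iterations", lower = 1)
  .assert_scalar_number(q, "q", lower = 1)
  .assert_scalar_number(theta, "theta", lower = 0, strict = TRUE)
  .assert_scalar_number(omega, "omega", lower = 1)
  .assert_scalar_number(eta, "eta", lower = 0, strict = TRUE)
  if (eta > 1) .config_stop("eta", "must be <= 1")
  .assert_scalar_number(n_runs, "n_runs", lower = 1)
  .assert_scalar_number(rng_seed, "rng_seed")
  .assert_scalar_number(submodel_max_lvs, "submodel_max_lvs", lower = 1)
  .assert_scalar_number(cv_folds, "cv_folds", lower = 2)
  structure(
    list(iterations = as.integer(iterations), q = as.integer(q),
         theta = theta, omega = omega, eta = eta,
         n_runs = as.integer(n_runs), rng_seed = as.integer(rng_seed),
         submodel_max_lvs = as.integer(submodel_max_lvs),
         cv_folds = as.integer(cv_folds)),
    class = "frog_config"
  )
}

# Coefficient ranking of a variable pool on the full calibration data:
# fit the PLS submodel on `pool` and return the pool ordered by
# decreasing |coefficient| (ties toward the lower variable index).
.rank_pool <- function(gram, pool, max_lvs, n) {
  a <- max(1L, min(length(pool), max_lvs, n - 1L))
  XtX <- gram$XtX[pool, pool, drop = FALSE]
  Xty <- gram$Xty[pool]
  path <- .pls_path(XtX, Xty, a)
  beta <- path$coefficients[, a]
  pool[order(-abs(beta), pool)]
}

#' Random-frog wavelength selection
#'
#' Runs the Random-frog chain `n_runs` times and averages the per-run
#' selection probabilities (SP): the fraction of iterations in which each
#' wavelength sat in the retained subset. Each iteration draws a
#' candidate subset size `Q*` from `Normal(Q_t, theta * Q_t)` (rounded,
#' clipped to `[1, p]`), builds a candidate subset — shrinking keeps the
#' `Q*` variables with the largest absolute submodel coefficients;
#' growing pools `omega * (Q* - Q_t)` fresh variables drawn uniformly
#' from the complement and trims the pooled fit back to `Q*` — and
#' accepts it outright when its cross-validated submodel RMSE does not
#' exceed the incumbent's, otherwise with probability
#' `eta * RMSE_incumbent / RMSE_candidate` (which is below `eta` by
#' construction). Deterministic for a fixed seed.
#'
#' @param table a [spectra_table()] with at least `cv_folds` samples.
#' @param config a [frog_config()].
#' @return Object of class `"frog_result"`: `selection_probability`
#'   (named by wavelength, averaged over runs), `sp_runs`
#'   (`n_runs x p` trace matrix), `wavelengths`, `ranking` (wavelengths
#'   by decreasing SP), `config`, and `n_rejected_nonfinite`.
#' @export
random_frog <- function(table, config = frog_config()) {
  stopifnot(inherits(table, "spectra_table"), inherits(config, "frog_config"))
  x <- table$x
  y <- table$y
  n <- nrow(x)
  p <- ncol(x)
  if (p < 1L) stop("table has no wavelengths", call. = FALSE)
  if (n < config$cv_folds) {
    stop("need at least 'cv_folds' samples", call. = FALSE)
  }
  q0 <- config$q
  if (q0 > p) {
    warning(sprintf("initial subset size Q = %d clipped to p = %d", q0, p))
    q0 <- p
  }
  gram <- .center_xprod(x, y)
  max_lvs <- config$submodel_max_lvs
  n_bad <- 0L
  sp_runs <- matrix(0, config$n_runs, p)
  .with_seed(config$rng_seed, {
    for (run in seq_len(config$n_runs)) {
      fold_id <- sample(rep_len(seq_len(config$cv_folds), n))
      ctx <- .cv_context(x, y, config$cv_folds, fold_id)
      V <- sort(sample.int(p, q0))
      err_V <- .cv_rmse(ctx, V, max_lvs)
      counts <- numeric(p)
      for (t in seq_len(config$iterations)) {
        qt <- length(V)
        qstar <- as.integer(round(stats::rnorm(1L, qt, config$theta * qt)))
        qstar <- min(max(qstar, 1L), p)
        if (qstar == qt) {
          Vstar <- V
          err_star <- err_V
        } else {
          if (qstar < qt) {
            Vstar <- sort(.rank_pool(gram, V, max_lvs, n)[seq_len(qstar)])
          } else {
            comp <- setdiff(seq_len(p), V)
            n_draw <- min(ceiling(config$omega * (qstar - qt)), length(comp))
            pool <- c(V, comp[sample.int(length(comp), n_draw)])
            Vstar <- sort(.rank_pool(gram, pool, max_lvs, n)[seq_len(qstar)])
          }
          err_star <- .cv_rmse(ctx, Vstar, max_lvs)
        }
        if (!is.finite(err_star)) {
          n_bad <- n_bad + 1L  # proposal rejected, event logged
        } else if (err_star <= err_V ||
                   stats::runif(1L) < config$eta * err_V / err_star) {
          V <- Vstar
          err_V <- err_star
        }
        counts[V] <- counts[V] + 1
      }
      sp_runs[run, ] <- counts / config$iterations
    }
  })
  sp <- colMeans(sp_runs)
  names(sp) <- format(table$wavelengths, trim = TRUE, digits = 10)
  ranking <- table$wavelengths[order(-sp, table$wavelengths)]
  structure(
    list(selection_probability = sp, sp_runs = sp_runs,
         wavelengths = table$wavelengths, ranking = ranking,
         config = config, n_rejected_nonfinite = n_bad),
    class = "frog_result"
  )
}

#' @export
print.frog_result <- function(x, ...) {
  cat(sprintf(
    "<frog_result> %d wavelengths, %d run(s) x %d iterations (seed %d)\n",
    length(x$wavelengths), x$config$n_runs, x$config$iterations,
    x$config$rng_seed))
  top <- utils::head(x$ranking, 8L)
  cat("  top wavelengths:", paste(format(top, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.frog_result <- function(x, ...) {
  graphics::plot(x$wavelengths, x$selection_probability, type = "h",
                 xlab = "wavelength (nm)", ylab = "selection probability",
                 main = "Random-frog selection probability", ...)
  invisible(x)
}

#' Top-k wavelengths of a Random-frog ranking
#'
#' Wavelengths ordered by decreasing selection probability; tied SPs are
#' resolved toward the lower wavelength.
#'
#' @param result a [random_frog()] result.
#' @param k how many wavelengths, `1 <= k <= p`.
#' @return Numeric vector of `k` wavelengths (nm).
#' @export
rank_wavelengths <- function(result, k) {
  stopifnot(inherits(result, "frog_result"))
  p <- length(result$wavelengths)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > p) {
    stop(sprintf("'k' must lie in [1, %d]", p), call. = FALSE)
  }
  result$ranking[seq_len(as.integer(k))]
}

#' Write / read a Random-frog result as JSON
#'
#' @param result a [random_frog()] result.
#' @param path JSON destination / source.
#' @return `write_frog_json`: `path` invisibly; `read_frog_json`: a
#'   `"frog_result"` object (without the per-run trace matrix).
#' @export
write_frog_json <- function(result, path) {
  stopifnot(inherits(result, "frog_result"))
  obj <- list(
    wavelengths = result$wavelengths,
    selection_probability = unname(result$selection_probability),
    ranking = result$ranking,
    config = unclass(result$config),
    n_rejected_nonfinite = result$n_rejected_nonfinite
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_frog_json
#' @export
read_frog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$selection_probability
  names(sp) <- format(obj$wavelengths, trim = TRUE, digits = 10)
  structure(
    list(selection_probability = sp, sp_runs = NULL,
         wavelengths = obj$wavelengths, ranking = obj$ranking,
         config = do.call(frog_config, obj$config),
         n_rejected_nonfinite = obj$n_rejected_nonfinite),
    class = "frog_result"
  )
}
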