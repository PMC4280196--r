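#' Fit a partial least squares regression (PLS1)
#'
#' Mean-centered PLSR of a single response on a spectral matrix, computed
#' with the kernel form of the NIPALS component sequence (numerically
#' identical for one response). No autoscaling is applied: the pipeline
#' models reflectance as-is. The fitted model carries both its latent
#' structure (weights, loadings, projection) and the equivalent explicit
#' linear form — intercept plus one coefficient per wavelength — which is
#' what pixel-wise chemical imaging consumes.
#'
#' @param x numeric `n x p` matrix of spectra, or a [spectra_table()]
#'   (in which case `y` defaults to its TNC values).
#' @param y numeric response vector, length `n`.
#' @param ncomp number of latent variables, `1 <= ncomp <= min(n - 1, p)`.
#' @param wavelengths optional numeric band labels (nm); taken from
#'   column names / the table when available.
#' @return Object of class `"plsr_fit"` with components including
#'   `coefficients` (per-wavelength, centered-data scale already folded
#'   into the intercept), `intercept`, `ncomp`, `ncomp_used`,
#'   `projection`, `y_loadings`, `x_mean`, `y_mean`, `fitted_values`.
#' @examples
#' x <- matrix(rnorm(40 * 6), 40)
#' y <- x[, 2] * 2 + rnorm(40, sd = 0.1)
#' fit <- fit_plsr(x, y, ncomp = 2)
#' coef(fit)
#' @export
fit_plsr <- function(x, y = NULL, ncomp, wavelengths = NULL) {
  if (inherits(x, "spectra_table")) {
    if (is.null(y)) y <- x$y
    if (is.null(wavelengths)) wavelengths <- x$wavelengths
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("'y' must have one value per row of 'x'", call. = FALSE)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("'x' and 'y' must be finite", call. = FALSE)
  }
  max_ncomp <- min(n - 1L, p)
  if (!is.numeric(ncomp) || length(ncomp) != 1L || ncomp < 1L) {
    stop("'ncomp' must be a positive integer", call. = FALSE)
  }
  if (ncomp > max_ncomp) {
    warning(sprintf("ncomp reduced from %d to feasible maximum %d", ncomp, max_ncomp))
    ncomp <- max_ncomp
  }
  if (is.null(wavelengths)) {
    wavelengths <- suppressWarnings(as.numeric(colnames(x)))
    if (length(wavelengths) != p || any(is.na(wavelengths))) {
      wavelengths <- seq_len(p)
    }
  }
  cp <- .center_xprod(x, y)
  path <- .pls_path(cp$XtX, cp$Xty, ncomp)
  if (path$ncomp < ncomp) {
    if (path$ncomp == 0L) {
      warning("response or spectra have no usable variance; returning a ",
              "degenerate intercept-only model")
    } else {
      warning(sprintf(
        "rank supports only %d latent variable(s); fitted with %d instead of %d",
        path$ncomp, path$ncomp, ncomp))
    }
  }
  used <- max(path$ncomp, 1L)
  beta <- path$coefficients[, min(ncomp, max(path$ncomp, 1L))]
  if (path$ncomp == 0L) beta <- numeric(p)
  intercept <- cp$ybar - sum(beta * cp$xbar)
  fitted <- intercept + drop(x %*% beta)
  obj <- structure(
    list(coefficients = stats::setNames(beta, format(wavelengths, trim = TRUE, digits = 10)),
         intercept = intercept,
         wavelengths = wavelengths,
         ncomp = ncomp, ncomp_used = path$ncomp,
         projection = path$projection, y_loadings = path$y_loadings,
         x_loadings = path$loadings, weights = path$weights,
         x_mean = cp$xbar, y_mean = cp$ybar,
         fitted_values = fitted, residuals = y - fitted,
         n = n, p = p, call = match.call()),
    class = "plsr_fit"
  )
  obj
}

#' Predict from a fitted PLSR model
#'
#' Two numerically equivalent routes are available: the explicit linear
#' form (`intercept + X beta`) and the latent form (project onto the
#' score space, then apply the y-loadings). Their agreement is a model
#' invariant.
#'
#' @param object a [fit_plsr()] model.
#' @param newdata numeric matrix (or [spectra_table()]) with the model's
#'   wavelengths.
#' @param form `"linear"` or `"latent"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_fit <- function(object, newdata, form = c("linear", "latent"), ...) {
  form <- match.arg(form)
  if (inherits(newdata, "spectra_table")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop(sprintf("newdata has %d columns; model expects %d", ncol(newdata), object$p),
         call. = FALSE)
  }
  if (form == "linear") {
    object$intercept + drop(newdata %*% object$coefficients)
  } else {
    if (object$ncomp_used == 0L) return(rep(object$y_mean, nrow(newdata)))
    xc <- sweep(newdata, 2L, object$x_mean)
    scores <- xc %*% object$projection
    object$y_mean + drop(scores %*% object$y_loadings)
  }
}

#' @export
coef.plsr_fit <- function(object, intercept = FALSE, ...) {
  if (intercept) c("(Intercept)" = object$intercept, object$coefficients)
  else object$coefficients
}

#' @export
fitted.plsr_fit <- function(object, ...) object$fitted_values

#' @export
residuals.plsr_fit <- function(object, ...) object$residuals

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d samples, %d wavelengths, %d latent variable(s)\n",
              x$n, x$p, x$ncomp_used))
  ev <- evaluate_model(x, NULL, NULL, .self = TRUE)
  cat(sprintf("  calibration: R_C = %.4f, RMSEC = %.4f\n", ev$r, ev$rmse))
  invisible(x)
}

#' @export
summary.plsr_fit <- function(object, ...) {
  ev <- evaluate_model(object, NULL, NULL, .self = TRUE)
  out <- list(n = object$n, p = object$p, ncomp = object$ncomp_used,
              r_c = ev$r, rmsec = ev$rmse,
              coef_range = range(object$coefficients))
  class(out) <- "summary.plsr_fit"
  out
}

#' @export
print.summary.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR fit: n = %d, p = %d, latent variables = %d\n", x$n, x$p, x$ncomp))
  cat(sprintf("Calibration R_C = %.4f, RMSEC = %.4f\n", x$r_c, x$rmsec))
  cat(sprintf("Coefficient range: [%.4g, %.4g]\n", x$coef_range[1L], x$coef_range[2L]))
  invisible(x)
}

#' Leave-one-out cross-validation over latent-variable counts
#'
#' For each candidate number of latent variables, every sample is left out
#' in turn, the model is refit on the remainder and the held-out sample
#' predicted; the RMSECV curve over components is returned together with
#' the chosen count — the curve minimiser, ties resolved toward fewer
#' components. The per-fold refits reuse downdated cross-products, so the
#' full curve costs one Gram matrix plus `O(n * A * p^2)`.
#'
#' @param x spectra matrix or [spectra_table()].
#' @param y response vector (defaults to the table's TNC).
#' @param max_lvs largest component count to try (clipped to feasibility
#'   with a warning); default 20.
#' @return Object of class `"plsr_loocv"`: `ncomp`, `rmsecv` (curve),
#'   `cv_predictions` (`n x A`), `r_cv` per count.
#' @export
loocv_select_lvs <- function(x, y = NULL, max_lvs = 20) {
  if (inherits(x, "spectra_table")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("leave-one-out selection needs at least three samples", call. = FALSE)
  feasible <- min(n - 2L, p)
  if (max_lvs > feasible) {
    warning(sprintf("max_lvs reduced from %d to feasible maximum %d", max_lvs, feasible))
    max_lvs <- feasible
  }
  A <- as.integer(max_lvs)
  Sxx <- crossprod(x)
  sxy <- drop(crossprod(x, y))
  xsum <- colSums(x); ysum <- sum(y)
  preds <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    nt <- n - 1L
    xbar <- (xsum - xi) / nt
    ybar <- (ysum - y[i]) / nt
    XtX <- Sxx - tcrossprod(xi) - nt * tcrossprod(xbar)
    Xty <- sxy - xi * y[i] - nt * xbar * ybar
    path <- .pls_path(XtX, Xty, A)
    preds[i, ] <- ybar + drop((xi - xbar) %*% path$coefficients)
  }
  err <- y - preds
  rmsecv <- sqrt(colMeans(err^2))
  r_cv <- apply(preds, 2L, function(p_a) {
    if (stats::sd(p_a) == 0 || stats::sd(y) == 0) 0 else stats::cor(p_a, y)
  })
  ncomp <- which.min(rmsecv)  # first minimum = fewest components on ties
  structure(list(ncomp = ncomp, rmsecv = rmsecv, r_cv = r_cv,
                 cv_predictions = preds, max_lvs = A),
            class = "plsr_loocv")
}

#' @export
print.plsr_loocv <- function(x, ...) {
  cat(sprintf("<plsr_loocv> chosen latent variables: %d (RMSECV = %.4f)\n",
              x$ncomp, x$rmsecv[x$ncomp]))
  invisible(x)
}

#' Correlation / RMSE evaluation of a model on a sample set
#'
#' `R` is the Pearson correlation between predicted and measured values;
#' `RMSE` the root mean squared prediction error, in TNC %. If either
#' vector has zero variance the correlation is undefined and is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param model a [fit_plsr()] model.
#' @param x spectra matrix or [spectra_table()].
#' @param y measured values (defaults to the table's TNC).
#' @param set optional label (`"calibration"`, `"prediction"`, ...).
#' @param .self internal: evaluate on the training data stored in the fit.
#' @return List with `r`, `rmse`, `n`, `set`, `degenerate`.
#' @export
evaluate_model <- function(model, x, y = NULL, set = "calibration", .self = FALSE) {
  stopifnot(inherits(model, "plsr_fit"))
  if (.self) {
    pred <- model$fitted_values
    y <- pred + model$residuals
  } else {
    if (inherits(x, "spectra_table")) {
      if (is.null(y)) y <- x$y
      wl <- x$wavelengths
      if (length(wl) != length(model$wavelengths) ||
          !isTRUE(all.equal(wl, model$wavelengths))) {
        stop("wavelengths of 'x' do not match the model", call. = FALSE)
      }
      x <- x$x
    }
    pred <- predict(model, x)
    y <- as.numeric(y)
  }
  degenerate <- length(y) < 2L || stats::sd(pred) == 0 || stats::sd(y) == 0
  r <- if (degenerate) 0 else stats::cor(pred, y)
  list(r = r, rmse = sqrt(mean((pred - y)^2)), n = length(y), set = set,
       degenerate = degenerate)
}

#' Variable-elimination percentage
#'
#' Share of wavelengths removed when a full-spectrum model is reduced to
#' `k` selected wavelengths: `100 * (p_full - k) / p_full`.
#'
#' @param p_full number of wavelengths in the full model.
#' @param k number of selected wavelengths, `k < p_full`.
#' @return Percentage eliminated.
#' @examples
#' variable_elimination(460, 8)  # 98.26...
#' @export
variable_elimination <- function(p_full, k) {
  if (k >= p_full) stop("'k' must be smaller than 'p_full'", call. = FALSE)
  100 * (p_full - k) / p_full
}

.metric_triad <- function(x_cal, y_cal, x_pred, y_pred, max_lvs) {
  max_lvs <- min(max_lvs, ncol(x_cal), nrow(x_cal) - 2L)
  sel <- loocv_select_lvs(x_cal, y_cal, max_lvs = max_lvs)
  model <- fit_plsr(x_cal, y_cal, ncomp = sel$ncomp)
  cal <- evaluate_model(model, x_cal, y_cal, set = "calibration")
  cvp <- sel$cv_predictions[, sel$ncomp]
  cv_deg <- stats::sd(cvp) == 0 || stats::sd(y_cal) == 0
  prd <- evaluate_model(model, x_pred, y_pred, set = "prediction")
  list(model = model, lvs = sel$ncomp,
       r_c = cal$r, rmsec = cal$rmse,
       r_cv = if (cv_deg) 0 else stats::cor(cvp, y_cal),
       rmsecv = sel$rmsecv[sel$ncomp],
       r_p = prd$r, rmsep = prd$rmse)
}

#' Full-spectrum vs selected-wavelength PLSR comparison
#'
#' Fits the full-spectrum model (F-PLSR) and the model restricted to the
#' top-`k` wavelengths of a Random-frog ranking (RF-PLSR) on the
#' calibration set of an SPXY split, each with its own LOOCV-chosen
#' latent-variable count, and reports the R/RMSE triads on calibration,
#' cross-validation and prediction together with the variable-elimination
#' percentage.
#'
#' @param table a [spectra_table()].
#' @param split a [spxy_split()] of that table.
#' @param frog_result a [random_frog()] result on the same wavelengths.
#' @param k number of selected wavelengths for the reduced model.
#' @param max_lvs latent-variable cap for both models; default 20.
#' @param label optional target label (e.g. `"whole-plant"`).
#' @return Object of class `"plsr_comparison"`.
#' @export
full_vs_selected_report <- function(table, split, frog_result, k, max_lvs = 20,
                                    label = "whole-plant") {
  stopifnot(inherits(table, "spectra_table"), inherits(split, "spxy_split"))
  p_full <- length(table$wavelengths)
  if (k >= p_full) stop("'k' must be smaller than the number of wavelengths",
                        call. = FALSE)
  sel_wl <- rank_wavelengths(frog_result, k)
  wl_idx <- match(sel_wl, table$wavelengths)
  if (any(is.na(wl_idx))) {
    stop("selected wavelengths not present in the table grid", call. = FALSE)
  }
  cal <- subset_samples(table, split$calibration)
  prd <- subset_samples(table, split$prediction)
  full <- .metric_triad(cal$x, cal$y, prd$x, prd$y, max_lvs)
  red <- .metric_triad(cal$x[, wl_idx, drop = FALSE], cal$y,
                       prd$x[, wl_idx, drop = FALSE], prd$y, max_lvs)
  red$model$wavelengths <- table$wavelengths[wl_idx]
  structure(
    list(label = label,
         full = full[-1L], selected = red[-1L],
         full_model = full$model, selected_model = red$model,
         selected_wavelengths = table$wavelengths[wl_idx],
         n_full = p_full, k = k,
         elimination_percent = variable_elimination(p_full, k),
         n_cal = length(split$calibration), n_pred = length(split$prediction)),
    class = "plsr_comparison"
  )
}

#' @export
print.plsr_comparison <- function(x, ...) {
  cat(sprintf("PLSR comparison (%s): %d calibration / %d prediction samples\n",
              x$label, x$n_cal, x$n_pred))
  fmt <- function(nm, m, nvar) {
    sprintf("  %-8s N=%4d LVs=%2d  R_C=%.3f RMSEC=%.3f  R_CV=%.3f RMSECV=%.3f  R_P=%.3f RMSEP=%.3f",
            nm, nvar, m$lvs, m$r_c, m$rmsec, m$r_cv, m$rmsecv, m$r_p, m$rmsep)
  }
  cat(fmt("F-PLSR", x$full, x$n_full), "\n")
  cat(fmt("RF-PLSR", x$selected, x$k), "\n")
  cat(sprintf("  variable elimination: %.2f%% (%d -> %d wavelengths)\n",
              x$elimination_percent, x$n_full, x$k))
  invisible(x)
}
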