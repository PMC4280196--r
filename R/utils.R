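# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points route through this so that a
# user-level set.seed() is never silently consumed.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Configuration error naming the offending field.
.config_stop <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

.assert_scalar_number <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .config_stop(field, "must be a single finite number")
  }
  if (strict && x <= lower) .config_stop(field, sprintf("must be > %g", lower))
  if (!strict && x < lower) .config_stop(field, sprintf("must be >= %g", lower))
  invisible(x)
}

# Truncated-normal draws by inverse-CDF; exact and vectorised.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
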