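# Physical constants and small shared helpers.

#' Boltzmann constant in J/K
#' @noRd
.kB <- 1.380649e-23

#' Stop with a classed condition so callers/tests can match on error class
#' @noRd
nm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "nucmech_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Check a scalar is a finite number, optionally positive
#' @noRd
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    nm_stop(sprintf("'%s' must be a finite numeric scalar", name), "invalid_config")
  if (positive && x <= 0)
    nm_stop(sprintf("'%s' must be > 0", name), "invalid_config")
  if (nonneg && x < 0)
    nm_stop(sprintf("'%s' must be >= 0", name), "invalid_config")
  invisible(x)
}

#' Evaluate an expression under a local RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Standard error of the mean (sample sd / sqrt(n)); NA for n < 2
#' @noRd
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
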