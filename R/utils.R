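# Internal numerical and validation helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable.
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b > a) {
    # tolerate rounding when the difference is numerically zero
    if (b - a < 1e-9) return(-Inf)
    stop("logdiffexp: negative difference")
  }
  if (b == -Inf) return(a)
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

#' @keywords internal
stopf <- function(fmt, ..., class = "exburden_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @keywords internal
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single number in [0, 1]", name, class = "exburden_config_error")
  invisible(x)
}

#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min, class = "exburden_config_error")
  invisible(as.integer(x))
}

# Two-sided normal p from a z score.
#' @keywords internal
z2p <- function(z) 2 * stats::pnorm(-abs(z))
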