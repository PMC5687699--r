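# Small shared helpers.

#' Wrap angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map -pi back to +pi so the interval is half-open at the left
  w[w == -pi] <- pi
  w
}

# internal: stop with a call-free message
abort <- function(...) stop(..., call. = FALSE)

# internal: check a scalar is a single finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# internal: geometric mean
geomean <- function(x) exp(mean(log(x)))
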