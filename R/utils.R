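#' Wrap angles to the principal branch (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles congruent to `x` modulo 2*pi, each in `(-pi, pi]`.
#' @export
wrap_pi <- function(x) {
  w <- x %% (2 * pi)            # [0, 2*pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Circular mean of angles
#'
#' Mean direction on the unit circle: `atan2(mean(sin x), mean(cos x))`.
#' Returns 0 (with no warning) when the resultant length is numerically
#' zero, in which case the mean direction is undefined.
#'
#' @param x numeric vector of angles in radians.
#' @return mean direction in `(-pi, pi]`.
#' @export
circular_mean <- function(x) {
  s <- mean(sin(x))
  c <- mean(cos(x))
  if (sqrt(s^2 + c^2) < 1e-12) return(0)
  wrap_pi(atan2(s, c))
}

# stopifnot-style scalar checks with the offending field in the message
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("field '%s' must not be NULL", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("field '%s' must be a finite numeric scalar", name),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("field '%s' must be an integer", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("field '%s' = %g outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
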