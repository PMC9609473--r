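#' Construct a release curve
#'
#' A sampled dialysis release time series: times in hours and release
#' conversions xi in \[0, 1\], optionally tagged with the
#' [experiment_condition()] under which it was measured or simulated.
#'
#' @param times Sampling times in hours; strictly increasing, first
#'   >= 0, length >= 4.
#' @param xi Release conversions, same length as `times`, all in
#'   \[0, 1\].
#' @param condition Optional [experiment_condition()].
#' @return An object of class `release_curve`.
#' @examples
#' release_curve(c(0, 2, 4, 8), c(0, 0.02, 0.04, 0.06))
#' @export
release_curve <- function(times, xi, condition = NULL) {
  if (!is.numeric(times) || !is.numeric(xi))
    rk_stop("curve", "times and xi must be numeric")
  if (length(times) != length(xi))
    rk_stop("curve", "times and xi must have the same length")
  if (length(times) < 4L)
    rk_stop("curve", "a release curve needs at least 4 points, got ",
            length(times))
  if (any(!is.finite(times)) || any(!is.finite(xi)))
    rk_stop("curve", "times and xi must be finite")
  if (times[1] < 0) rk_stop("curve", "first time must be >= 0")
  bad <- which(diff(times) <= 0)
  if (length(bad))
    rk_stop("curve", "times must be strictly increasing; violation at row ",
            bad[1] + 1L)
  out <- which(xi < 0 | xi > 1)
  if (length(out))
    rk_stop("curve", "conversion outside [0, 1] at row ", out[1])
  if (!is.null(condition) && !inherits(condition, "experiment_condition"))
    rk_stop("curve", "condition must be an experiment_condition")
  structure(list(times = as.numeric(times), xi = as.numeric(xi),
                 condition = condition),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve: %d points over %g-%g h, xi in [%.4g, %.4g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$xi), max(x$xi)))
  if (!is.null(x$condition)) print(x$condition)
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(time_h = x$times, conversion = x$xi)
}

#' @export
length.release_curve <- function(x) length(x$times)

#' @export
plot.release_curve <- function(x, ...,
                               xlab = "time (h)", ylab = "conversion") {
  plot(x$times, x$xi, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
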