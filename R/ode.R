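#' Numerically integrate the reversible release rate equation
#'
#' Independent cross-check of the closed-form profile: integrates the
#' two-state system `dC_free/dt = k1 * C_bound - k_minus1 * C_free`,
#' `dC_bound/dt = -dC_free/dt`, from `C_free(0) = 0`,
#' `C_bound(0) = c_max`, with a stiff-capable solver (`deSolve::lsoda`).
#' Both pools are integrated independently so that mass conservation
#' `C_free + C_bound = c_max` is a genuine check on the integration, not
#' an identity.
#'
#' @param constants A [rate_constants()] object.
#' @param c_max Maximum free-drug concentration at complete release
#'   (> 0); any concentration unit, carried through.
#' @param times Output times in hours (>= 0, increasing).
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `time`, `c_free`, `c_bound`,
#'   `conversion`.
#' @examples
#' ode_release(rate_constants(0.0165, 0.153), 1, seq(0, 48, 4))
#' @export
ode_release <- function(constants, c_max, times, rtol = 1e-11,
                        atol = 1e-14) {
  stopifnot(inherits(constants, "rate_constants"))
  if (!is.numeric(c_max) || length(c_max) != 1L || c_max <= 0)
    rk_stop("ode", "c_max must be a single value > 0")
  if (any(times < 0)) rk_stop("ode", "negative times are not allowed")
  if (is.unsorted(times, strictly = FALSE))
    rk_stop("ode", "times must be non-decreasing")
  k1 <- constants$k1; km1 <- constants$k_minus1
  deriv <- function(t, y, p) {
    flux <- k1 * y[2] - km1 * y[1]
    list(c(flux, -flux))
  }
  # lsoda needs the initial time in the grid
  t0 <- times
  prepend <- FALSE
  if (length(t0) == 0L || t0[1] > 0) { t0 <- c(0, t0); prepend <- TRUE }
  sol <- deSolve::lsoda(c(c_free = 0, c_bound = c_max), t0, deriv, NULL,
                        rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    rk_stop("ode", "integrator failed (istate = ",
            attr(sol, "istate")[1], ")")
  if (any(!is.finite(sol[, "c_free"])))
    rk_stop("ode", "integrator returned non-finite concentrations")
  if (prepend) sol <- sol[-1, , drop = FALSE]
  data.frame(time = sol[, "time"], c_free = sol[, "c_free"],
             c_bound = sol[, "c_bound"],
             conversion = sol[, "c_free"] / c_max)
}
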