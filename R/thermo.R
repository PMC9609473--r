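#' Arrhenius analysis of a rate-constant temperature series
#'
#' Ordinary least squares of `ln k` on `1/T`; the activation energy is
#' `Ea = -slope * R` with R = 8.314 J mol-1 K-1. For the doxorubicin
#' system the release constant k1 is strongly activated (Ea about
#' 40.7 kJ/mol, kinetic control) while binding is nearly
#' temperature-independent (about 5.6 kJ/mol, diffusion control).
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct values).
#' @param k Rate constants, 1/h, all > 0, same length.
#' @return An object of class `arrhenius_fit`: `activation_energy`
#'   (J/mol), `ln_pre_exponential`, `r_squared`, `n_points`, `slope`.
#' @examples
#' arrhenius_fit(c(278, 298, 310, 323), c(2.80e-3, 1.27e-2, 1.65e-2, 3.52e-2))
#' @export
arrhenius_fit <- function(temperature, k) {
  if (length(temperature) != length(k))
    rk_stop("arrhenius", "temperature and k must have the same length")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    rk_stop("arrhenius", "temperatures must be positive (K)")
  if (any(!is.finite(k)) || any(k <= 0))
    rk_stop("arrhenius", "rate constants must all be > 0")
  if (length(unique(temperature)) < 2L)
    rk_stop("arrhenius", "need at least 2 distinct temperatures")
  x <- 1 / temperature
  y <- log(k)
  fit <- stats::lm(y ~ x)
  r2 <- r_squared_of(fit, y)
  structure(list(activation_energy = -unname(stats::coef(fit)[2]) * R_GAS,
                 ln_pre_exponential = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2, n_points = length(k),
                 temperature = temperature, k = k),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit (%d points): Ea = %.1f kJ/mol, ln A = %.3f, r^2 = %.4f\n",
    x$n_points, x$activation_energy / 1000, x$ln_pre_exponential,
    x$r_squared))
  invisible(x)
}

#' van't Hoff analysis of an equilibrium-constant temperature series
#'
#' Ordinary least squares of `ln K` on `1/T`; the standard enthalpy of
#' release is `dH = -slope * R`. Since `K = k1/k_minus1`, the van't Hoff
#' slope equals the difference of the two Arrhenius slopes.
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct).
#' @param K Equilibrium constants, all > 0.
#' @return An object of class `vant_hoff_fit`: `delta_H` (J/mol),
#'   `intercept`, `slope`, `r_squared`, `n_points`.
#' @examples
#' vant_hoff_fit(c(278, 298, 310, 323),
#'               c(2.80e-3, 1.27e-2, 1.65e-2, 3.52e-2) /
#'               c(0.119, 0.137, 0.153, 0.166))
#' @export
vant_hoff_fit <- function(temperature, K) {
  if (length(temperature) != length(K))
    rk_stop("vant_hoff", "temperature and K must have the same length")
  if (any(!is.finite(K)) || any(K <= 0))
    rk_stop("vant_hoff", "equilibrium constants must all be > 0")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    rk_stop("vant_hoff", "temperatures must be positive (K)")
  if (length(unique(temperature)) < 2L)
    rk_stop("vant_hoff", "need at least 2 distinct temperatures")
  x <- 1 / temperature
  y <- log(K)
  fit <- stats::lm(y ~ x)
  r2 <- r_squared_of(fit, y)
  structure(list(delta_H = -unname(stats::coef(fit)[2]) * R_GAS,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2, n_points = length(K),
                 temperature = temperature, K = K),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "van't Hoff fit (%d points): dH = %.1f kJ/mol, r^2 = %.4f\n",
    x$n_points, x$delta_H / 1000, x$r_squared))
  invisible(x)
}

#' Standard Gibbs energy of release
#'
#' `dG(T) = -R T ln K`; positive when K < 1, i.e. when the drug stays
#' mostly bound at equilibrium.
#'
#' @param K Release equilibrium constant(s), > 0.
#' @param temperature Temperature(s) in kelvin, > 0.
#' @return Gibbs energy in J/mol (vectorized).
#' @examples
#' gibbs_energy(1.27e-2 / 0.137, 298)  # about 5.9 kJ/mol
#' @export
gibbs_energy <- function(K, temperature) {
  if (any(!is.finite(K)) || any(K <= 0))
    rk_stop("gibbs", "K must be > 0")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    rk_stop("gibbs", "temperature must be > 0 (K)")
  -R_GAS * temperature * log(K)
}

#' Standard entropy of release
#'
#' `dS(T) = (dH - dG(T)) / T`, the Gibbs-Helmholtz rearrangement.
#'
#' @param delta_H Standard enthalpy, J/mol.
#' @param delta_G Standard Gibbs energy, J/mol.
#' @param temperature Temperature in kelvin, > 0.
#' @return Entropy in J mol-1 K-1 (vectorized).
#' @examples
#' entropy_change(35.2e3, 5.9e3, 298)  # about 98 J/mol/K
#' @export
entropy_change <- function(delta_H, delta_G, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    rk_stop("entropy", "temperature must be > 0 (K)")
  (delta_H - delta_G) / temperature
}

#' Full thermodynamic report from matched rate-constant series
#'
#' Given k1 and k-1 measured on the same temperature grid, builds
#' `K(T) = k1/k_minus1`, fits both Arrhenius lines and the van't Hoff
#' line, and evaluates `dG(T) = -RT ln K` and `dS(T) = (dH - dG)/T` at
#' every grid temperature. The Gibbs-Helmholtz identity
#' `dG = dH - T dS` is asserted on construction. Note that with a single
#' van't Hoff enthalpy, `dS(T)` is constant across the grid by
#' construction; it is still tabulated per temperature for reporting.
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct).
#' @param k1 Release rate constants, 1/h, > 0, matching `temperature`.
#' @param k_minus1 Binding rate constants, 1/h, > 0, matching grid.
#' @return An object of class `thermo_report`: `arrhenius_release`,
#'   `arrhenius_binding`, `vant_hoff`, and a `table` with columns
#'   `temperature`, `k1`, `k_minus1`, `K`, `delta_G`, `delta_S` (J
#'   units).
#' @examples
#' thermo_report(c(278, 298, 310, 323),
#'               c(2.80e-3, 1.27e-2, 1.65e-2, 3.52e-2),
#'               c(0.119, 0.137, 0.153, 0.166))
#' @export
thermo_report <- function(temperature, k1, k_minus1) {
  if (length(k1) != length(temperature) ||
      length(k_minus1) != length(temperature))
    rk_stop("thermo", "k1 and k_minus1 must match the temperature grid")
  if (length(unique(temperature)) < 2L)
    rk_stop("thermo", "need at least 2 distinct temperatures for dH")
  arr1 <- arrhenius_fit(temperature, k1)
  arr2 <- arrhenius_fit(temperature, k_minus1)
  K <- k1 / k_minus1
  vh <- vant_hoff_fit(temperature, K)
  dG <- gibbs_energy(K, temperature)
  dS <- entropy_change(vh$delta_H, dG, temperature)
  # Gibbs-Helmholtz identity must close to numerical precision
  gap <- abs(dG - (vh$delta_H - temperature * dS))
  if (any(gap > 1e-6 * max(abs(vh$delta_H), 1)))
    rk_stop("thermo", "internal inconsistency: dG != dH - T dS")
  tab <- data.frame(temperature = temperature, k1 = k1,
                    k_minus1 = k_minus1, K = K, delta_G = dG,
                    delta_S = dS)
  structure(list(arrhenius_release = arr1, arrhenius_binding = arr2,
                 vant_hoff = vh, table = tab),
            class = "thermo_report")
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("Thermodynamics of reversible drug release\n")
  cat("  release  : "); print(x$arrhenius_release)
  cat("  binding  : "); print(x$arrhenius_binding)
  cat("  van't Hoff: "); print(x$vant_hoff)
  tab <- x$table
  tab$delta_G <- round(tab$delta_G / 1000, 1)   # kJ/mol
  tab$delta_S <- round(tab$delta_S, 1)          # J/mol/K
  names(tab)[names(tab) == "delta_G"] <- "dG_kJ_mol"
  names(tab)[names(tab) == "delta_S"] <- "dS_J_mol_K"
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.thermo_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  tT <- x$table$temperature
  invT <- 1 / tT
  plot(invT, log(x$table$k1), xlab = "1/T (1/K)", ylab = "ln k",
       ylim = range(log(c(x$table$k1, x$table$k_minus1))),
       main = "Arrhenius", ...)
  graphics::points(invT, log(x$table$k_minus1), pch = 2)
  graphics::abline(x$arrhenius_release$ln_pre_exponential,
                   x$arrhenius_release$slope)
  graphics::abline(x$arrhenius_binding$ln_pre_exponential,
                   x$arrhenius_binding$slope, lty = 2)
  plot(invT, log(x$table$K), xlab = "1/T (1/K)", ylab = "ln K",
       main = "van't Hoff", ...)
  graphics::abline(x$vant_hoff$intercept, x$vant_hoff$slope)
  plot(tT, x$table$delta_G / 1000, xlab = "T (K)",
       ylab = "dG (kJ/mol)", main = "Gibbs energy", ...)
  invisible(x)
}
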