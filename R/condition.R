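#' Describe one release experiment
#'
#' Bundles the controlled variables of a single dialysis release
#' experiment: temperature, pH, the mole fraction of acrylic-acid
#' residues in the copolymer chain, the copolymer mass concentration and
#' the initial drug load.
#'
#' @param temperature Temperature in kelvin (> 0).
#' @param pH pH of the buffer, in \[0, 14\].
#' @param x_aa Mole fraction of acrylic-acid residues in the copolymer
#'   chain, in \[0, 1\].
#' @param copolymer_conc Copolymer mass concentration in g/mL (>= 0).
#' @param drug_load Initial doxorubicin hydrochloride concentration in
#'   g/mL (> 0).
#' @param label Free-text label for the experiment.
#'
#' @return An object of class `experiment_condition`.
#' @examples
#' experiment_condition(310, 7, 0.039, 1e-2)
#' @export
experiment_condition <- function(temperature, pH = 7, x_aa = 0,
                                 copolymer_conc = 0, drug_load = 2e-4,
                                 label = "") {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    rk_stop("condition", "temperature must be a single positive value (K)")
  if (!is.numeric(pH) || pH < 0 || pH > 14)
    rk_stop("condition", "pH must lie in [0, 14]")
  if (!is.numeric(x_aa) || x_aa < 0 || x_aa > 1)
    rk_stop("condition", "x_aa must be a mole fraction in [0, 1]")
  if (!is.numeric(copolymer_conc) || copolymer_conc < 0)
    rk_stop("condition", "copolymer_conc must be >= 0 (g/mL)")
  if (!is.numeric(drug_load) || drug_load <= 0)
    rk_stop("condition", "drug_load must be > 0 (g/mL)")
  structure(
    list(temperature = as.numeric(temperature), pH = as.numeric(pH),
         x_aa = as.numeric(x_aa),
         copolymer_conc = as.numeric(copolymer_conc),
         drug_load = as.numeric(drug_load), label = as.character(label)),
    class = "experiment_condition")
}

#' @export
print.experiment_condition <- function(x, ...) {
  cat("Release experiment condition",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat(sprintf("  T = %g K, pH = %g, x(AA) = %g, copolymer %g g/mL\n",
              x$temperature, x$pH, x$x_aa, x$copolymer_conc))
  invisible(x)
}

#' Concentration of carboxyl groups in the system
#'
#' Converts the copolymer mass concentration into the molar concentration
#' of acrylic-acid carboxyl groups, C_COOH, which normalises the
#' pseudo-first-order binding constant (see
#' [normalized_binding_constant()]).
#'
#' The chain is treated as `x_aa` acrylic-acid units (72.06 g/mol) and
#' `1 - x_aa` N-vinyl-2-pyrrolidone units (111.14 g/mol); end groups are
#' neglected. Then
#' `C_COOH = 1000 * copolymer_conc / (x_aa*M_AA + (1-x_aa)*M_VP) * x_aa`
#' in mol/L. This convention is the package's own; it rescales only the
#' normalised binding constant, never k1, k-1 or K.
#'
#' @param condition An [experiment_condition()].
#' @return C_COOH in mol/L.
#' @examples
#' cooh_concentration(experiment_condition(310, 7, 0.039, 1e-2))
#' @export
cooh_concentration <- function(condition) {
  stopifnot(inherits(condition, "experiment_condition"))
  x <- condition$x_aa
  if (x == 0) return(0)
  mean_mass <- x * M_AA + (1 - x) * M_VP
  1000 * condition$copolymer_conc / mean_mass * x
}
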