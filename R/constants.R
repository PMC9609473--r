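# Physical constants and unit conventions used throughout.
# Time is in hours, rate constants in 1/h, energies in J/mol,
# concentrations in mol/L unless a function documents otherwise.

#' Gas constant (J mol-1 K-1)
#'
#' The molar gas constant used for all Arrhenius, van't Hoff and Gibbs
#' energy computations, R = 8.314 J mol-1 K-1.
#' @export
R_GAS <- 8.314

# Repeat-unit molar masses (g/mol) for the amphiphilic copolymer:
# acrylic acid (AA) and N-vinyl-2-pyrrolidone (VP). End groups are
# neglected when converting a mass concentration to mol of repeat units.
M_AA <- 72.06
M_VP <- 111.14

# internal: stage-tagged error so pipeline failures name their origin
rk_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# internal: coefficient of determination without summary.lm (which
# warns on exact fits); SST of 0 counts as a perfect fit
r_squared_of <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
}

# internal: run expr with a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
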