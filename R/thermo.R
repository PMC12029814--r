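#' Gas constant in cal/(mol K)
#'
#' CODATA value expressed in the calorie-based unit convention used
#' throughout calorimetry software.
#' @export
R_CAL <- 1.98720425

#' Gibbs energy of association from the binding constant
#'
#' \deqn{\Delta G = -R T \ln K}
#' with R in cal/(mol K) and the result expressed in kcal/mol.
#'
#' @param K Association constant (L/mol), > 0.
#' @param temperature Absolute temperature (K), default 298.15.
#' @return \eqn{\Delta G} in kcal/mol (negative for K > 1: spontaneous
#'   association).
#' @examples
#' gibbs_from_K(1096, 298.15)  # about -4.14 kcal/mol
#' @export
gibbs_from_K <- function(K, temperature = 298.15) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("K must be positive for ln(K)")
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  -R_CAL * temperature * log(K) / 1000
}

#' Association constant back from Gibbs energy
#'
#' Inverse of [gibbs_from_K()]; used for round-trip checks.
#' @param dG Gibbs energy (kcal/mol).
#' @param temperature Absolute temperature (K).
#' @return K (L/mol).
#' @export
K_from_gibbs <- function(dG, temperature = 298.15) {
  exp(-1000 * dG / (R_CAL * temperature))
}

#' Entropy change from the thermodynamic linkage
#'
#' \deqn{\Delta S = (\Delta H - \Delta G) / T,}
#' inputs in kcal/mol, result in cal/(mol K).
#'
#' @param dH Enthalpy change (kcal/mol).
#' @param dG Gibbs energy change (kcal/mol).
#' @param temperature Absolute temperature (K), > 0.
#' @return \eqn{\Delta S} in cal/(mol K).
#' @examples
#' entropy_from_linkage(-1.013, -4.144, 298.15)  # about +10.5
#' @export
entropy_from_linkage <- function(dH, dG, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  1000 * (dH - dG) / temperature
}

#' Assemble a full thermodynamic result from K and dH
#'
#' @param K Association constant (L/mol).
#' @param dH Enthalpy change (kcal/mol).
#' @param temperature Absolute temperature (K).
#' @return A list of class `thermo_result` with `K`, `dG`, `dH` (kcal/mol),
#'   `dS` (cal/(mol K)), `temperature` and the gas constant used.
#' @export
thermo_result <- function(K, dH, temperature = 298.15) {
  dG <- gibbs_from_K(K, temperature)
  structure(
    list(K = K, dG = dG, dH = dH,
         dS = entropy_from_linkage(dH, dG, temperature),
         temperature = temperature, R_const = R_CAL),
    class = "thermo_result")
}

#' Internal-consistency check of a thermodynamic result
#'
#' Verifies both linkage identities,
#' \eqn{\Delta G = -RT\ln K} and \eqn{\Delta G = \Delta H - T \Delta S},
#' within a tolerance in kcal/mol. Useful for validating values transcribed
#' from reports that were rounded independently.
#'
#' @param result A `thermo_result` (or a list with fields `K`, `dG`, `dH`,
#'   `dS`, `temperature`).
#' @param tol_kcal Tolerance on each identity (kcal/mol), default 0.01.
#' @return A list with per-identity residuals (kcal/mol) and pass flags,
#'   plus an overall `pass`.
#' @export
check_consistency <- function(result, tol_kcal = 0.01) {
  res_K <- result$dG - gibbs_from_K(result$K, result$temperature)
  res_S <- result$dG - (result$dH - result$temperature * result$dS / 1000)
  out <- list(
    residual_gibbs_vs_K = res_K,
    residual_gibbs_vs_HS = res_S,
    pass_gibbs_vs_K = abs(res_K) <= tol_kcal,
    pass_gibbs_vs_HS = abs(res_S) <= tol_kcal,
    tol_kcal = tol_kcal)
  out$pass <- out$pass_gibbs_vs_K && out$pass_gibbs_vs_HS
  out
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "K = %.4g L/mol at T = %.2f K\n  dG = %+.3f kcal/mol\n  dH = %+.3f kcal/mol\n  dS = %+.2f cal/(mol K)\n",
    x$K, x$temperature, x$dG, x$dH, x$dS))
  invisible(x)
}
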