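#' Exact 1:1 complexation equilibrium
#'
#' For the association equilibrium H + G <-> HG with association constant
#' \eqn{K = [HG] / ([H][G])} (L/mol), the complex concentration at totals
#' \eqn{A} (guest) and \eqn{B} (host) is the smaller root of
#' \deqn{x^2 - (A + B + 1/K)\,x + AB = 0,}
#' i.e. \eqn{x = \tfrac12\left[(A+B+1/K) - \sqrt{(A+B+1/K)^2 - 4AB}\right]}.
#' This is the exact mass-action solution with no fast-ligand or excess-host
#' approximation. The implementation uses the conjugate (multiply-through)
#' form \eqn{x = 2AB / (b + \sqrt{b^2 - 4AB})} with \eqn{b = A + B + 1/K},
#' which avoids subtractive cancellation when \eqn{4AB \ll b^2} (weak binding
#' or dilute solutions).
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param A_total Total guest concentration (mol/L), >= 0.
#' @param B_total Total host concentration (mol/L), >= 0.
#' @param K Association constant (L/mol), >= 0. `K = 0` returns 0 by
#'   continuity (the no-binding limit).
#' @return Complex concentration \eqn{[HG]} in mol/L, bounded by
#'   `min(A_total, B_total)`.
#' @examples
#' complex_concentration(2e-3, 2e-3, 81.97)
#' complex_concentration(1e-3, 3e-3, 1e12)  # saturation: ~ 1e-3
#' @export
complex_concentration <- function(A_total, B_total, K) {
  n <- max(length(A_total), length(B_total), length(K))
  A <- rep_len(as.numeric(A_total), n)
  B <- rep_len(as.numeric(B_total), n)
  K <- rep_len(as.numeric(K), n)
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("concentrations must be finite")
  if (any(A < 0) || any(B < 0))
    stop("total concentrations must be non-negative")
  if (any(K < 0))
    stop("association constant K must be non-negative")
  x <- numeric(n)
  ok <- K > 0 & A > 0 & B > 0
  if (any(ok)) {
    b <- A[ok] + B[ok] + 1 / K[ok]
    disc <- b * b - 4 * A[ok] * B[ok]
    # disc >= (A - B)^2 + ... > 0 algebraically; clamp against rounding
    disc[disc < 0] <- 0
    x[ok] <- 2 * A[ok] * B[ok] / (b + sqrt(disc))
  }
  pmin(x, pmin(A, B))
}

#' Predicted fast-exchange chemical-shift perturbation
#'
#' Under fast exchange the observed shift of a proton is the
#' population-weighted average of its free and complexed shifts, so the
#' perturbation relative to the free state is
#' \deqn{\Delta\delta_{i,j} = \Delta\delta_c(j) \cdot [HG]_i / X_i,}
#' where \eqn{X} is the total concentration of the molecule the proton
#' belongs to (guest total \eqn{A} or host total \eqn{B}) and
#' \eqn{\Delta\delta_c(j)} is the signed limiting shift difference between
#' the free component and the pure inclusion complex.
#'
#' @param A_total,B_total,K Equilibrium inputs as in
#'   [complex_concentration()].
#' @param delta_c Limiting complexation shift \eqn{\Delta\delta_c} (ppm,
#'   signed).
#' @param molecule `"guest"` or `"host"`: selects which total concentration
#'   normalizes the bound fraction.
#' @return Predicted \eqn{\Delta\delta} (ppm), same sign as `delta_c` and
#'   bounded by it in magnitude.
#' @export
predicted_shift_perturbation <- function(A_total, B_total, K, delta_c,
                                         molecule = c("guest", "host")) {
  molecule <- match.arg(molecule)
  hg <- complex_concentration(A_total, B_total, K)
  X <- if (molecule == "guest") A_total else B_total
  if (any(X <= 0))
    stop("total concentration of the proton's molecule must be positive")
  delta_c * hg / X
}

#' Shift perturbation from observed and free-state shifts
#'
#' Sign convention: \eqn{\Delta\delta = \delta_{free} - \delta_{obs}}.
#' A positive value means the resonance moved upfield on complexation;
#' interpretation is left to the caller.
#'
#' @param delta_free Free-state chemical shift (ppm).
#' @param delta_obs Observed chemical shift in the mixture (ppm).
#' @return \eqn{\Delta\delta} (ppm), signed.
#' @export
shift_perturbation_from_observed <- function(delta_free, delta_obs) {
  if (any(!is.finite(delta_free)) || any(!is.finite(delta_obs)))
    stop("chemical shifts must be finite")
  delta_free - delta_obs
}

#' Proton assignment table constructor
#'
#' Builds the per-proton metadata consumed by the continuous-variation
#' generator and fitter: which molecule each traced proton belongs to, its
#' free-state shift, and (for simulation) its limiting complexation shift.
#'
#' @param proton_id Character vector of unique proton labels (e.g. `"H3"`,
#'   `"Hd"`).
#' @param molecule `"guest"` or `"host"` per proton.
#' @param delta_free Free-state shift (ppm) per proton.
#' @param delta_c Limiting complexation shift (ppm, signed) per proton;
#'   `NA` where unknown (fitting estimates it).
#' @return A `data.frame` with one row per proton.
#' @export
proton_assignments <- function(proton_id, molecule, delta_free,
                               delta_c = NA_real_) {
  proton_id <- as.character(proton_id)
  if (anyDuplicated(proton_id))
    stop("proton_id labels must be unique within an assignment set")
  molecule <- match.arg(molecule, c("guest", "host"), several.ok = TRUE)
  molecule <- rep_len(molecule, length(proton_id))
  stopifnot(length(delta_free) == length(proton_id))
  data.frame(
    proton_id = proton_id,
    molecule = molecule,
    delta_free = as.numeric(delta_free),
    delta_c = rep_len(as.numeric(delta_c), length(proton_id)),
    stringsAsFactors = FALSE
  )
}
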