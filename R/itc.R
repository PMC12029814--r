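#' ITC experimental design
#'
#' Describes a titration: an overfilled perfusion cell of volume `cell_volume`
#' initially holding the host (macromolecule) at `cell_conc`, titrated with
#' guest (ligand) at `syringe_conc` over a schedule of injections.
#'
#' @param cell_volume Active cell volume (L). Default 1.0 mL, typical for
#'   low-volume perfusion calorimeters.
#' @param cell_conc Initial host concentration in the cell (mol/L).
#' @param syringe_conc Guest concentration in the syringe (mol/L).
#' @param injection_volumes Vector of injection volumes (L), length >= 2.
#' @param temperature Absolute temperature (K).
#' @param spacing Injection spacing (s); metadata only.
#' @return A list of class `itc_design`.
#' @examples
#' itc_design()  # 0.75 mM host, 3 mM guest, 25 x 10 uL at 25 C
#' @export
itc_design <- function(cell_volume = 1e-3,
                       cell_conc = 0.75e-3,
                       syringe_conc = 3e-3,
                       injection_volumes = rep(10e-6, 25L),
                       temperature = 298.15,
                       spacing = 300) {
  if (cell_volume <= 0 || any(injection_volumes <= 0))
    stop("volumes must be positive")
  if (cell_conc <= 0 || syringe_conc <= 0)
    stop("concentrations must be positive")
  if (length(injection_volumes) < 2L)
    stop("an ITC design needs at least 2 injections")
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature, spacing = spacing),
    class = "itc_design")
}

# Per-injection cell bookkeeping for an overfilled perfusion cell: each
# injection of volume dV expels an equal volume of (pre-mixing) cell
# contents, diluting what was there by the symmetric factor
# (1 - dV/2V0)/(1 + dV/2V0); the injected material adds syringe_conc*dV/V0.
# With displacement = FALSE, contents are only diluted by the added titrant
# being ignored volumetrically (the simple 'no-expulsion' oracle variant).
.itc_concentration_series <- function(design, displacement = TRUE) {
  V0 <- design$cell_volume
  nk <- length(design$injection_volumes)
  M <- X <- fac <- numeric(nk)
  m_prev <- design$cell_conc
  x_prev <- 0
  for (k in seq_len(nk)) {
    dV <- design$injection_volumes[k]
    f <- if (displacement) (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)) else 1
    M[k] <- m_prev * f
    X[k] <- x_prev * f + design$syringe_conc * dV / V0
    fac[k] <- f
    m_prev <- M[k]
    x_prev <- X[k]
  }
  list(M = M, X = X, dilution = fac)
}

#' Simulate an ITC thermogram under the independent-sites model
#'
#' Forward model for a single set of n identical, independent sites: after
#' each injection the total cell concentrations of host \eqn{M_k} and guest
#' \eqn{X_k} are updated with perfusion-cell displacement (the injected
#' volume expels cell liquid; the symmetric overfilled-cell factor
#' \eqn{(1 - dV/2V_0)/(1 + dV/2V_0)} is applied to the pre-injection
#' contents), the 1:1 equilibrium is solved with effective site
#' concentration \eqn{n M_k}, and the injection heat is
#' \deqn{q_k = \Delta H \cdot V_0 \cdot
#'   (\mathrm{bound}_k - f_k\,\mathrm{bound}_{k-1}),}
#' where \eqn{f_k} corrects the previously bound material for displacement.
#' Heats are in calories (exothermic negative when \eqn{\Delta H < 0}).
#'
#' @param K Association constant (L/mol).
#' @param n Site number (host:guest stoichiometry), > 0.
#' @param dH Molar binding enthalpy (cal/mol).
#' @param design An [itc_design()].
#' @param displacement If `FALSE`, disable the expulsion correction (used
#'   by oracle cross-checks where exact heat conservation holds).
#' @param max_injected_fraction Warn when the cumulative injected volume
#'   exceeds this fraction of the cell volume (default 0.3).
#' @return A `data.frame` of class `thermogram` with columns `injection`,
#'   `volume_L`, `heat_cal`, `molar_ratio` (total guest / total host in the
#'   cell after the injection); the design is attached as an attribute.
#' @export
simulate_thermogram <- function(K, n, dH, design = itc_design(),
                                displacement = TRUE,
                                max_injected_fraction = 0.3) {
  stopifnot(inherits(design, "itc_design"))
  if (K < 0 || n <= 0) stop("require K >= 0 and n > 0")
  tot <- sum(design$injection_volumes)
  if (tot > max_injected_fraction * design$cell_volume)
    warning(sprintf(
      "cumulative injected volume (%.0f uL) exceeds %.0f%% of the cell volume",
      tot * 1e6, 100 * max_injected_fraction))
  cs <- .itc_concentration_series(design, displacement)
  bound <- complex_concentration(cs$X, n * cs$M, K)
  bound_prev <- c(0, bound[-length(bound)])
  q <- dH * design$cell_volume * (bound - cs$dilution * bound_prev)
  out <- data.frame(
    injection = seq_along(q),
    volume_L = design$injection_volumes,
    heat_cal = q,
    molar_ratio = cs$X / cs$M)
  class(out) <- c("thermogram", "data.frame")
  attr(out, "design") <- design
  out
}

#' Subtract a control (blank) titration
#'
#' Dilution heats measured by titrating the guest into solvent alone are
#' removed by elementwise subtraction; molar ratios are kept from the
#' sample run.
#'
#' @param sample,control Thermograms with equal injection counts.
#' @return The corrected thermogram.
#' @export
blank_subtract <- function(sample, control) {
  if (nrow(sample) != nrow(control))
    stop("sample and control have different injection counts (",
         nrow(sample), " vs ", nrow(control), ")")
  sample$heat_cal <- sample$heat_cal - control$heat_cal
  sample
}

# Variable projection inner stage: dH enters the forward model linearly,
# so at fixed (K, n) the optimal dH and the residual SSR are closed-form.
.itc_inner_fit <- function(q, K, n, design, displacement) {
  w <- simulate_thermogram(K, n, 1, design, displacement,
                           max_injected_fraction = Inf)$heat_cal
  ww <- sum(w * w)
  if (ww <= 0) return(list(dH = 0, ssr = sum(q^2), fitted = rep(0, length(q))))
  dH <- sum(w * q) / ww
  fitted <- dH * w
  list(dH = dH, ssr = sum((q - fitted)^2), fitted = fitted)
}

#' Fit the independent-sites model to an ITC thermogram
#'
#' Least-squares fit of (K, n, dH) to per-injection heats, using the same
#' forward model as [simulate_thermogram()]. dH is profiled out exactly
#' (it enters the model linearly); the remaining search over
#' \eqn{(\log_{10} K, n)} starts from a coarse grid and is polished by
#' Nelder-Mead. With `fix_n`, only \eqn{\log_{10} K} is searched.
#'
#' The Wiseman parameter \eqn{c = n K M_0} is always reported: for
#' \eqn{c \lesssim 1} the isotherm is shallow and K and n are weakly
#' identified (a warning is attached rather than hidden), which is the
#' regime of many cyclodextrin complexes.
#'
#' @param thermogram A `thermogram` (column `heat_cal`), e.g. from
#'   [simulate_thermogram()] or [read_thermogram()], after any
#'   [blank_subtract()].
#' @param design The [itc_design()] the heats were measured under.
#' @param fix_n Optional fixed site number; `NULL` (default) fits n.
#' @param discard_first Drop injection 1 before fitting (common practice
#'   for syringe-diffusion artifacts); default `FALSE`.
#' @param displacement Displacement convention passed to the forward model.
#' @param log10K_range Search range for \eqn{\log_{10} K}.
#' @return A list of class `itc_fit`: `K` (L/mol), `n`, `dH` (cal/mol),
#'   `thermo` (a [thermo_result()] at the design temperature, dH in
#'   kcal/mol), `c_parameter`, `identifiability_warning`, `ssr`, `fitted`,
#'   `residuals`, `converged`.
#' @export
fit_independent_model <- function(thermogram, design, fix_n = NULL,
                                  discard_first = FALSE,
                                  displacement = TRUE,
                                  log10K_range = c(-1, 8)) {
  stopifnot(inherits(design, "itc_design"))
  q_full <- thermogram$heat_cal
  keep <- seq_along(q_full)
  if (discard_first) keep <- keep[-1L]
  if (length(keep) < 5L) stop("need at least 5 usable injections")
  if (all(abs(q_full[keep]) < 1e-15))
    stop("flat thermogram: binding parameters are unidentifiable")

  # objective on the full schedule (the forward model is sequential), with
  # residuals restricted to the kept injections
  obj_fit <- function(K, n) {
    w <- simulate_thermogram(K, n, 1, design, displacement,
                             max_injected_fraction = Inf)$heat_cal
    w <- w[keep]; q <- q_full[keep]
    ww <- sum(w * w)
    dH <- if (ww > 0) sum(w * q) / ww else 0
    list(dH = dH, ssr = sum((q - dH * w)^2), fitted = dH * w)
  }

  if (is.null(fix_n)) {
    grid <- expand.grid(lk = seq(log10K_range[1], log10K_range[2], by = 0.5),
                        n = c(0.25, 0.5, 1, 2, 4))
    ssr0 <- mapply(function(lk, n) obj_fit(10^lk, n)$ssr, grid$lk, grid$n)
    start <- unlist(grid[which.min(ssr0), ])
    opt <- stats::optim(
      start,
      function(p) {
        if (p[2] <= 0) return(1e30)
        obj_fit(10^p[1], p[2])$ssr
      },
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000))
    K <- 10^opt$par[1]; n <- opt$par[2]
    converged <- opt$convergence == 0
  } else {
    if (fix_n <= 0) stop("fix_n must be positive")
    lks <- seq(log10K_range[1], log10K_range[2], by = 0.25)
    ssr0 <- vapply(lks, function(lk) obj_fit(10^lk, fix_n)$ssr, numeric(1))
    i0 <- which.min(ssr0)
    lo <- lks[max(1L, i0 - 1L)]; hi <- lks[min(length(lks), i0 + 1L)]
    opt <- stats::optimize(function(lk) obj_fit(10^lk, fix_n)$ssr,
                           c(lo, hi), tol = 1e-12)
    K <- 10^opt$minimum; n <- fix_n
    converged <- TRUE
  }

  best <- obj_fit(K, n)
  c_par <- n * K * design$cell_conc
  warn <- if (c_par < 0.01 || c_par > 1e4) {
    sprintf(paste0("Wiseman c = %.3g lies outside [0.01, 1e4]; ",
                   "K and n are poorly identified at this design"), c_par)
  } else if (c_par < 1) {
    sprintf(paste0("low-c regime (c = %.3g < 1): the isotherm is shallow ",
                   "and K/n estimates may be strongly correlated"), c_par)
  } else NULL

  structure(
    list(K = K, n = n, dH = best$dH,
         thermo = thermo_result(K, best$dH / 1000, design$temperature),
         c_parameter = c_par, identifiability_warning = warn,
         ssr = best$ssr, fitted = best$fitted,
         residuals = q_full[keep] - best$fitted,
         injections_used = keep, converged = converged),
    class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("independent-sites ITC fit\n")
  cat(sprintf("  K  = %.4g L/mol\n  n  = %.3f\n  dH = %.1f cal/mol (%.3f kcal/mol)\n",
              x$K, x$n, x$dH, x$dH / 1000))
  cat(sprintf("  dG = %+.3f kcal/mol, dS = %+.2f cal/(mol K) at %.2f K\n",
              x$thermo$dG, x$thermo$dS, x$thermo$temperature))
  cat(sprintf("  Wiseman c = %.3g\n", x$c_parameter))
  if (!is.null(x$identifiability_warning))
    cat("  note:", x$identifiability_warning, "\n")
  invisible(x)
}
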