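#' Default free-state chemical shifts (ppm)
#'
#' Guest (an ethyl-thiazolylidene hydroxybenzohydrazide, protons Ha-Hh,
#' assigned in D2O at 500 MHz) and host (beta-cyclodextrin cavity protons
#' H3 and H5) free-state shifts used by the synthetic generator. The guest
#' values are the published free-state assignments; the host values are
#' literature-typical for beta-CD in D2O.
#'
#' @return Named numeric vector of shifts (ppm).
#' @export
cv_free_shifts <- function() {
  c(Ha = 6.97, Hb = 7.79, Hc = 6.88, Hd = 6.96, He = 6.98, Hf = 6.90,
    Hg = 1.24, Hh = 4.00,            # guest, free state
    H3 = 3.94, H5 = 3.83)            # host (beta-CD cavity), free state
}

#' Default limiting complexation shifts (ppm, signed)
#'
#' Plausible magnitudes (0.01-0.1 ppm) for beta-CD inclusion, with the
#' host cavity protons (H3, H5) shifted in the opposite sense to the guest
#' aromatics. These are generator configuration, not measured values, and
#' every analysis that depends on them takes them explicitly.
#'
#' @return Named numeric vector of \eqn{\Delta\delta_c} (ppm).
#' @export
cv_default_delta_c <- function() {
  c(Hd = -0.030, He = -0.045, Hf = -0.020,  # guest aromatics
    H3 = 0.060, H5 = 0.090)                 # host cavity protons
}

#' Ground truth for a synthetic continuous-variation experiment
#'
#' @param K True association constant (L/mol). Default 81.97, a typical
#'   weak cyclodextrin association constant.
#' @param protons Proton labels to trace; the default set spans both
#'   molecules (guest aromatics Hd, He, Hf and host cavity H3, H5).
#' @param delta_c Named limiting shifts (ppm) covering `protons`.
#' @param delta_free Named free-state shifts (ppm) covering `protons`.
#' @param noise_sd Gaussian noise SD on observed shifts (ppm); 0 = exact.
#' @param seed RNG seed used by [generate_cv_table()].
#' @return A list of class `cv_truth`.
#' @export
cv_ground_truth <- function(K = 81.97,
                            protons = c("Hd", "He", "Hf", "H3", "H5"),
                            delta_c = cv_default_delta_c(),
                            delta_free = cv_free_shifts(),
                            noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  missing_dc <- setdiff(protons, names(delta_c))
  if (length(missing_dc))
    stop("delta_c missing for: ", paste(missing_dc, collapse = ", "))
  missing_df <- setdiff(protons, names(delta_free))
  if (length(missing_df))
    stop("delta_free missing for: ", paste(missing_df, collapse = ", "))
  structure(
    list(K = K, protons = protons,
         delta_c = delta_c[protons], delta_free = delta_free[protons],
         molecule = ifelse(grepl("^H[0-9]", protons), "host", "guest"),
         noise_sd = noise_sd, seed = seed),
    class = "cv_truth")
}

#' Generate a synthetic continuous-variation shift table
#'
#' Forward-simulates observed shifts under the exact 1:1 fast-exchange
#' model: \eqn{\delta_{obs}(i,j) = \delta_{free}(j) - \Delta\delta(i,j) +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, seeded and reproducible.
#' With `noise_sd = 0` the table is exact and the fitter round-trips the
#' true K.
#'
#' @param truth A [cv_ground_truth()].
#' @param design A [build_cv_design()] (defaults to 11 mixtures, 4 mM
#'   total).
#' @return A shift table `data.frame` with columns `sample_id`, `A_total`,
#'   `B_total` (mol/L), `proton_id`, `molecule`, `delta_obs`, `delta_free`,
#'   `delta_delta` (ppm).
#' @export
generate_cv_table <- function(truth, design = build_cv_design()) {
  stopifnot(inherits(truth, "cv_truth"))
  grid <- expand.grid(sample_id = design$sample_id,
                      proton_id = truth$protons,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id), , drop = FALSE]
  i <- match(grid$sample_id, design$sample_id)
  j <- match(grid$proton_id, truth$protons)
  A <- design$A_total[i]
  B <- design$B_total[i]
  molecule <- truth$molecule[j]
  hg <- complex_concentration(A, B, truth$K)
  X <- ifelse(molecule == "guest", A, B)
  dd_model <- truth$delta_c[j] * hg / X
  eps <- if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    stats::rnorm(nrow(grid), 0, truth$noise_sd)
  } else rep(0, nrow(grid))
  delta_obs <- truth$delta_free[j] - dd_model + eps
  data.frame(
    sample_id = grid$sample_id,
    A_total = A, B_total = B,
    proton_id = grid$proton_id,
    molecule = molecule,
    delta_obs = delta_obs,
    delta_free = truth$delta_free[j],
    delta_delta = shift_perturbation_from_observed(truth$delta_free[j],
                                                   delta_obs),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Ground truth for a synthetic ITC experiment
#'
#' Defaults reproduce a weak (low Wiseman c) cyclodextrin inclusion
#' titration: K about 1.1e3 L/mol, 1:1 stoichiometry, a small exothermic
#' enthalpy, 3 mM guest titrated into 0.75 mM host over 25 x 10 uL
#' injections at 25 C.
#'
#' @param K True association constant (L/mol).
#' @param n True site number.
#' @param dH True molar enthalpy (cal/mol; exothermic negative).
#' @param design An [itc_design()].
#' @param noise_sd Gaussian noise SD on injection heats (cal);
#'   0.5 ucal = 5e-7 cal is a realistic instrument noise floor.
#' @param seed RNG seed used by [generate_itc_thermogram()].
#' @return A list of class `itc_truth`.
#' @export
itc_ground_truth <- function(K = 1096, n = 1, dH = -1013,
                             design = itc_design(),
                             noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(K = K, n = n, dH = dH, design = design,
                 noise_sd = noise_sd, seed = seed),
            class = "itc_truth")
}

#' Generate a synthetic ITC thermogram (optionally with a matched control)
#'
#' Simulates per-injection heats under the independent-sites model and adds
#' seeded Gaussian noise. The optional control emulates a blank titration
#' of guest into solvent: zero binding heat plus noise of the same SD,
#' suitable for exercising [blank_subtract()].
#'
#' @param truth An [itc_ground_truth()].
#' @param with_control Also return a noise-only control thermogram.
#' @return A `thermogram`, or, with `with_control = TRUE`, a list with
#'   elements `sample` and `control`.
#' @export
generate_itc_thermogram <- function(truth, with_control = FALSE) {
  stopifnot(inherits(truth, "itc_truth"))
  tg <- simulate_thermogram(truth$K, truth$n, truth$dH, truth$design)
  nk <- nrow(tg)
  if (truth$noise_sd > 0 || with_control) set.seed(truth$seed)
  if (truth$noise_sd > 0)
    tg$heat_cal <- tg$heat_cal + stats::rnorm(nk, 0, truth$noise_sd)
  if (!with_control) return(tg)
  ctrl <- tg
  ctrl$heat_cal <- if (truth$noise_sd > 0)
    stats::rnorm(nk, 0, truth$noise_sd) else rep(0, nk)
  list(sample = tg, control = ctrl)
}
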