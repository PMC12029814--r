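#' Read a continuous-variation shift table from CSV
#'
#' Dialect: header row with columns `sample_id`, `A_total_mM`,
#' `B_total_mM`, `proton_id`, `molecule`, `delta_obs_ppm`,
#' `delta_free_ppm`; UTF-8, '.' decimal separator. Concentrations are
#' converted to mol/L on read and the shift perturbation
#' \eqn{\Delta\delta = \delta_{free} - \delta_{obs}} is computed per
#' record. If the samples do not share a constant total concentration
#' within `C_tolerance` (relative), a warning is attached — continuous
#' variation assumes A + B constant — but the read succeeds.
#'
#' @param path CSV file path.
#' @param C_tolerance Relative tolerance on the constancy of A + B
#'   (default 1e-6).
#' @return A shift table `data.frame` (internal units: mol/L, ppm).
#' @export
read_shift_table <- function(path, C_tolerance = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "A_total_mM", "B_total_mM", "proton_id",
            "molecule", "delta_obs_ppm", "delta_free_ppm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("shift-table CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("A_total_mM", "B_total_mM", "delta_obs_ppm",
                "delta_free_ppm")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1])
    if (anyNA(v)) stop("missing value in column '", col, "'")
    raw[[col]] <- v
  }
  dup <- duplicated(raw[c("sample_id", "proton_id")])
  if (any(dup))
    stop("duplicate (sample, proton) pair at row ", which(dup)[1],
         ": sample ", raw$sample_id[which(dup)[1]],
         ", proton ", raw$proton_id[which(dup)[1]])
  if (!all(raw$molecule %in% c("guest", "host")))
    stop("column 'molecule' must be 'guest' or 'host'")
  tab <- data.frame(
    sample_id = raw$sample_id,
    A_total = raw$A_total_mM * 1e-3,
    B_total = raw$B_total_mM * 1e-3,
    proton_id = raw$proton_id,
    molecule = raw$molecule,
    delta_obs = raw$delta_obs_ppm,
    delta_free = raw$delta_free_ppm,
    stringsAsFactors = FALSE)
  tab$delta_delta <- shift_perturbation_from_observed(tab$delta_free,
                                                      tab$delta_obs)
  C <- tab$A_total + tab$B_total
  if (diff(range(C)) > C_tolerance * max(C)) {
    warning("total concentration A + B is not constant across samples ",
            "(range ", signif(min(C), 4), " - ", signif(max(C), 4),
            " mol/L); continuous-variation analysis assumes it is")
    attr(tab, "constant_total") <- FALSE
  } else {
    attr(tab, "constant_total") <- TRUE
  }
  tab
}

#' Write a shift table to CSV
#'
#' Inverse of [read_shift_table()]; concentrations are written in mM.
#'
#' @param table A shift table `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path) {
  out <- data.frame(
    sample_id = table$sample_id,
    A_total_mM = table$A_total * 1e3,
    B_total_mM = table$B_total * 1e3,
    proton_id = table$proton_id,
    molecule = table$molecule,
    delta_obs_ppm = table$delta_obs,
    delta_free_ppm = table$delta_free)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ITC thermogram from CSV
#'
#' Dialect: columns `injection_index`, `volume_uL`, `heat`, `heat_units`
#' (`ucal` or `uJ`). Heats are converted to calories internally
#' (1 cal = 4.184 J). When a design is supplied, the injection count is
#' checked against its schedule.
#'
#' @param path CSV file path.
#' @param design Optional [itc_design()] to validate against.
#' @return A `thermogram` `data.frame` (`heat_cal` in cal).
#' @export
read_thermogram <- function(path, design = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection_index", "volume_uL", "heat", "heat_units")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("thermogram CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(raw$heat_units %in% c("ucal", "uJ")))
    stop("heat_units must be 'ucal' or 'uJ'")
  heat_cal <- ifelse(raw$heat_units == "ucal",
                     raw$heat * 1e-6,
                     raw$heat * 1e-6 / 4.184)
  tg <- data.frame(
    injection = as.integer(raw$injection_index),
    volume_L = raw$volume_uL * 1e-6,
    heat_cal = heat_cal,
    molar_ratio = NA_real_)
  if (!is.null(design)) {
    if (nrow(tg) != length(design$injection_volumes))
      stop("thermogram has ", nrow(tg), " injections but the design has ",
           length(design$injection_volumes))
    cs <- .itc_concentration_series(design)
    tg$molar_ratio <- cs$X / cs$M
    attr(tg, "design") <- design
  }
  class(tg) <- c("thermogram", "data.frame")
  tg
}

#' Write an ITC thermogram to CSV
#'
#' @param thermogram A `thermogram`.
#' @param path Output CSV path.
#' @param units Output heat units, `"ucal"` (default) or `"uJ"`.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(thermogram, path, units = c("ucal", "uJ")) {
  units <- match.arg(units)
  heat <- if (units == "ucal") thermogram$heat_cal * 1e6
          else thermogram$heat_cal * 4.184 * 1e6
  out <- data.frame(
    injection_index = thermogram$injection,
    volume_uL = thermogram$volume_L * 1e6,
    heat = heat,
    heat_units = units)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable fit report
#'
#' JSON report with a reproducibility block (package version, seed, config
#' echo) so that any analysis output can be traced back to its inputs.
#'
#' @param fit An `nmr_binding_fit` or `itc_fit`.
#' @param path Output JSON path.
#' @param seed Seed used by the producing analysis (echoed, not consumed).
#' @param config Optional named list echoed verbatim into the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL, config = NULL) {
  repro <- list(
    package = "cdbind",
    version = as.character(utils::packageVersion("cdbind")),
    seed = seed,
    config = config)
  body <- if (inherits(fit, "nmr_binding_fit")) {
    list(model = "nmr_cv_1to1",
         K_per_M = fit$K,
         delta_c_ppm = as.list(fit$delta_c),
         correlation_R = fit$correlation,
         n_iterations = fit$n_iterations,
         converged = fit$converged,
         bootstrap_ci95_K = if (!is.null(fit$bootstrap))
           fit$bootstrap$ci95 else NULL)
  } else if (inherits(fit, "itc_fit")) {
    list(model = "itc_independent_sites",
         K_per_M = fit$K,
         n_sites = fit$n,
         dH_kcal_per_mol = fit$dH / 1000,
         dG_kcal_per_mol = fit$thermo$dG,
         dS_cal_per_mol_K = fit$thermo$dS,
         temperature_K = fit$thermo$temperature,
         wiseman_c = fit$c_parameter,
         identifiability_warning = fit$identifiability_warning,
         converged = fit$converged)
  } else stop("unsupported fit object of class ", class(fit)[1])
  jsonlite::write_json(c(body, list(reproducibility = repro)), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
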