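#' Build a continuous-variation (Job) design
#'
#' A continuous-variation series holds the total concentration
#' \eqn{C = A + B} constant while the mole ratio \eqn{r = A / C} of the
#' guest spans the open interval (0, 1). Interior ratios are evenly spaced,
#' \eqn{r_i = i / (n + 1)} for \eqn{i = 1 \dots n}; the endpoints r = 0 and
#' r = 1 are the pure components, whose spectra serve as the free-state
#' references rather than as mixtures, and are excluded.
#'
#' With an odd `n_samples` the middle sample is exactly equimolar. The
#' 11-sample, 4 mM-total design typical of cyclodextrin studies is the
#' default.
#'
#' @param C_total Constant total concentration \eqn{A + B} (mol/L).
#' @param n_samples Number of binary mixtures (>= 3).
#' @return A `data.frame` with columns `sample_id`, `r` (guest mole ratio),
#'   `A_total`, `B_total` (mol/L); `C_total` is stored as an attribute.
#' @examples
#' d <- build_cv_design(4e-3, 11)
#' d[6, ]  # equimolar midpoint: A = B = 2 mM
#' @export
build_cv_design <- function(C_total = 4e-3, n_samples = 11L) {
  if (!is.finite(C_total) || C_total <= 0)
    stop("C_total must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L)
    stop("a continuous-variation design needs at least 3 mixtures")
  r <- seq_len(n_samples) / (n_samples + 1)
  design <- data.frame(
    sample_id = seq_len(n_samples),
    r = r,
    A_total = r * C_total,
    B_total = (1 - r) * C_total
  )
  attr(design, "C_total") <- C_total
  design
}

#' Job curve for one traced proton
#'
#' The Job (continuous-variation) response for proton \eqn{j} is
#' \eqn{y_i = \Delta\delta(i, j) \cdot X_i}, the shift perturbation scaled
#' by the total concentration of the proton's own molecule. For a 1:1
#' complex the curve is symmetric about the equimolar point and peaks at
#' r = 0.5 regardless of K. The peak location is refined by parabolic
#' interpolation through the discrete maximum (of \eqn{|y|}, so protons
#' with negative limiting shifts are handled) and its two neighbours; a
#' maximum at the edge of the design is reported unrefined. Ties resolve
#' to the smallest r.
#'
#' @param table A shift table (see [read_shift_table()] or
#'   [generate_cv_table()]) containing columns `sample_id`, `A_total`,
#'   `B_total`, `proton_id`, `molecule`, `delta_delta`.
#' @param proton_id Label of the proton to trace.
#' @return An object of class `job_curve`: a list with `r` (mole ratios),
#'   `y` (signed Job response, ppm * mol/L), `r_max`, and `proton_id`.
#' @export
job_curve <- function(table, proton_id) {
  rec <- table[table$proton_id == proton_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("proton '", proton_id, "' not found in the shift table")
  rec <- rec[order(rec$A_total / (rec$A_total + rec$B_total)), , drop = FALSE]
  r <- rec$A_total / (rec$A_total + rec$B_total)
  X <- ifelse(rec$molecule == "guest", rec$A_total, rec$B_total)
  y <- rec$delta_delta * X
  if (all(abs(y) < .Machine$double.eps))
    stop("flat Job curve: all shift perturbations are zero for proton '",
         proton_id, "'")
  a <- abs(y)
  k <- which(a == max(a))[1L]  # ties -> smallest r (rows sorted by r)
  if (k == 1L || k == length(y)) {
    r_max <- r[k]
  } else {
    r_max <- .parabolic_vertex(r[k - 1L], r[k], r[k + 1L],
                               a[k - 1L], a[k], a[k + 1L])
  }
  structure(list(r = r, y = y, r_max = r_max, proton_id = proton_id),
            class = "job_curve")
}

# Vertex abscissa of the parabola through three points; falls back to the
# middle point when the three are collinear.
.parabolic_vertex <- function(x0, x1, x2, y0, y1, y2) {
  num <- (x1 - x0)^2 * (y1 - y2) - (x1 - x2)^2 * (y1 - y0)
  den <- (x1 - x0) * (y1 - y2) - (x1 - x2) * (y1 - y0)
  if (abs(den) < .Machine$double.eps) return(x1)
  x1 - 0.5 * num / den
}

#' Classify complex stoichiometry from a Job curve
#'
#' A 1:1 complex peaks at r = 0.5; peaks near 1/3 or 2/3 signal 1:2 or 2:1
#' association, which this package does not model further.
#'
#' @param curve A [job_curve()] object.
#' @param tolerance Half-width of the acceptance window around 0.5
#'   (default 0.05).
#' @return A list with `classification` (`"1:1"` or `"non-1:1"`) and
#'   `r_max`.
#' @export
estimate_stoichiometry <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "job_curve"))
  cls <- if (abs(curve$r_max - 0.5) <= tolerance) "1:1" else "non-1:1"
  list(classification = cls, r_max = curve$r_max)
}

# Inner (linear) stage of the variable-projection fit: given K, the model
# Delta-delta(i,j) = delta_c(j) * HG_i / X_j,i is linear in each proton's
# delta_c, so the least-squares delta_c and the residual sum of squares
# have closed forms.
.cv_inner_fit <- function(table, K) {
  hg <- complex_concentration(table$A_total, table$B_total, K)
  X <- ifelse(table$molecule == "guest", table$A_total, table$B_total)
  m <- hg / X
  protons <- unique(table$proton_id)
  delta_c <- stats::setNames(numeric(length(protons)), protons)
  fitted <- numeric(nrow(table))
  for (p in protons) {
    idx <- table$proton_id == p
    mm <- sum(m[idx]^2)
    delta_c[p] <- if (mm > 0) sum(m[idx] * table$delta_delta[idx]) / mm else 0
    fitted[idx] <- delta_c[p] * m[idx]
  }
  list(delta_c = delta_c, fitted = fitted,
       ssr = sum((table$delta_delta - fitted)^2))
}

#' Fit the association constant from continuous-variation shift data
#'
#' Global least-squares fit of the exact 1:1 fast-exchange model to the
#' pooled shift perturbations of all traced protons:
#' \deqn{\min_{K,\ \Delta\delta_c} \sum_{i,j}
#'   \left[\Delta\delta_{obs}(i,j) -
#'   \Delta\delta_c(j)\, [HG]_i / X_i \right]^2.}
#' The model is linear in each \eqn{\Delta\delta_c(j)} at fixed K, so the
#' fit uses variable projection: an exact linear inner solve per proton,
#' wrapped in a derivative-free golden-section search on \eqn{\log_{10} K}
#' (coarse grid scan first, to bracket the global minimum). One association
#' constant is shared by all protons of both molecules.
#'
#' The reported correlation is the Pearson correlation between observed and
#' fitted \eqn{\Delta\delta} pooled over all (sample, proton) records — the
#' single-scalar "correlation factor" convention of multi-proton fits.
#' Uncertainty on K is available by nonparametric bootstrap over records.
#'
#' @param table A shift table with columns `sample_id`, `A_total`,
#'   `B_total`, `proton_id`, `molecule`, `delta_delta`.
#' @param log10K_range Search interval for \eqn{\log_{10} K} (K in L/mol);
#'   default `c(-2, 8)`.
#' @param tol Convergence tolerance: the search stops when the relative
#'   change of the bracketed \eqn{\log_{10} K} falls below `tol`
#'   (default 1e-8).
#' @param max_iter Maximum outer iterations (default 200); exceeding it
#'   returns a partial result with `converged = FALSE`.
#' @param bootstrap Number of bootstrap resamples for the K confidence
#'   interval (0 disables; 500 is a reasonable choice).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `nmr_binding_fit`: `K` (L/mol), `delta_c`
#'   (named vector, ppm), `correlation`, `fitted`, `residuals` (ppm),
#'   `converged`, `n_iterations`, `objective_trace` (best SSR per outer
#'   iteration, non-increasing), and optionally `bootstrap` with the
#'   resampled K values and a 95% percentile interval.
#' @export
fit_association_constant <- function(table, log10K_range = c(-2, 8),
                                     tol = 1e-8, max_iter = 200L,
                                     bootstrap = 0L, seed = NULL) {
  need <- c("A_total", "B_total", "proton_id", "molecule", "delta_delta")
  if (!all(need %in% names(table)))
    stop("shift table must contain columns: ", paste(need, collapse = ", "))
  nz <- abs(table$delta_delta) > 0
  if (!any(nz))
    stop("K is unidentifiable: every shift perturbation in the table is zero")
  if (length(unique(table$sample_id[nz])) < 2L)
    stop("need nonzero perturbations in at least 2 samples to constrain K")

  core <- .cv_fit_core(table, log10K_range, tol, max_iter)
  obs <- table$delta_delta
  correlation <- suppressWarnings(stats::cor(obs, core$fitted))

  fit <- structure(
    list(K = core$K, delta_c = core$delta_c, correlation = correlation,
         fitted = core$fitted, residuals = obs - core$fitted,
         ssr = core$ssr, converged = core$converged,
         n_iterations = core$n_iterations,
         objective_trace = core$objective_trace),
    class = "nmr_binding_fit")

  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(table)
    K_boot <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        .cv_fit_core(table[idx, , drop = FALSE], log10K_range, tol, max_iter),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$K
    }, numeric(1))
    fit$bootstrap <- list(
      K = K_boot,
      ci95 = stats::quantile(K_boot, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE))
  }
  fit
}

.cv_fit_core <- function(table, log10K_range, tol, max_iter) {
  obj <- function(lk) .cv_inner_fit(table, 10^lk)$ssr

  # coarse scan brackets the global minimum before golden-section refinement
  grid <- seq(log10K_range[1], log10K_range[2], length.out = 61L)
  vals <- vapply(grid, obj, numeric(1))
  i0 <- which.min(vals)
  a <- grid[max(1L, i0 - 1L)]
  b <- grid[min(length(grid), i0 + 1L)]

  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  trace <- min(vals[i0], f1, f2)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- obj(x2)
    }
    trace <- c(trace, min(trace[length(trace)], f1, f2))
    mid <- (a + b) / 2
    if ((b - a) < tol * max(1, abs(mid))) { converged <- TRUE; break }
  }
  lk <- if (f1 <= f2) x1 else x2
  inner <- .cv_inner_fit(table, 10^lk)
  list(K = 10^lk, delta_c = inner$delta_c, fitted = inner$fitted,
       ssr = inner$ssr, converged = converged, n_iterations = iter,
       objective_trace = trace)
}

#' @export
print.nmr_binding_fit <- function(x, ...) {
  cat("1:1 NMR binding fit (variable projection)\n")
  cat(sprintf("  K = %.4g L/mol  (converged: %s, %d outer iterations)\n",
              x$K, x$converged, x$n_iterations))
  cat(sprintf("  correlation R (obs vs fitted, pooled) = %.4f\n",
              x$correlation))
  cat("  limiting shifts delta_c (ppm):\n")
  for (p in names(x$delta_c))
    cat(sprintf("    %-4s %+.4f\n", p, x$delta_c[[p]]))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap 95%% CI for K: [%.4g, %.4g] (%d resamples)\n",
                x$bootstrap$ci95[1], x$bootstrap$ci95[2],
                length(x$bootstrap$K)))
  invisible(x)
}
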