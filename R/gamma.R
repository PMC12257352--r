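#' Gamma analysis configuration
#'
#' A gamma criterion: dose difference as a percentage of the global maximum
#' of the reference dose, distance-to-agreement in mm, the low-dose
#' threshold as a fraction of the reference maximum, and the search
#' parameters (candidate sub-voxel lattice pitch and search radius).
#'
#' @param dose_criterion_pct dose-difference criterion (% of global max).
#' @param distance_criterion_mm distance-to-agreement criterion (mm).
#' @param threshold_fraction reference-dose threshold fraction in `[0, 1)`;
#'   voxels below it are excluded from numerator and denominator.
#' @param search_cap_mm search radius; defaults to twice the distance
#'   criterion (farther points score gamma > 2 on distance alone).
#' @param interp_step_mm candidate lattice pitch; defaults to a tenth of
#'   the distance criterion.
#' @return An object of class `gamma_config`.
#' @export
gamma_config <- function(dose_criterion_pct, distance_criterion_mm,
                         threshold_fraction = 0.10,
                         search_cap_mm = 2 * distance_criterion_mm,
                         interp_step_mm = distance_criterion_mm / 10) {
  if (dose_criterion_pct <= 0 || distance_criterion_mm <= 0)
    stop("gamma criteria must be > 0")
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in [0, 1)")
  structure(list(dose_criterion_pct = dose_criterion_pct,
                 distance_criterion_mm = distance_criterion_mm,
                 threshold_fraction = threshold_fraction,
                 search_cap_mm = search_cap_mm,
                 interp_step_mm = interp_step_mm,
                 normalization = "global_max"),
            class = "gamma_config")
}

#' Standard criterion set
#'
#' The three patient-specific-QA criteria used throughout the framework:
#' 1%/1 mm, 3%/2 mm (the TG-218 benchmark) and 5%/3 mm, each with a 10%
#' threshold and global normalization.
#' @return List of three [gamma_config()] objects.
#' @export
standard_gamma_criteria <- function() {
  list(gamma_config(1, 1), gamma_config(3, 2), gamma_config(5, 3))
}

#' 3-D gamma index between two dose distributions
#'
#' For every reference voxel at or above the threshold dose, the gamma
#' index is the minimum over candidate points `p` within the search radius
#' of `sqrt(|p - r|^2 / dta^2 + (D_eval(p) - D_ref(r))^2 / dd^2)`, with the
#' dose criterion `dd` taken as a percentage of the reference's global
#' maximum, candidates on a sub-voxel lattice with trilinear evaluation of
#' the evaluated dose. A voxel passes when gamma <= 1.
#'
#' @param reference reference dose (`scalar_volume`, Gy) — in accumulation
#'   validation, the ground-truth accumulated dose.
#' @param evaluated evaluated dose (`scalar_volume`, Gy) — the
#'   system-accumulated dose. May live on a different (resampleable) grid.
#' @param config a [gamma_config()].
#' @param brute_force use the exhaustive full-scan search (test oracle)
#'   instead of the sorted early-exit search.
#' @return An object of class `gamma_result`: `pass_rate_pct`,
#'   `n_evaluated`, `gamma_map` (`scalar_volume`, NA below threshold) and
#'   the config.
#' @export
gamma_index <- function(reference, evaluated, config = gamma_config(3, 2),
                        brute_force = FALSE) {
  gmax <- max(reference$values)
  if (gmax <= 0) stop("reference dose has no voxels above zero")
  thr <- config$threshold_fraction * gmax
  if (!any(reference$values >= thr))
    stop("no reference voxels at or above the threshold dose")
  dd_abs <- config$dose_criterion_pct / 100 * gmax
  fn <- if (brute_force) cpp_gamma_brute else cpp_gamma
  res <- fn(reference$values, reference$grid$size, reference$grid$spacing,
            reference$grid$origin,
            evaluated$values, evaluated$grid$size, evaluated$grid$spacing,
            evaluated$grid$origin,
            dd_abs, config$distance_criterion_mm, thr,
            config$interp_step_mm, config$search_cap_mm)
  structure(list(pass_rate_pct = 100 * res$n_pass / res$n_evaluated,
                 n_evaluated = res$n_evaluated,
                 gamma_map = scalar_volume(
                   array(res$gamma, dim = reference$grid$size),
                   reference$grid, "mask"),
                 config = config),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (thr %g%%): %.1f%% of %d voxels pass\n",
              x$config$dose_criterion_pct, x$config$distance_criterion_mm,
              100 * x$config$threshold_fraction, x$pass_rate_pct, x$n_evaluated))
  invisible(x)
}

#' Gamma pass rates over several criteria
#'
#' @param reference,evaluated dose volumes as in [gamma_index()].
#' @param criteria list of [gamma_config()] objects
#'   (default [standard_gamma_criteria()]).
#' @return A data.frame with one row per criterion: `dose_criterion_pct`,
#'   `distance_criterion_mm`, `pass_rate_pct`, `n_evaluated`.
#' @export
multi_criteria_gamma <- function(reference, evaluated,
                                 criteria = standard_gamma_criteria()) {
  if (length(criteria) == 0)
    return(data.frame(dose_criterion_pct = numeric(0),
                      distance_criterion_mm = numeric(0),
                      pass_rate_pct = numeric(0), n_evaluated = numeric(0)))
  rows <- lapply(criteria, function(cf) {
    r <- gamma_index(reference, evaluated, cf)
    data.frame(dose_criterion_pct = cf$dose_criterion_pct,
               distance_criterion_mm = cf$distance_criterion_mm,
               pass_rate_pct = r$pass_rate_pct,
               n_evaluated = r$n_evaluated)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
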