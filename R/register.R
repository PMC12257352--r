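#' Registration parameters for the intensity-based DIR stand-in
#'
#' Parameters of the multi-resolution, Gaussian-regularized demons
#' registration used as the pluggable system under test. `degrade_factor`
#' is a deliberate quality knob: 0 returns the best estimate, values toward
#' 1 blend the estimate into a smooth seeded noise field, emulating an
#' inaccurate DIR so the downstream metrics can be shown to detect it.
#'
#' @param levels multi-resolution pyramid depth (>= 1, coarsest level
#'   downsampled by `2^(levels-1)`).
#' @param iterations iterations per level, coarsest first (recycled to
#'   `levels`).
#' @param update_smoothing_sigma_mm Gaussian sigma (mm) applied to each
#'   demons update (fluid-like regularization).
#' @param field_smoothing_sigma_mm Gaussian sigma (mm) applied to the
#'   accumulated field each iteration (diffusion-like regularization).
#' @param degrade_factor in `[0, 1]`; see above.
#' @param field_grid_factor integer coarsening of the returned field grid
#'   relative to the image grid (the clinical system exports its field at
#'   roughly 4x the CT voxel size).
#' @param max_step_mm cap on the per-iteration demons step.
#' @param noise_sigma_mm amplitude (RMS mm) of the degradation noise field.
#' @param seed seed for the degradation noise.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(levels = 3L,
                                iterations = c(100L, 60L, 30L),
                                update_smoothing_sigma_mm = 2,
                                field_smoothing_sigma_mm = 1.2,
                                degrade_factor = 0,
                                field_grid_factor = 4L,
                                max_step_mm = 2,
                                noise_sigma_mm = 3,
                                seed = 1L) {
  if (levels < 1) stop("levels must be >= 1")
  if (update_smoothing_sigma_mm < 0 || field_smoothing_sigma_mm < 0)
    stop("smoothing sigmas must be >= 0")
  if (degrade_factor < 0 || degrade_factor > 1)
    stop("degrade_factor must lie in [0, 1]")
  if (field_grid_factor < 1) stop("field_grid_factor must be >= 1")
  iterations <- rep_len(as.integer(iterations), levels)
  structure(list(levels = as.integer(levels), iterations = iterations,
                 update_smoothing_sigma_mm = update_smoothing_sigma_mm,
                 field_smoothing_sigma_mm = field_smoothing_sigma_mm,
                 degrade_factor = degrade_factor,
                 field_grid_factor = as.integer(field_grid_factor),
                 max_step_mm = max_step_mm,
                 noise_sigma_mm = noise_sigma_mm,
                 seed = as.integer(seed)),
            class = "registration_params")
}

# Grid downsampled by an integer factor, covering the same extent.
coarsen_grid <- function(grid, factor) {
  if (factor <= 1) return(grid)
  size <- pmax(as.integer(ceiling(grid$size / factor)), 2L)
  spacing <- grid$spacing * (grid$size - 1) / pmax(size - 1, 1L)
  volume_grid(size, spacing, grid$origin)
}

smooth_volume <- function(vol, sigma) {
  scalar_volume(cpp_gauss_smooth(vol$values, vol$grid$size, vol$grid$spacing, sigma),
                vol$grid, vol$quantity)
}

smooth_field_inplace <- function(disp, grid, sigma) {
  if (sigma <= 0) return(disp)
  for (c_i in 1:3)
    disp[, , , c_i] <- cpp_gauss_smooth(disp[, , , c_i], grid$size, grid$spacing, sigma)
  disp
}

#' Estimate a plan-to-treatment displacement field (system under test)
#'
#' A Gaussian-regularized, multi-resolution demons registration of the
#' treatment image onto the planning image, returning the pull-back
#' `plan_to_mod` field used for dose accumulation: the estimated `v`
#' satisfies `moving(x + v(x)) ~ fixed(x)`. The returned field lives on a
#' grid coarsened by `field_grid_factor` (the exported-field resolution of
#' the emulated clinical system). Deterministic for fixed inputs and seed.
#'
#' @param fixed planning CT (`scalar_volume`, HU).
#' @param moving treatment CT on the same physical extent.
#' @param params a [registration_params()].
#' @return A `vector_field` tagged `plan_to_mod`.
#' @export
estimate_field <- function(fixed, moving, params = registration_params()) {
  if (max(abs(fixed$grid$origin - moving$grid$origin)) > 1e-6 ||
      max(abs(fixed$grid$origin + (fixed$grid$size - 1) * fixed$grid$spacing -
              (moving$grid$origin + (moving$grid$size - 1) * moving$grid$spacing))) > 1e-3)
    stop("fixed and moving volumes must share their physical extent")
  levels <- params$levels
  field <- NULL
  for (lv in seq_len(levels)) {
    factor <- 2^(levels - lv)
    g <- coarsen_grid(fixed$grid, factor)
    presmooth <- if (factor > 1) 0.5 * factor * mean(fixed$grid$spacing) else 0
    f_lv <- resample_to_grid(if (presmooth > 0) smooth_volume(fixed, presmooth) else fixed, g)
    m_lv <- resample_to_grid(if (presmooth > 0) smooth_volume(moving, presmooth) else moving, g)
    field <- if (is.null(field)) zero_field(g, "plan_to_mod") else resample_field(field, g)
    disp <- field$disp
    for (it in seq_len(params$iterations[lv])) {
      warped <- cpp_warp(m_lv$values, g$size, g$spacing, g$origin,
                         disp, g$size, g$spacing, g$origin,
                         g$size, g$spacing, g$origin, TRUE, -1000, TRUE)
      upd <- cpp_demons_update(f_lv$values, warped, g$size, g$spacing, params$max_step_mm)
      upd <- smooth_field_inplace(upd, g, params$update_smoothing_sigma_mm)
      # compositive update: v <- du o v
      disp <- cpp_compose(disp, g$size, g$spacing, g$origin,
                          upd, g$size, g$spacing, g$origin)
      disp <- smooth_field_inplace(disp, g, params$field_smoothing_sigma_mm)
    }
    field <- vector_field(disp, g, "plan_to_mod")
  }
  out_grid <- coarsen_grid(fixed$grid, params$field_grid_factor)
  field <- resample_field(field, out_grid)

  # anatomy outside the FOV is unknown: taper the estimate to zero toward
  # the image faces (10 mm smoothstep), mirroring the authoring convention
  co <- grid_coord_arrays(out_grid)
  lo <- out_grid$origin
  hi <- out_grid$origin + (out_grid$size - 1) * out_grid$spacing
  face <- pmin(co$x - lo[1], hi[1] - co$x,
               co$y - lo[2], hi[2] - co$y,
               co$z - lo[3], hi[3] - co$z)
  t <- pmin(pmax(face / 10, 0), 1)
  w <- t^2 * (3 - 2 * t)
  field <- vector_field(field$disp * as.vector(w), out_grid, "plan_to_mod")

  # suppress displacements in the partial-volume shell at the patient
  # surface: the air-tissue gradient dominates the demons force there while
  # the image carries no anatomical deformation signal. The body is taken
  # from the fixed image at the conventional -400 HU threshold.
  body <- resample_to_grid(
    scalar_volume((fixed$values > -400) * 1, fixed$grid, "mask"), out_grid)
  d_in <- cpp_edt((body$values < 0.5) * 1, out_grid$size, out_grid$spacing)
  cap <- 0.6 * pmax(d_in - 1.5 * max(out_grid$spacing), 0)
  mag <- sqrt(field$disp[, , , 1]^2 + field$disp[, , , 2]^2 + field$disp[, , , 3]^2)
  scl <- pmin(1, cap / pmax(mag, 1e-9))
  field <- vector_field(field$disp * as.vector(scl), out_grid, "plan_to_mod")

  if (params$degrade_factor > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(params$seed)
    noise <- array(stats::rnorm(prod(out_grid$size) * 3), dim = c(out_grid$size, 3L))
    noise <- smooth_field_inplace(noise, out_grid, 10)
    rms <- sqrt(mean(noise^2))
    if (rms > 0) noise <- noise / rms * params$noise_sigma_mm / sqrt(3)
    d <- params$degrade_factor
    field <- vector_field((1 - d) * field$disp + d * noise, out_grid, "plan_to_mod")
  }
  field
}

#' Perfect-registration control arm
#'
#' Returns the numerically inverted true authored field as the estimated
#' `plan_to_mod` registration, so the full pipeline can be verified to
#' produce complete agreement (up to inversion tolerance) when the DIR is
#' perfect.
#'
#' @param true_field the authored `mod_to_plan` `vector_field`.
#' @param tol_mm inversion tolerance passed to [invert_field()].
#' @return A `vector_field` tagged `plan_to_mod`.
#' @export
register_with_oracle <- function(true_field, tol_mm = 0.05) {
  if (true_field$direction != "mod_to_plan")
    stop("the true field must be tagged 'mod_to_plan'")
  invert_field(true_field, tol_mm = tol_mm)
}
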