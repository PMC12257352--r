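#' Deformation specification
#'
#' Describes one authored organ deformation: radial expansion or shrinkage
#' of the organ surface by a target peak displacement, or a bulk shift, with
#' a smooth Gaussian falloff of influence outside the organ. Fields are
#' authored directly in the `mod_to_plan` pull-back direction used to
#' synthesize the deformed treatment image.
#'
#' @param organ structure name the deformation acts on.
#' @param mode `"expand"`, `"shrink"` or `"shift"`.
#' @param magnitude_mm target peak surface displacement (mm, > 0); for
#'   `shift` the magnitude of `shift_vec` is used instead.
#' @param shift_vec length-3 displacement (mm) for `mode = "shift"`.
#' @param decay_mm Gaussian falloff length (mm) of the influence region
#'   outside the organ. Defaults to `max(8, 0.4 * magnitude)` for
#'   expansions and shifts toward the organ, and `max(8, 0.8 * magnitude)`
#'   for shrinks (an outward-decaying shrink field needs the broader
#'   falloff to keep the map invertible; expansions are invertible for any
#'   falloff).
#' @param profile `"radial"` (spherical organs: displacement about the 3-D
#'   centroid) or `"axial"` (tubular organs: in-plane displacement about a
#'   per-slice centerline).
#' @param seed accepted for interface uniformity; authoring is analytic.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(organ, mode = c("expand", "shrink", "shift"),
                             magnitude_mm = NULL, shift_vec = NULL,
                             decay_mm = NULL, profile = c("radial", "axial"),
                             seed = 1L) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (mode == "shift") {
    if (is.null(shift_vec) || length(shift_vec) != 3)
      stop("mode 'shift' needs a length-3 shift_vec")
    magnitude_mm <- sqrt(sum(shift_vec^2))
  }
  if (is.null(magnitude_mm) || magnitude_mm <= 0)
    stop("magnitude_mm must be > 0")
  if (is.null(decay_mm))
    decay_mm <- if (mode == "shrink") max(8, 0.8 * magnitude_mm)
                else max(8, 0.4 * magnitude_mm)
  if (decay_mm <= 0) stop("decay_mm must be > 0")
  structure(list(organ = organ, mode = mode, magnitude_mm = magnitude_mm,
                 shift_vec = shift_vec, decay_mm = decay_mm,
                 profile = profile, seed = as.integer(seed)),
            class = "deformation_spec")
}

# Displacement magnitude profile: smoothstep ramp from 0 at the center to
# the peak M at the anchor radius r0, Gaussian decay beyond. Both pieces
# have zero slope at the anchor, so the profile is C^1 everywhere (a kink
# there would cost interpolation accuracy during inversion). The bounded
# ramp slope (1.5 M / r0) keeps the radial map monotone for all shipped
# magnitudes.
ramp_profile <- function(r, r0, M, sigma) {
  t <- pmin(r / r0, 1)
  inside <- M * t^2 * (3 - 2 * t)
  ifelse(r <= r0, inside, M * exp(-(r - r0)^2 / (2 * sigma^2)))
}

# Smooth elementwise minimum (4-norm): caps the displacement magnitude
# without introducing slope discontinuities.
soft_cap <- function(m, cap) {
  pos <- m > 1e-12
  out <- m
  out[pos] <- (m[pos]^-4 + pmax(cap[pos], 1e-9)^-4)^(-1 / 4)
  out
}

author_one_field <- function(structures, spec, co, cap) {
  grid <- structures$grid
  mask <- get_mask(structures, spec$organ) != 0
  if (!any(mask)) stop(sprintf("structure '%s' is empty", spec$organ))
  M <- spec$magnitude_mm
  sigma <- spec$decay_mm
  n <- grid$size
  u <- array(0, dim = c(n, 3L))

  if (spec$mode == "shift") {
    d <- cpp_edt(mask * 1, n, grid$spacing)
    w <- exp(-d^2 / (2 * sigma^2))
    w[mask] <- 1
    m <- sqrt(sum(spec$shift_vec^2)) * w
    w <- w * soft_cap(m, cap) / pmax(m, 1e-9)
    for (c_i in 1:3) u[, , , c_i] <- -spec$shift_vec[c_i] * w
    return(vector_field(u, grid, "mod_to_plan"))
  }

  sgn <- if (spec$mode == "expand") -1 else 1
  if (spec$profile == "radial") {
    idx <- which(mask)
    ctr <- c(mean(co$x[idx]), mean(co$y[idx]), mean(co$z[idx]))
    dx <- co$x - ctr[1]; dy <- co$y - ctr[2]; dz <- co$z - ctr[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    R <- max(r[idx])
    r0 <- if (spec$mode == "expand") R + M else R - M
    if (r0 <= 0)
      stop(sprintf("shrink magnitude %.1f mm exceeds the radius of '%s'", M, spec$organ))
    m <- soft_cap(ramp_profile(r, r0, M, sigma), cap)
    scale <- sgn * m / pmax(r, 1e-9)
    u[, , , 1] <- scale * dx
    u[, , , 2] <- scale * dy
    u[, , , 3] <- scale * dz
  } else {
    # per-slice centerline for tubular organs; in-plane displacement only
    zpresent <- apply(mask, 3, any)
    cx <- cy <- rep(NA_real_, n[3])
    for (k in which(zpresent)) {
      sl <- mask[, , k]
      cx[k] <- mean(co$x[, , k][sl])
      cy[k] <- mean(co$y[, , k][sl])
    }
    ks <- which(zpresent)
    for (k in seq_len(n[3])[!zpresent]) {
      nearest <- ks[which.min(abs(ks - k))]
      cx[k] <- cx[nearest]; cy[k] <- cy[nearest]
    }
    ctrx <- array(rep(cx, each = n[1] * n[2]), dim = n)
    ctry <- array(rep(cy, each = n[1] * n[2]), dim = n)
    dx <- co$x - ctrx; dy <- co$y - ctry
    r <- sqrt(dx^2 + dy^2)
    idx <- which(mask)
    R <- max(r[idx])
    r0 <- if (spec$mode == "expand") R + M else R - M
    if (r0 <= 0)
      stop(sprintf("shrink magnitude %.1f mm exceeds the lumen radius of '%s'", M, spec$organ))
    m <- ramp_profile(r, r0, M, sigma)
    # attenuate beyond the organ's craniocaudal extent
    zax <- grid_axis(grid, 3)
    zlo <- min(zax[zpresent]); zhi <- max(zax[zpresent])
    dzout <- pmax(0, pmax(zlo - co$z, co$z - zhi))
    m <- soft_cap(m * exp(-dzout^2 / (2 * sigma^2)), cap)
    scale <- sgn * m / pmax(r, 1e-9)
    u[, , , 1] <- scale * dx
    u[, , , 2] <- scale * dy
  }
  vector_field(u, grid, "mod_to_plan")
}

#' Author a ground-truth deformation field
#'
#' Builds the pull-back displacement field (`mod_to_plan`) realizing the
#' requested organ deformations: for each spec a smooth radial (or in-plane
#' axial) displacement about the organ scaled so the pull-back warp moves
#' the organ surface outward (`expand`) or inward (`shrink`) by
#' approximately the requested magnitude, with Gaussian decay of influence
#' away from the organ. Displacement is forced to zero outside the body and
#' inside femoral-head structures (bone does not deform), and its magnitude
#' is capped at 0.6 times the distance to the skin so the field tapers
#' smoothly to zero at the body surface and the map stays invertible
#' (anatomy near the skin moves less than deep organs). Multiple specs are
#' combined by map composition in list order (first spec applied first).
#'
#' @param structures planning `structure_set` (must contain `body`; femur
#'   structures are any whose name starts with `"femur"`).
#' @param specs list of [deformation_spec()] objects; an empty list yields
#'   the zero field.
#' @param check_invertibility run the Jacobian screen and fail on
#'   non-invertible requests (default TRUE).
#' @return A `vector_field` with direction tag `mod_to_plan`.
#' @export
author_field <- function(structures, specs, check_invertibility = TRUE) {
  grid <- structures$grid
  if (length(specs) == 0) return(zero_field(grid, "mod_to_plan"))
  if (inherits(specs, "deformation_spec")) specs <- list(specs)
  co <- grid_coord_arrays(grid)

  body <- get_mask(structures, "body") != 0
  freeze <- !body
  for (nm in grep("^femur", names(structures$masks), value = TRUE))
    freeze <- freeze | (structures$masks[[nm]] != 0)
  # taper to zero over the partial-volume shell at frozen-region borders:
  # a skin voxel mixing air must not move, or warps alias the boundary
  shell <- 1.5 * max(grid$spacing)
  cap <- 0.6 * pmax(cpp_edt(freeze * 1, grid$size, grid$spacing) - shell, 0)
  # the anatomy outside the field of view is unknown: taper toward the
  # image faces as well, so warps never sample beyond the FOV
  lo <- grid$origin
  hi <- grid$origin + (grid$size - 1) * grid$spacing
  face <- pmin(co$x - lo[1], hi[1] - co$x,
               co$y - lo[2], hi[2] - co$y,
               co$z - lo[3], hi[3] - co$z)
  cap <- pmin(cap, 0.5 * face)  # a face voxel never samples beyond the FOV

  fields <- lapply(specs, function(s) {
    f <- author_one_field(structures, s, co, cap)
    for (c_i in 1:3) {
      comp <- f$disp[, , , c_i]
      comp[freeze] <- 0
      f$disp[, , , c_i] <- comp
    }
    f
  })
  combined <- fields[[1]]
  for (f in fields[-1]) combined <- compose_fields(combined, f)
  if (check_invertibility) {
    chk <- verify_invertibility(combined)
    if (!chk$ok)
      stop(sprintf("authored field fails the Jacobian screen (min det %.3f)",
                   chk$min_jacobian))
  }
  combined
}

#' Jacobian screen for invertibility
#'
#' Central-difference Jacobian determinant of the map `x + u(x)` at every
#' voxel; the field is accepted when the minimum determinant exceeds 0.05.
#'
#' @param field a `vector_field`.
#' @return List with `ok` (logical) and `min_jacobian`.
#' @export
verify_invertibility <- function(field) {
  det <- cpp_jacobian_det(field$disp, field$grid$size, field$grid$spacing)
  mj <- min(det)
  list(ok = mj > 0.05, min_jacobian = mj)
}

#' Jacobian determinant map of a displacement field
#' @param field a `vector_field`.
#' @return A `scalar_volume` of determinants of `d(x + u)/dx`.
#' @export
jacobian_determinant <- function(field) {
  det <- cpp_jacobian_det(field$disp, field$grid$size, field$grid$spacing)
  scalar_volume(array(det, dim = field$grid$size), field$grid, "mask")
}

#' Classify a deformation magnitude
#'
#' Assigns the conventional magnitude class from the peak displacement over
#' a mask: below 5 mm small, 5-10 mm medium (boundaries inclusive), above
#' 10 mm large.
#'
#' @param field a `vector_field`.
#' @param mask binary array on the field's grid.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
classify_magnitude <- function(field, mask) {
  mask <- as.array(mask) != 0
  if (!any(mask)) stop("mask is empty")
  mag <- field_magnitude(field)$values
  peak <- max(mag[mask])
  if (peak < 5) "small" else if (peak <= 10) "medium" else "large"
}

#' Shipped deformation scenario presets
#'
#' The per-site treatment-course scenario lists: a no-change fraction plus
#' bladder/rectum (and uterus for the cervix site) filling changes in the
#' medium and large magnitude classes, including combined two-organ
#' fractions. Magnitudes are placed mid-class (medium 7.5 mm, large 15 mm)
#' with a 30 mm bladder `large_expand` for the prostate site; the cervix
#' rectum `large_shrink` uses 11 mm, the largest shrink the rectum lumen
#' admits.
#'
#' @param site `"prostate_like"` or `"cervix_like"`.
#' @return Named list of scenarios; each scenario is a (possibly empty)
#'   list of [deformation_spec()] objects.
#' @export
scenario_presets <- function(site = c("prostate_like", "cervix_like")) {
  site <- match.arg(site)
  bl <- function(mode, mag) deformation_spec("bladder", mode, mag)
  re <- function(mode, mag) deformation_spec("rectum", mode, mag, profile = "axial")
  ut <- function(mode, mag) deformation_spec("uterus", mode, mag)
  if (site == "prostate_like") {
    list(
      no_change = list(),
      bladder_med_shrink = list(bl("shrink", 7.5)),
      bladder_med_expand = list(bl("expand", 7.5)),
      bladder_large_expand = list(bl("expand", 30)),
      rectum_med_shrink = list(re("shrink", 7.5)),
      rectum_med_expand = list(re("expand", 7.5)),
      rectum_large_expand = list(re("expand", 15)),
      bladder_med_shrink_rectum_med_expand = list(bl("shrink", 7.5), re("expand", 7.5)),
      bladder_med_expand_rectum_med_expand = list(bl("expand", 7.5), re("expand", 7.5))
    )
  } else {
    list(
      no_change = list(),
      bladder_med_shrink = list(bl("shrink", 7.5)),
      bladder_med_expand = list(bl("expand", 7.5)),
      bladder_large_expand = list(bl("expand", 15)),
      rectum_large_shrink = list(re("shrink", 11)),
      rectum_med_shrink = list(re("shrink", 7.5)),
      rectum_large_expand = list(re("expand", 15)),
      bladder_med_expand_rectum_med_shrink = list(bl("expand", 7.5), re("shrink", 7.5)),
      bladder_med_expand_rectum_med_expand = list(bl("expand", 7.5), re("expand", 7.5)),
      uterus_med_expand = list(ut("expand", 7.5)),
      uterus_med_shrink = list(ut("shrink", 7.5))
    )
  }
}
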