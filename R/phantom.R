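#' Phantom configuration
#'
#' Parameters of the synthetic pelvic phantom: site, grid, organ geometry,
#' tissue HU assignments, PTV margin and the seed for the CT texture. The
#' defaults give a male-pelvis-like (`prostate_like`) or female-pelvis-like
#' (`cervix_like`) anatomy of body, bladder, rectum (gas-filled tube),
#' target organ (prostate or uterus, plus bowel for the cervix site) and two
#' femoral heads, on a 128 x 128 x 64 grid at 2 x 2 x 2.5 mm. The grid is
#' placed so its geometric center coincides with the target-organ centroid,
#' as cone-beam treatment images are centered on the isocenter.
#'
#' Organ geometry entries are lists with fields `type` (`"ellipsoid"` or
#' `"tube"`), `center` (mm), `radii` (mm; for tubes `c(rx, ry, half_length)`)
#' and `hu`.
#'
#' @param site `"prostate_like"` or `"cervix_like"`.
#' @param size,spacing grid specification (voxels, mm).
#' @param ptv_margin_mm isotropic CTV-to-PTV margin in mm.
#' @param seed integer seed for the CT texture.
#' @param organs optional named list overriding the default organ geometry.
#' @param hu_body soft-tissue HU of the body.
#' @param texture_sd_hu,texture_sigma_mm amplitude (HU) and correlation
#'   length (mm) of the smooth CT texture added inside the body.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(site = c("prostate_like", "cervix_like"),
                           size = c(128L, 128L, 64L),
                           spacing = if (match.arg(site) == "cervix_like")
                             c(2, 2, 2.5) else c(2, 2, 2.5),
                           ptv_margin_mm = 7,
                           seed = 1L,
                           organs = NULL,
                           hu_body = 35,
                           texture_sd_hu = 20,
                           texture_sigma_mm = 6) {
  site <- match.arg(site)
  if (ptv_margin_mm < 0) stop("ptv_margin_mm must be >= 0")
  geo <- default_organ_geometry(site)
  if (!is.null(organs)) geo[names(organs)] <- organs
  for (g in geo) if (any(unlist(g$radii) <= 0)) stop("organ radii must be > 0")
  cfg <- list(site = site, size = as.integer(size), spacing = as.numeric(spacing),
              ptv_margin_mm = ptv_margin_mm, seed = as.integer(seed),
              organs = geo, hu_body = hu_body,
              texture_sd_hu = texture_sd_hu, texture_sigma_mm = texture_sigma_mm)
  class(cfg) <- "phantom_config"
  cfg
}

default_organ_geometry <- function(site) {
  common <- list(
    rectum  = list(type = "tube", center = c(0, 38, 0), radii = c(14, 14, 55),
                   hu = 40, gas_radius = 7, hu_gas = -750),
    femur_L = list(type = "ellipsoid", center = c(-78, 5, 0), radii = c(24, 24, 24), hu = 700),
    femur_R = list(type = "ellipsoid", center = c(78, 5, 0), radii = c(24, 24, 24), hu = 700)
  )
  if (site == "prostate_like") {
    c(list(
      bladder  = list(type = "ellipsoid", center = c(0, -42, 22), radii = c(32, 26, 24), hu = 0),
      prostate = list(type = "ellipsoid", center = c(0, 0, 0), radii = c(20, 20, 20), hu = 45)
    ), common)
  } else {
    c(list(
      bladder = list(type = "ellipsoid", center = c(0, -52, -18), radii = c(30, 25, 22), hu = 0),
      uterus  = list(type = "ellipsoid", center = c(0, -12, 8), radii = c(22, 16, 36), hu = 45),
      bowel   = list(type = "ellipsoid", center = c(0, -18, 56), radii = c(55, 40, 20), hu = 20)
    ), common)
  }
}

target_organ <- function(site) if (site == "prostate_like") "prostate" else "uterus"

#' Prescription context
#'
#' @param total_dose_Gy prescribed total dose (Gy), > 0.
#' @param n_fractions number of fractions, >= 1.
#' @param goal_set list of clinical goals (see [parse_goal()]).
#' @return An object of class `prescription_context`.
#' @export
prescription_context <- function(total_dose_Gy, n_fractions, goal_set = list()) {
  if (total_dose_Gy <= 0) stop("total_dose_Gy must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  structure(list(total_dose_Gy = total_dose_Gy, n_fractions = as.integer(n_fractions),
                 goal_set = goal_set),
            class = "prescription_context")
}

#' @export
print.prescription_context <- function(x, ...) {
  cat(sprintf("<prescription> %.4g Gy in %d fractions (%.4g Gy/fx), %d clinical goals\n",
              x$total_dose_Gy, x$n_fractions, x$total_dose_Gy / x$n_fractions,
              length(x$goal_set)))
  invisible(x)
}

ellipsoid_mask <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 +
    ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

tube_mask <- function(co, center, radii) {
  inplane <- ((co$x - center[1]) / radii[1])^2 + ((co$y - center[2]) / radii[2])^2 <= 1
  inplane & abs(co$z - center[3]) <= radii[3]
}

#' Build the synthetic pelvic phantom
#'
#' Generates the planning CT (HU, with seeded soft-tissue texture), the
#' structure set (body, organs, CTV = target organ, PTV = CTV expanded by
#' the configured margin and clipped to the body) and the prescription
#' context (prostate-style 60 Gy / 20 fx or cervix-style 45 Gy / 25 fx with
#' the shipped clinical goal sets). Deterministic for a fixed config.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `ct` (`scalar_volume`), `structures`
#'   (`structure_set`), `rx` (`prescription_context`) and `config`.
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- volume_grid(config$size, config$spacing,
                      origin = -(config$size - 1) * config$spacing / 2)
  co <- grid_coord_arrays(grid)

  # body: elliptical cylinder, full z extent
  body_semi <- c(115, 90)
  body <- (co$x / body_semi[1])^2 + (co$y / body_semi[2])^2 <= 1

  masks <- list(body = body)
  ct <- array(-1000, dim = grid$size)
  ct[body] <- config$hu_body
  for (nm in names(config$organs)) {
    g <- config$organs[[nm]]
    m <- if (g$type == "tube") tube_mask(co, g$center, g$radii)
         else ellipsoid_mask(co, g$center, g$radii)
    if (any(m & !body))
      stop(sprintf("organ '%s' overlaps the body boundary", nm))
    masks[[nm]] <- m
    ct[m] <- g$hu
    if (!is.null(g$gas_radius)) {
      core <- g
      core$radii[1:2] <- g$gas_radius
      mcore <- tube_mask(co, core$center, core$radii)
      ct[mcore] <- g$hu_gas
    }
  }
  if (config$site == "cervix_like")
    masks$bowel <- masks$bowel & !masks$uterus & !masks$bladder & !masks$rectum

  tgt <- target_organ(config$site)
  masks$CTV <- masks[[tgt]]
  masks$PTV <- expand_margin(masks$CTV, config$ptv_margin_mm, grid$spacing) & body

  # seeded smooth texture so soft tissue carries intensity gradients
  if (config$texture_sd_hu > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
    noise <- array(stats::rnorm(prod(grid$size)), dim = grid$size)
    noise <- cpp_gauss_smooth(noise, grid$size, grid$spacing, config$texture_sigma_mm)
    noise <- noise / stats::sd(noise) * config$texture_sd_hu
    ct[body] <- ct[body] + noise[body]
  }

  order_names <- if (config$site == "prostate_like")
    c("body", "bladder", "rectum", "prostate", "CTV", "PTV", "femur_L", "femur_R")
  else
    c("body", "bladder", "rectum", "uterus", "bowel", "CTV", "PTV", "femur_L", "femur_R")
  structures <- structure_set(masks[order_names], grid)
  attr(structures, "body_semiaxes") <- body_semi

  rx <- if (config$site == "prostate_like")
    prescription_context(60, 20, default_goal_set("prostate_like"))
  else
    prescription_context(45, 25, default_goal_set("cervix_like"))

  list(ct = scalar_volume(ct, grid, "HU"), structures = structures,
       rx = rx, config = config)
}

#' Isotropic physical-margin expansion of a binary mask
#'
#' Dilates a mask by a physical distance using the anisotropic Euclidean
#' distance transform: a voxel belongs to the expanded mask iff its center
#' lies within `margin_mm` of some foreground voxel center.
#'
#' @param mask 3-D logical/binary array.
#' @param margin_mm expansion distance in mm, >= 0.
#' @param spacing voxel spacing (mm, length 3).
#' @return Logical array of the same shape.
#' @export
expand_margin <- function(mask, margin_mm, spacing) {
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  mask <- as.array(mask) != 0
  if (margin_mm == 0 || !any(mask)) return(mask)
  d <- cpp_edt(mask * 1, dim(mask), spacing)
  array(d <= margin_mm + 1e-9, dim = dim(mask))
}

# Depth from the body surface along the ray toward an in-plane source
# direction e = (cos theta, sin theta), for the analytic elliptical body.
beam_depth <- function(x, y, theta, semi) {
  cth <- cos(theta); sth <- sin(theta)
  A <- (cth / semi[1])^2 + (sth / semi[2])^2
  B <- 2 * (x * cth / semi[1]^2 + y * sth / semi[2]^2)
  C <- (x / semi[1])^2 + (y / semi[2])^2 - 1
  disc <- B^2 - 4 * A * C
  tpos <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
  ifelse(disc >= 0, pmax(tpos, 0), 0)
}

#' Analytic plan-like per-fraction dose
#'
#' Computes a per-fraction dose distribution of realistic shape without
#' radiation transport: a prescription plateau over the PTV with Gaussian
#' penumbra falloff, modulated outside the target by superposed entrance
#' fluence from discrete gantry angles (`imrt9`: nine beams with visible
#' beam-edge steps near the surface) or a fine angular sweep (`vmat`:
#' no discrete edges). Beam apertures are fitted to `plan_structures`' PTV
#' and frozen in room coordinates, so calling this with deformed
#' day-of-treatment structures emulates a *scheduled* (non-reoptimized)
#' plan recalculated on the anatomy of the day. Dose is zero outside the
#' day's body mask.
#'
#' @param structures day-of-treatment `structure_set` (provides the body).
#' @param rx a `prescription_context`.
#' @param technique `"imrt9"` or `"vmat"`.
#' @param seed accepted for interface uniformity; the model is analytic and
#'   deterministic.
#' @param penumbra_sigma_mm Gaussian penumbra sigma (mm).
#' @param plan_structures planning `structure_set` defining the PTV the
#'   apertures were fitted to (defaults to `structures`).
#' @param entrance_weight relative weight of the entrance-fluence term.
#' @param mu_mm linear attenuation coefficient (1/mm) of the entrance model.
#' @param plateau_boost target-plateau level relative to prescription
#'   (default 1.015: real plans slightly overcover the PTV, so coverage
#'   goals like D95% > 100% are met with margin on the planned dose).
#' @return A `scalar_volume` of per-fraction dose in Gy.
#' @export
synth_fraction_dose <- function(structures, rx, technique = c("imrt9", "vmat"),
                                seed = 1L, penumbra_sigma_mm = 4,
                                plan_structures = structures,
                                entrance_weight = 0.35, mu_mm = 0.005,
                                plateau_boost = 1.015) {
  technique <- match.arg(technique)
  grid <- structures$grid
  ptv <- get_mask(plan_structures, "PTV") != 0
  if (!any(ptv)) stop("PTV mask is empty")
  body <- get_mask(structures, "body") != 0
  rx_fx <- rx$total_dose_Gy / rx$n_fractions
  co <- grid_coord_arrays(grid)

  # plateau + penumbra around the (planning) PTV
  d_out <- cpp_edt(ptv * 1, grid$size, grid$spacing)
  A <- exp(-d_out^2 / (2 * penumbra_sigma_mm^2))

  # aperture geometry frozen on the planning PTV
  idx <- which(ptv != 0)
  cx <- mean(co$x[idx]); cy <- mean(co$y[idx]); cz <- mean(co$z[idx])
  r_inplane <- sqrt((co$x[idx] - cx)^2 + (co$y[idx] - cy)^2)
  w <- max(r_inplane) + 1
  h <- max(abs(co$z[idx] - cz)) + 1
  semi <- attr(plan_structures, "body_semiaxes")
  if (is.null(semi)) {
    bidx <- which(get_mask(plan_structures, "body") != 0)
    semi <- c(max(abs(co$x[bidx])), max(abs(co$y[bidx])))
  }

  n_beams <- if (technique == "imrt9") 9L else 72L
  angles <- 2 * pi * (seq_len(n_beams) - 1) / n_beams
  edge <- 1.2  # mm sigmoid width of the aperture edge
  E <- array(0, dim = grid$size)
  zs <- stats::plogis((h - abs(co$z - cz)) / edge)
  for (th in angles) {
    depth <- beam_depth(co$x, co$y, th, semi)
    lat <- -(co$x - cx) * sin(th) + (co$y - cy) * cos(th)
    ap <- stats::plogis((w - abs(lat)) / edge) * zs
    d_iso <- beam_depth(cx, cy, th, semi)
    E <- E + ap * exp(-mu_mm * (depth - d_iso))  # unit fluence-dose at iso
  }
  E <- E / n_beams  # = 1 at the isocenter by construction

  dose <- rx_fx * (plateau_boost * A + entrance_weight * (1 - A) * E)
  dose[!body] <- 0
  dose[dose < 0] <- 0
  scalar_volume(array(dose, dim = grid$size), grid, "Gy")
}

#' Shipped clinical goal sets
#'
#' Loads the site's clinical goal set from the package's JSON fixtures:
#' eviQ-style pelvic planning objectives (target D0.03cc / D95% / V-coverage
#' goals with allowed variations; serial and parallel organ-at-risk dose and
#' volume constraints), phrased against the phantom's structure names.
#'
#' @param site `"prostate_like"` or `"cervix_like"`.
#' @return List of `clinical_goal` objects.
#' @export
default_goal_set <- function(site = c("prostate_like", "cervix_like")) {
  site <- match.arg(site)
  f <- system.file("extdata",
                   if (site == "prostate_like") "goals_prostate.json" else "goals_cervix.json",
                   package = "dosewarpqa", mustWork = TRUE)
  read_goal_set(f)
}

#' Read a clinical goal set from JSON
#'
#' The JSON is an array of `{"structure": ..., "goal": ...}` entries whose
#' `goal` strings use the clinical grammar parsed by [parse_goal()], e.g.
#' `"D0.03cc < 105% (109%)"` or `"V60Gy > 95% (93%)"`.
#'
#' @param path JSON file path.
#' @return List of `clinical_goal` objects.
#' @export
read_goal_set <- function(path) {
  entries <- jsonlite::read_json(path)
  lapply(entries, function(e) parse_goal(e$structure, e$goal))
}
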