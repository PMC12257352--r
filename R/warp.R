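#' Warp a scalar volume through a displacement field
#'
#' Pull-back warping: `out(x) = moving(x + u(x))` for every voxel center `x`
#' of the target grid. The displacement field may live on a coarser grid
#' than the target; it is interpolated trilinearly (with edge clamping) at
#' evaluation time. Points mapping outside the moving volume return the
#' quantity's fill value (-1000 HU, 0 Gy, 0 mask).
#'
#' @param moving a `scalar_volume`.
#' @param field a `vector_field` (use [zero_field()] for pure resampling).
#' @param target target `volume_grid`; defaults to the field's grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill out-of-extent fill (defaults per quantity).
#' @return A `scalar_volume` on `target`.
#' @export
warp_image <- function(moving, field, target = field$grid,
                       mode = c("linear", "nearest"), fill = NULL) {
  mode <- match.arg(mode)
  if (is.null(fill)) fill <- default_fill(moving$quantity)
  vals <- cpp_warp(moving$values, moving$grid$size, moving$grid$spacing, moving$grid$origin,
                   field$disp, field$grid$size, field$grid$spacing, field$grid$origin,
                   target$size, target$spacing, target$origin,
                   mode == "linear", fill)
  scalar_volume(array(vals, dim = target$size), target, moving$quantity)
}

#' Warp a binary mask through a displacement field
#'
#' Masks are warped as real-valued fractions and thresholded at 0.5, which
#' gives less staircase error than nearest-neighbor lookup on anisotropic
#' grids.
#'
#' @param mask 3-D binary array on `mask_grid`.
#' @param mask_grid the mask's `volume_grid`.
#' @param field a `vector_field`.
#' @param target target grid (defaults to the field's grid).
#' @return Logical array on `target`.
#' @export
warp_mask <- function(mask, mask_grid, field, target = field$grid) {
  frac <- warp_image(scalar_volume((mask != 0) * 1, mask_grid, "mask"),
                     field, target, mode = "linear", fill = 0)
  frac$values >= 0.5
}

#' Warp a whole structure set
#'
#' @param structures a `structure_set`.
#' @param field a `vector_field`.
#' @param target target grid (defaults to the field's grid).
#' @return A `structure_set` on `target` with every mask warped by
#'   [warp_mask()].
#' @export
warp_structure_set <- function(structures, field, target = field$grid) {
  masks <- lapply(structures$masks, warp_mask,
                  mask_grid = structures$grid, field = field, target = target)
  out <- structure_set(masks, target)
  attr(out, "body_semiaxes") <- attr(structures, "body_semiaxes")
  out
}

#' Numerically invert a displacement field
#'
#' Damped fixed-point iteration `v <- v + alpha (-u(x + v(x)) - v)`,
#' stopping when the largest update falls below `tol_mm` or after
#' `max_iter` iterations. The damping factor is chosen automatically from
#' the field's largest displacement-gradient row norm, which keeps the
#' iteration contractive even for strongly compressive (organ-shrink)
#' maps; smooth mild fields get `alpha = 1`, the classical iteration. The
#' returned field carries the opposite direction tag; the attained
#' composition residual `max |u(x + v(x)) + v(x)|` is attached as
#' attribute `"residual_mm"` (restricted to `mask` when given).
#'
#' @param field a `vector_field` (should pass [verify_invertibility()]).
#' @param tol_mm convergence tolerance on the update, mm.
#' @param max_iter maximum fixed-point iterations.
#' @param mask optional binary array over which the residual is reported.
#' @return The inverse `vector_field`.
#' @export
invert_field <- function(field, tol_mm = 0.05, max_iter = 50L, mask = NULL) {
  lambda <- max_gradient_norm(field)
  alpha <- min(1, 1.8 / (1 + lambda))
  res <- cpp_invert(field$disp, field$grid$size, field$grid$spacing,
                    field$grid$origin, tol_mm, max_iter, alpha)
  resid <- res$residual
  if (!is.null(mask)) resid <- resid[as.array(mask) != 0]
  rmax <- if (length(resid)) max(resid) else 0
  if (rmax > 5 * tol_mm)
    stop(sprintf("field inversion did not converge: residual %.3f mm > %.3f mm",
                 rmax, 5 * tol_mm))
  out <- vector_field(res$disp, field$grid, opposite_direction(field$direction))
  attr(out, "residual_mm") <- rmax
  attr(out, "iterations") <- res$iterations
  out
}

# Largest row norm of the displacement Jacobian (forward differences):
# an upper-bound estimate of the field's Lipschitz constant, used to pick
# the inversion damping.
max_gradient_norm <- function(field) {
  d <- field$disp
  sp <- field$grid$spacing
  n <- field$grid$size
  safe_max <- function(x) if (length(x)) max(x) else 0
  lam <- 0
  for (c_i in 1:3) {
    comp <- d[, , , c_i]
    g1 <- safe_max(abs(comp[-1, , , drop = FALSE] - comp[-n[1], , , drop = FALSE])) / sp[1]
    g2 <- safe_max(abs(comp[, -1, , drop = FALSE] - comp[, -n[2], , drop = FALSE])) / sp[2]
    g3 <- safe_max(abs(comp[, , -1, drop = FALSE] - comp[, , -n[3], drop = FALSE])) / sp[3]
    lam <- max(lam, g1 + g2 + g3)
  }
  lam
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map: `w(x) = u_inner(x) +
#' u_outer(x + u_inner(x))`, i.e. the map that first applies `inner`, then
#' `outer`, on the inner field's grid. The composed field inherits the
#' inner field's direction tag.
#'
#' @param outer,inner `vector_field` objects.
#' @return A `vector_field` on the inner grid.
#' @export
compose_fields <- function(outer, inner) {
  w <- cpp_compose(outer$disp, outer$grid$size, outer$grid$spacing, outer$grid$origin,
                   inner$disp, inner$grid$size, inner$grid$spacing, inner$grid$origin)
  vector_field(w, inner$grid, inner$direction)
}

#' Accumulate a fraction dose by direct dose mapping
#'
#' DDM: `D_acc(y) = D_fx(y + v(y))` by trilinear sampling of the fraction
#' dose at the field-mapped positions, with 0 Gy outside the fraction-dose
#' extent and no energy/mass rescaling. The accumulation field must carry
#' the `plan_to_mod` tag (it maps planning positions into the fraction
#' anatomy).
#'
#' @param fraction_dose `scalar_volume` (Gy) on the treatment-image grid.
#' @param plan_to_mod `vector_field` tagged `plan_to_mod` on the plan grid.
#' @return Accumulated `scalar_volume` (Gy) on the field's grid.
#' @export
accumulate_dose_ddm <- function(fraction_dose, plan_to_mod) {
  if (fraction_dose$quantity != "Gy") stop("fraction_dose must be a Gy volume")
  if (plan_to_mod$direction != "plan_to_mod")
    stop(sprintf("accumulation field must be tagged 'plan_to_mod', got '%s'",
                 plan_to_mod$direction))
  warp_image(fraction_dose, plan_to_mod, plan_to_mod$grid,
             mode = "linear", fill = 0)
}

#' Voxel-wise sum of dose volumes on one grid
#'
#' @param doses list of `scalar_volume` (Gy) sharing a grid.
#' @return A `scalar_volume` (Gy).
#' @export
sum_doses <- function(doses) {
  if (length(doses) == 0) stop("no doses to sum")
  g <- doses[[1]]$grid
  acc <- array(0, dim = g$size)
  for (d in doses) {
    if (!grids_equal(d$grid, g)) stop("doses must share one grid")
    acc <- acc + d$values
  }
  scalar_volume(acc, g, "Gy")
}
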