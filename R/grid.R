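#' Axis-aligned volume grid
#'
#' Defines the physical lattice shared by CT volumes, dose volumes,
#' displacement fields and structure masks: voxel counts per axis, voxel
#' spacing in mm and the physical position (mm) of the *center* of voxel
#' index (1,1,1). Only identity-orientation, axis-aligned grids are
#' supported; the physical position of voxel (i,j,k) is
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param size integer vector of length 3, voxels per axis.
#' @param spacing numeric length 3, voxel spacing in mm (strictly positive).
#' @param origin numeric length 3, mm position of the first voxel center.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(size, spacing, origin = c(0, 0, 0)) {
  size <- as.integer(size)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(size) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(size < 1L)) stop("grid size must be >= 1 on every axis")
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive")
  structure(list(size = size, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$size[1], x$size[2], x$size[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Test two grids for equality
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance (mm) on spacing and origin.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$size, b$size) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel center coordinates along one axis
#' @param grid a `volume_grid`.
#' @param axis integer 1..3.
#' @return Numeric vector of voxel-center positions (mm).
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$size[axis]) - 1) * grid$spacing[axis]
}

#' Voxel volume in cubic centimeters
#' @param grid a `volume_grid`.
#' @return Voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# Arrays of the x/y/z physical coordinate at every voxel (used by the
# analytic phantom and field authoring; ~8 MB each at the default grid).
grid_coord_arrays <- function(grid) {
  n <- grid$size
  list(
    x = array(rep(grid_axis(grid, 1), times = n[2] * n[3]), dim = n),
    y = array(rep(rep(grid_axis(grid, 2), each = n[1]), times = n[3]), dim = n),
    z = array(rep(grid_axis(grid, 3), each = n[1] * n[2]), dim = n)
  )
}

#' Scalar volume on a grid
#'
#' A 3-D lattice of real values with physical geometry. `quantity` records
#' what the values are: Hounsfield units (`"HU"`), absorbed dose in Gy
#' (`"Gy"`) or a mask/mask-fraction in `[0, 1]` (`"mask"`).
#'
#' @param values 3-D numeric array whose dim equals `grid$size`.
#' @param grid a `volume_grid`.
#' @param quantity one of `"HU"`, `"Gy"`, `"mask"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, quantity = c("HU", "Gy", "mask")) {
  quantity <- match.arg(quantity)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$size))
    stop("values array shape does not match grid size")
  storage.mode(values) <- "double"
  if (quantity == "Gy" && any(values < 0))
    stop("dose volumes must be non-negative")
  structure(list(grid = grid, values = values, quantity = quantity),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<scalar_volume> [%s] %d x %d x %d, range [%.4g, %.4g]\n",
              x$quantity, x$grid$size[1], x$grid$size[2], x$grid$size[3],
              rng[1], rng[2]))
  invisible(x)
}

#' Displacement vector field
#'
#' Per-voxel 3-vectors of displacement in mm, physical space, pull-back
#' convention: a field `u` with tag `mod_to_plan` synthesizes the modified
#' image as `CT_Mod(x) = CT_Plan(x + u(x))`; a field `v` with tag
#' `plan_to_mod` accumulates dose as `D_acc(y) = D_fx(y + v(y))`. A field
#' and its inverse carry opposite tags.
#'
#' @param disp 4-D numeric array, dim `c(grid$size, 3)`, mm.
#' @param grid a `volume_grid`.
#' @param direction `"mod_to_plan"` or `"plan_to_mod"`.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(disp, grid, direction = c("mod_to_plan", "plan_to_mod")) {
  direction <- match.arg(direction)
  disp <- as.array(disp)
  if (!identical(as.integer(dim(disp)), c(grid$size, 3L)))
    stop("displacement array shape must be c(grid size, 3)")
  storage.mode(disp) <- "double"
  structure(list(grid = grid, disp = disp, direction = direction),
            class = "vector_field")
}

#' Zero displacement field
#' @param grid a `volume_grid`.
#' @param direction direction tag for the new field.
#' @return A `vector_field` of zeros.
#' @export
zero_field <- function(grid, direction = "mod_to_plan") {
  vector_field(array(0, dim = c(grid$size, 3L)), grid, direction)
}

#' @export
print.vector_field <- function(x, ...) {
  m <- field_magnitude(x)
  cat(sprintf("<vector_field> [%s] %d x %d x %d, |u| max %.3f mm\n",
              x$direction, x$grid$size[1], x$grid$size[2], x$grid$size[3],
              max(m$values)))
  invisible(x)
}

#' Per-voxel displacement magnitude
#' @param field a `vector_field`.
#' @return A `scalar_volume` (quantity `"mask"` is not meaningful here; the
#'   values are mm) holding the Euclidean norm of the displacement.
#' @export
field_magnitude <- function(field) {
  d <- field$disp
  mag <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  scalar_volume(array(mag, dim = field$grid$size), field$grid, "mask")
}

opposite_direction <- function(direction) {
  if (direction == "mod_to_plan") "plan_to_mod" else "mod_to_plan"
}

#' Named structure masks on a shared grid
#'
#' @param masks named list of 3-D arrays (logical or 0/1) on `grid`.
#' @param grid a `volume_grid`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, grid) {
  if (is.null(names(masks)) || any(names(masks) == "") || anyDuplicated(names(masks)))
    stop("structure masks must have unique non-empty names")
  masks <- lapply(masks, function(m) {
    m <- as.array(m)
    if (!identical(as.integer(dim(m)), grid$size))
      stop("every mask must share the structure set grid")
    if (is.logical(m)) m <- m * 1
    storage.mode(m) <- "double"
    if (!all(m %in% c(0, 1))) stop("masks must be binary")
    m
  })
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vv <- voxel_volume_cc(x$grid)
  cat(sprintf("<structure_set> %d structures on %d x %d x %d grid\n",
              length(x$masks), x$grid$size[1], x$grid$size[2], x$grid$size[3]))
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %8.1f cc\n", nm, sum(x$masks[[nm]]) * vv))
  invisible(x)
}

get_mask <- function(structures, name) {
  if (!name %in% names(structures$masks))
    stop(sprintf("unknown structure '%s'", name))
  structures$masks[[name]]
}

#' Sample a scalar volume at physical points
#'
#' Trilinear (or nearest-neighbor) interpolation at arbitrary physical
#' points in mm. Points outside the grid's physical extent (the hull of
#' voxel centers) return `fill`.
#'
#' @param vol a `scalar_volume`.
#' @param points n x 3 numeric matrix of mm coordinates.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill value returned for out-of-extent points. Defaults to the
#'   physically motivated fill for the volume's quantity: -1000 HU (air),
#'   0 Gy, 0 mask.
#' @return Numeric vector of sampled values.
#' @export
sample_scalar <- function(vol, points, mode = c("linear", "nearest"), fill = NULL) {
  mode <- match.arg(mode)
  if (is.null(fill)) fill <- default_fill(vol$quantity)
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_sample(vol$values, vol$grid$size, vol$grid$spacing, vol$grid$origin,
             points, mode == "linear", fill)
}

default_fill <- function(quantity) {
  switch(quantity, HU = -1000, Gy = 0, mask = 0)
}

#' Resample a scalar volume onto a target grid
#'
#' @param vol a `scalar_volume`.
#' @param target a `volume_grid`.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill out-of-extent fill value (defaults per quantity).
#' @return A `scalar_volume` on `target`. Resampling to the volume's own
#'   grid returns the values unchanged.
#' @export
resample_to_grid <- function(vol, target, mode = c("linear", "nearest"), fill = NULL) {
  mode <- match.arg(mode)
  if (grids_equal(vol$grid, target)) return(scalar_volume(vol$values, target, vol$quantity))
  if (is.null(fill)) fill <- default_fill(vol$quantity)
  vals <- cpp_warp(vol$values, vol$grid$size, vol$grid$spacing, vol$grid$origin,
                   numeric(0), integer(3), numeric(3), numeric(3),
                   target$size, target$spacing, target$origin,
                   mode == "linear", fill)
  scalar_volume(array(vals, dim = target$size), target, vol$quantity)
}

#' Resample a vector field onto a target grid
#'
#' Each displacement component is interpolated trilinearly; outside the
#' field's extent the edge value is held (constant extrapolation), matching
#' how coarse registration fields are evaluated against full-resolution
#' volumes.
#'
#' @param field a `vector_field`.
#' @param target a `volume_grid`.
#' @return A `vector_field` on `target` with the same direction tag.
#' @export
resample_field <- function(field, target) {
  if (grids_equal(field$grid, target)) return(field)
  pts <- grid_coord_arrays(target)
  n <- prod(target$size)
  out <- array(0, dim = c(target$size, 3L))
  g <- field$grid
  # clamp to the source lattice, then trilinear per component
  cx <- pmin(pmax((as.vector(pts$x) - g$origin[1]) / g$spacing[1], 0), g$size[1] - 1)
  cy <- pmin(pmax((as.vector(pts$y) - g$origin[2]) / g$spacing[2], 0), g$size[2] - 1)
  cz <- pmin(pmax((as.vector(pts$z) - g$origin[3]) / g$spacing[3], 0), g$size[3] - 1)
  p <- cbind(g$origin[1] + cx * g$spacing[1],
             g$origin[2] + cy * g$spacing[2],
             g$origin[3] + cz * g$spacing[3])
  for (c_i in 1:3) {
    out[, , , c_i] <- array(
      cpp_sample(field$disp[, , , c_i], g$size, g$spacing, g$origin, p, TRUE, 0),
      dim = target$size)
  }
  vector_field(out, target, field$direction)
}
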