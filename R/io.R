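# NIfTI-1 I/O through RNifti, with a JSON sidecar carrying the metadata
# NIfTI cannot (quantity of a scalar volume, direction tag of a field).
# Only axis-aligned, identity-orientation images are accepted: the readers
# reject oblique volumes rather than silently resampling them.

volume_xform <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]
  m[2, 2] <- grid$spacing[2]
  m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  m
}

grid_from_xform <- function(xf, size, path) {
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  if (any(sp <= 0)) stop(sprintf("'%s': degenerate voxel spacing", path))
  dir <- sweep(rot, 2, sp, "/")
  if (max(abs(dir - diag(3))) > 1e-4)
    stop(sprintf(paste0("'%s': non-axis-aligned orientation; only identity-",
                        "direction volumes are supported"), path))
  volume_grid(size, sp, xf[1:3, 4])
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a scalar volume or vector field to NIfTI
#'
#' Scalar volumes are written as 3-D NIfTI; vector fields as 4-D NIfTI with
#' the displacement component as the 4th dimension. A JSON sidecar
#' (same name, `.json`) records the quantity or direction tag so that
#' `read_volume()` round-trips the object exactly.
#'
#' @param obj a `scalar_volume` or `vector_field`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "scalar_volume")) {
    arr <- obj$values
    meta <- list(type = "scalar_volume", quantity = obj$quantity)
  } else if (inherits(obj, "vector_field")) {
    arr <- obj$disp
    meta <- list(type = "vector_field", direction_tag = obj$direction)
  } else stop("obj must be a scalar_volume or vector_field")
  grid <- obj$grid
  img <- RNifti::asNifti(arr, datatype = "double")
  xf <- volume_xform(grid)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a scalar volume or vector field from NIfTI
#'
#' The JSON sidecar written by [write_volume()] determines the object type;
#' without a sidecar, 3-D images are read as scalar volumes of `quantity`
#' and 4-D images with a 3-long 4th dimension as vector fields of
#' `direction`. Oblique (non-axis-aligned) images are rejected.
#'
#' @param path NIfTI file path.
#' @param quantity fallback quantity for sidecar-less scalar volumes.
#' @param direction fallback direction tag for sidecar-less vector fields.
#' @return A `scalar_volume` or `vector_field`.
#' @export
read_volume <- function(path, quantity = "HU", direction = "mod_to_plan") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage attributes
  d <- dim(arr)
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc)
  if (length(d) == 4 && d[4] == 1) { arr <- arr[, , , 1, drop = TRUE]; d <- dim(arr) }
  if (length(d) == 3) {
    grid <- grid_from_xform(xf, d, path)
    q <- if (!is.null(meta$quantity)) meta$quantity else quantity
    scalar_volume(arr, grid, q)
  } else if (length(d) == 4) {
    if (d[4] != 3)
      stop(sprintf("'%s': vector field must have 3 components, found %d", path, d[4]))
    grid <- grid_from_xform(xf, d[1:3], path)
    dir_tag <- if (!is.null(meta$direction_tag)) meta$direction_tag else direction
    vector_field(arr, grid, dir_tag)
  } else {
    stop(sprintf("'%s': unsupported image dimensionality (%d-D)", path, length(d)))
  }
}

#' Write a structure set as per-structure NIfTI masks plus a JSON name map
#'
#' Masks may overlap (CTV inside PTV inside body), so each structure is
#' written as its own binary NIfTI; `<prefix>.json` maps structure names to
#' file names.
#'
#' @param structures a `structure_set`.
#' @param prefix output path prefix; files are written as
#'   `<prefix>_<name>.nii.gz` and `<prefix>.json`.
#' @return The JSON index path, invisibly.
#' @export
write_structure_set <- function(structures, prefix) {
  files <- list()
  for (nm in names(structures$masks)) {
    f <- paste0(prefix, "_", nm, ".nii.gz")
    write_volume(scalar_volume(structures$masks[[nm]], structures$grid, "mask"), f)
    files[[nm]] <- basename(f)
  }
  idx <- paste0(prefix, ".json")
  jsonlite::write_json(list(type = "structure_set", structures = files),
                       idx, auto_unbox = TRUE)
  invisible(idx)
}

#' Read a structure set written by [write_structure_set()]
#'
#' @param index_path path to the `<prefix>.json` name map.
#' @return A `structure_set`.
#' @export
read_structure_set <- function(index_path) {
  meta <- jsonlite::read_json(index_path)
  dirn <- dirname(index_path)
  masks <- list()
  grid <- NULL
  for (nm in names(meta$structures)) {
    vol <- read_volume(file.path(dirn, meta$structures[[nm]]), quantity = "mask")
    if (is.null(grid)) grid <- vol$grid
    else if (!grids_equal(grid, vol$grid)) stop("structure masks disagree on grid")
    masks[[nm]] <- vol$values >= 0.5
  }
  structure_set(masks, grid)
}
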