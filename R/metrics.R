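#' Per-structure displacement-magnitude statistics
#'
#' Maximum and mean Euclidean displacement magnitude of a field over each
#' structure of the planning structure set — the per-structure
#' range-of-motion summary used to characterize authored and estimated
#' deformations. The field is resampled to the structure grid if needed.
#'
#' @param field a `vector_field`.
#' @param structures a `structure_set`.
#' @return data.frame with columns `structure`, `max_dvf_mm`, `mean_dvf_mm`.
#' @export
dvf_stats_per_structure <- function(field, structures) {
  field <- resample_field(field, structures$grid)
  mag <- field_magnitude(field)$values
  rows <- lapply(names(structures$masks), function(nm) {
    m <- structures$masks[[nm]] != 0
    if (!any(m)) stop(sprintf("structure '%s' is empty", nm))
    data.frame(structure = nm, max_dvf_mm = max(mag[m]), mean_dvf_mm = mean(mag[m]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Voxel-wise displacement error between two fields
#'
#' Statistics of `|u_est - u_true|` over a mask — the voxel-wise comparison
#' that per-structure maxima cannot provide (similar maxima do not imply
#' agreement). Fields must share a direction tag; the estimated field is
#' resampled onto the truth's grid.
#'
#' @param estimated,truth `vector_field` objects with equal direction tags.
#' @param mask binary array on the truth grid.
#' @return List with `max_mm` and `mean_mm`.
#' @export
dvf_error <- function(estimated, truth, mask) {
  if (estimated$direction != truth$direction)
    stop("fields have mismatched direction tags")
  estimated <- resample_field(estimated, truth$grid)
  mask <- as.array(mask) != 0
  d <- estimated$disp - truth$disp
  err <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)[mask]
  list(max_mm = max(err), mean_mm = mean(err))
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks are defined as identical
#' (DSC 1).
#'
#' @param a,b binary arrays on one grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as.array(a) != 0; b <- as.array(b) != 0
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

mask_surface <- function(mask) {
  # 6-connected single-voxel erosion difference
  d <- dim(mask)
  er <- mask
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    er <- er & shift_and(mask, ax, 1) & shift_and(mask, ax, -1)
  }
  # voxels at the array border count as surface
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  mask & (!er | border)
}

#' Hausdorff distance between two masks
#'
#' Symmetric surface distance in physical mm: surfaces are extracted as the
#' single-voxel erosion difference and distances computed with the
#' anisotropic Euclidean distance transform. The default (100th percentile)
#' is the classical maximum Hausdorff distance; `percentile = 95` gives the
#' robust HD95 variant.
#'
#' @param a,b non-empty binary arrays on one grid.
#' @param spacing voxel spacing in mm.
#' @param percentile percentile of the directed surface distances
#'   (default 100 = maximum).
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b, spacing, percentile = 100) {
  a <- as.array(a) != 0; b <- as.array(b) != 0
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  if (!any(a) || !any(b)) stop("hausdorff needs two non-empty masks")
  sa <- mask_surface(a); sb <- mask_surface(b)
  da <- cpp_edt(sb * 1, dim(b), spacing)[sa]  # distance of A-surface to B-surface
  db <- cpp_edt(sa * 1, dim(a), spacing)[sb]
  p <- percentile / 100
  max(stats::quantile(da, p, names = FALSE), stats::quantile(db, p, names = FALSE))
}

#' Contour-consistency metrics for matched structure sets
#'
#' @param set_a,set_b `structure_set` objects on one grid.
#' @param structures structure names to compare (defaults to those present
#'   in both sets).
#' @return data.frame with `structure`, `dsc`, `hd_mm`.
#' @export
contour_metrics <- function(set_a, set_b,
                            structures = intersect(names(set_a$masks),
                                                   names(set_b$masks))) {
  if (!grids_equal(set_a$grid, set_b$grid)) stop("structure sets must share a grid")
  sp <- set_a$grid$spacing
  rows <- lapply(structures, function(nm) {
    ma <- set_a$masks[[nm]] != 0
    mb <- set_b$masks[[nm]] != 0
    data.frame(structure = nm,
               dsc = dice(ma, mb),
               hd_mm = if (any(ma) && any(mb)) hausdorff(ma, mb, sp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
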