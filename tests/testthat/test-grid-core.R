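test_that("grids validate their geometry", {
  expect_error(volume_grid(c(4, 4, 4), c(1, 0, 1)), "strictly positive")
  g <- volume_grid(c(4, 5, 6), c(1, 2, 3), c(-1, -2, -3))
  expect_equal(grid_axis(g, 2), c(-2, 0, 2, 4, 6))
  expect_equal(voxel_volume_cc(g), 6 / 1000)
  expect_true(grids_equal(g, g))
  expect_false(grids_equal(g, volume_grid(c(4, 5, 6), c(1, 2, 3))))
})

test_that("scalar volumes enforce shape and dose positivity", {
  g <- volume_grid(c(3, 3, 3), c(1, 1, 1))
  expect_error(scalar_volume(array(0, c(2, 3, 3)), g), "shape")
  expect_error(scalar_volume(array(-1, c(3, 3, 3)), g, "Gy"), "non-negative")
  v <- scalar_volume(array(7, c(3, 3, 3)), g, "HU")
  expect_equal(v$quantity, "HU")
})

test_that("on-lattice sampling returns stored values; constants are constant", {
  g <- volume_grid(c(5, 5, 5), c(2, 2, 2), c(0, 0, 0))
  vals <- array(seq_len(125), dim = c(5, 5, 5))
  v <- scalar_volume(vals, g, "HU")
  pts <- as.matrix(expand.grid(x = c(0, 2, 8), y = c(0, 4), z = c(2, 6)))
  idx <- cbind(pts[, 1] / 2 + 1, pts[, 2] / 2 + 1, pts[, 3] / 2 + 1)
  expect_equal(sample_scalar(v, pts), vals[idx])
  u <- scalar_volume(array(7, c(5, 5, 5)), g, "HU")
  expect_equal(sample_scalar(u, cbind(runif(10, 0, 8), runif(10, 0, 8), runif(10, 0, 8))),
               rep(7, 10))
})

test_that("trilinear sampling reproduces affine functions of position", {
  g <- volume_grid(c(8, 8, 8), c(1, 1, 1))
  co <- dosewarpqa:::grid_coord_arrays(g)
  v <- scalar_volume(co$x, g, "HU")  # f(x) = x1
  expect_equal(sample_scalar(v, matrix(c(2.5, 3, 3), 1)), 2.5)
  aff <- scalar_volume(2 * co$x - 3 * co$y + 0.5 * co$z + 1, g, "HU")
  set.seed(1)
  pts <- cbind(runif(30, 0.5, 6.5), runif(30, 0.5, 6.5), runif(30, 0.5, 6.5))
  expect_equal(sample_scalar(aff, pts),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 1, tolerance = 1e-10)
})

test_that("out-of-extent points return the fill value", {
  g <- volume_grid(c(4, 4, 4), c(1, 1, 1))
  v <- scalar_volume(array(5, c(4, 4, 4)), g, "HU")
  expect_equal(sample_scalar(v, matrix(c(10, 0, 0), 1)), -1000)
  expect_equal(sample_scalar(v, matrix(c(10, 0, 0), 1), fill = 99), 99)
})

test_that("resampling to the same grid is the identity; linear ramps survive down-up", {
  g <- volume_grid(c(17, 17, 9), c(2, 2, 4))
  co <- dosewarpqa:::grid_coord_arrays(g)
  ramp <- scalar_volume(co$x, g, "HU")
  expect_identical(resample_to_grid(ramp, g)$values, ramp$values)
  coarse <- volume_grid(c(9, 9, 5), c(4, 4, 8), g$origin)
  down <- resample_to_grid(ramp, coarse)
  up <- resample_to_grid(down, g)
  interior <- up$values[3:15, 3:15, 3:7]
  expect_equal(interior, ramp$values[3:15, 3:15, 3:7], tolerance = 1e-9)
  const <- scalar_volume(array(3, g$size), g, "Gy")
  expect_true(all(resample_to_grid(const, coarse)$values == 3))
})

test_that("NIfTI round trips preserve geometry and values bit-exactly", {
  ph <- small_phantom()
  d <- synth_fraction_dose(ph$structures, ph$rx, "imrt9")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(d, f)
  d2 <- read_volume(f)
  expect_identical(d2$values, d$values)
  expect_true(grids_equal(d2$grid, d$grid))
  expect_equal(d2$quantity, "Gy")

  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(u, f2)
  u2 <- read_volume(f2)
  expect_identical(u2$disp, u$disp)
  expect_equal(u2$direction, "mod_to_plan")

  prefix <- file.path(tempdir(), "structs")
  idx <- write_structure_set(ph$structures, prefix)
  ss <- read_structure_set(idx)
  for (nm in names(ph$structures$masks))
    expect_equal(ss$masks[[nm]] * 1, ph$structures$masks[[nm]] * 1)
})

test_that("readers reject missing files and oblique orientations", {
  expect_error(read_volume(tempfile(fileext = ".nii.gz")), "no such file")
  # an oblique image: 10-degree in-plane rotation
  arr <- array(stats::runif(4^3), dim = c(4, 4, 4))
  img <- RNifti::asNifti(arr, datatype = "double")
  th <- 10 * pi / 180
  xf <- diag(4)
  xf[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  RNifti::sform(img) <- structure(xf, code = 2L)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "axis-aligned")
})

test_that("vector fields reject malformed component counts", {
  arr <- array(stats::runif(4^3 * 2), dim = c(4, 4, 4, 2))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::sform(img) <- structure(diag(4), code = 2L)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3 components")
})
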