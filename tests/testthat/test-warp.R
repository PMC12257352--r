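test_that("warping with the zero field is the identity on a shared grid", {
  ph <- small_phantom()
  z <- zero_field(ph$ct$grid)
  out <- warp_image(ph$ct, z, ph$ct$grid)
  expect_identical(out$values, ph$ct$values)
})

test_that("a constant field shifts a linear ramp by the closed-form amount", {
  g <- volume_grid(c(20, 12, 12), c(1, 2, 2))
  co <- dosewarpqa:::grid_coord_arrays(g)
  ramp <- scalar_volume(co$x, g, "HU")
  f <- zero_field(g)
  f$disp[, , , 1] <- 5
  out <- warp_image(ramp, f, g)
  interior <- 1:14  # x + 5 mm stays inside the extent for these columns
  expect_equal(out$values[interior, , ], co$x[interior, , ] + 5, tolerance = 1e-9)
})

test_that("mask warp and inverse warp round-trips organs with high overlap", {
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  v <- invert_field(u)
  for (nm in c("bladder", "prostate", "PTV")) {
    m <- ph$structures$masks[[nm]] != 0
    fwd <- warp_mask(m, ph$structures$grid, u)
    back <- warp_mask(fwd, ph$structures$grid, v)
    expect_gt(dice(m, back), 0.98)
  }
})

test_that("field inversion matches closed forms", {
  g <- volume_grid(c(16, 16, 16), c(2, 2, 2), c(-15, -15, -15))
  z <- zero_field(g)
  vz <- invert_field(z)
  expect_true(all(vz$disp == 0))
  expect_equal(attr(vz, "residual_mm"), 0)
  expect_equal(vz$direction, "plan_to_mod")

  tr <- z
  tr$disp[, , , 1] <- 3
  tr$disp[, , , 2] <- -2
  vt <- invert_field(tr)
  expect_equal(max(abs(vt$disp[, , , 1] + 3)), 0, tolerance = 1e-9)
  expect_equal(max(abs(vt$disp[, , , 2] - 2)), 0, tolerance = 1e-9)

  co <- dosewarpqa:::grid_coord_arrays(g)
  aff <- z
  for (c_i in 1:3) aff$disp[, , , c_i] <- 0.1 * list(co$x, co$y, co$z)[[c_i]]
  va <- invert_field(aff)
  # closed form: inverse of x -> 1.1 x is x -> x / 1.1
  interior <- 5:12
  for (c_i in 1:3) {
    want <- -(0.1 / 1.1) * list(co$x, co$y, co$z)[[c_i]][interior, interior, interior]
    expect_equal(va$disp[interior, interior, interior, c_i], want, tolerance = 0.05)
  }
  expect_lt(attr(va, "residual_mm"), 0.25)
})

test_that("inverting twice returns the original field", {
  # smooth analytic field: the double-inverse property at 2x tolerance
  g <- volume_grid(c(40, 40, 40), c(2, 2, 2), c(-39, -39, -39))
  co <- dosewarpqa:::grid_coord_arrays(g)
  f <- zero_field(g)
  f$disp[, , , 1] <- 5 * sin(2 * pi * co$x / 80)
  f$disp[, , , 2] <- 3 * sin(2 * pi * co$y / 80)
  ff <- invert_field(invert_field(f))
  d <- ff$disp - f$disp
  err <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  expect_lt(max(err[5:36, 5:36, 5:36]), 2 * 0.05)
  expect_equal(ff$direction, f$direction)

  # lattice-sampled authored field: interpolation of the stored field adds
  # error of order curvature * spacing^2 on this coarse grid
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  body <- ph$structures$masks$body != 0
  uu <- invert_field(invert_field(u, mask = body), mask = body)
  d2 <- uu$disp - u$disp
  err2 <- sqrt(d2[, , , 1]^2 + d2[, , , 2]^2 + d2[, , , 3]^2)
  expect_lt(max(err2[body]), 0.5)
})

test_that("composition has the zero field as identity and adds translations", {
  g <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  z <- zero_field(g)
  f <- z
  f$disp[, , , 1] <- 4
  f$disp[, , , 3] <- -1
  expect_equal(compose_fields(z, f)$disp, f$disp)
  expect_equal(compose_fields(f, z)$disp, f$disp)
  h <- z
  h$disp[, , , 1] <- -1
  h$disp[, , , 2] <- 2
  w <- compose_fields(h, f)
  expect_true(all(abs(w$disp[, , , 1] - 3) < 1e-9))
  expect_true(all(abs(w$disp[, , , 2] - 2) < 1e-9))
  expect_true(all(abs(w$disp[, , , 3] + 1) < 1e-9))
})

test_that("composing a field with its inverse is near zero over the body", {
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 4)))
  v <- invert_field(u)
  w <- compose_fields(v, u)
  body <- ph$structures$masks$body != 0
  expect_lt(max(field_magnitude(w)$values[body]), 0.5)
})

test_that("direct dose mapping reduces to sampling and respects closed forms", {
  g <- volume_grid(c(20, 12, 12), c(1, 2, 2))
  co <- dosewarpqa:::grid_coord_arrays(g)
  dose <- scalar_volume(co$x + 20, g, "Gy")  # f(x) = x1 + 20, gradient 1 Gy/mm
  z <- zero_field(g, "plan_to_mod")
  expect_identical(accumulate_dose_ddm(dose, z)$values, dose$values)
  f <- zero_field(g, "plan_to_mod")
  f$disp[, , , 1] <- 3
  acc <- accumulate_dose_ddm(dose, f)
  interior <- 1:16
  expect_equal(acc$values[interior, , ], dose$values[interior, , ] + 3, tolerance = 1e-9)
  wrong <- zero_field(g, "mod_to_plan")
  expect_error(accumulate_dose_ddm(dose, wrong), "plan_to_mod")
})

test_that("DDM is linear in dose and conserves the dose range", {
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  v <- invert_field(u)
  d1 <- synth_fraction_dose(ph$structures, ph$rx, "imrt9")
  d2 <- scalar_volume(d1$values * 0.5 + 0.1, d1$grid, "Gy")
  both <- accumulate_dose_ddm(sum_doses(list(d1, d2)), v)
  sep <- sum_doses(list(accumulate_dose_ddm(d1, v), accumulate_dose_ddm(d2, v)))
  expect_equal(both$values, sep$values, tolerance = 1e-9)
  acc <- accumulate_dose_ddm(d1, v)
  expect_gte(min(acc$values), min(d1$values))
  expect_lte(max(acc$values), max(d1$values))
})

test_that("accumulating the warped plan dose through the true inverse returns the plan dose", {
  ph <- full_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  v <- invert_field(u)
  d_plan <- synth_fraction_dose(ph$structures, ph$rx, "imrt9")
  d_fx <- warp_image(d_plan, u, ph$ct$grid)  # the fraction dose is the warped plan dose
  acc <- accumulate_dose_ddm(d_fx, v)
  ptv <- ph$structures$masks$PTV != 0
  expect_lt(mean(abs(acc$values[ptv] - d_plan$values[ptv])),
            0.005 * max(d_plan$values))
})

test_that("dose sums are permutation invariant and scale with copies", {
  g <- volume_grid(c(5, 5, 5), c(2, 2, 2))
  set.seed(4)
  ds <- lapply(1:3, function(i) scalar_volume(array(runif(125), c(5, 5, 5)), g, "Gy"))
  expect_identical(sum_doses(ds[1])$values, ds[[1]]$values)
  expect_equal(sum_doses(ds)$values, sum_doses(rev(ds))$values)
  expect_equal(sum_doses(list(ds[[1]], ds[[1]], ds[[1]]))$values, 3 * ds[[1]]$values)
  other <- scalar_volume(array(1, c(5, 5, 5)), volume_grid(c(5, 5, 5), c(1, 1, 1)), "Gy")
  expect_error(sum_doses(list(ds[[1]], other)), "share")
})
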