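test_that("self-registration returns a near-zero field", {
  ph <- small_phantom()
  est <- estimate_field(ph$ct, ph$ct, registration_params())
  expect_lt(max(field_magnitude(est)$values), 0.5)
  expect_equal(est$direction, "plan_to_mod")
})

test_that("registration recovers a medium bladder change at study resolution", {
  ph <- full_phantom()
  body <- ph$structures$masks$body != 0
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  ct_mod <- warp_image(ph$ct, u, ph$ct$grid)
  phi_true <- invert_field(u, mask = body)
  est <- estimate_field(ph$ct, ct_mod, registration_params())
  err <- dvf_error(est, phi_true, body)
  expect_lt(err$mean_mm, 3)
  # the estimate is itself a valid (invertible) deformation
  expect_true(verify_invertibility(est)$ok)
  # image criterion: body MSE reduced by at least half versus unregistered
  w <- warp_image(ct_mod, resample_field(est, ph$ct$grid), ph$ct$grid)
  mse1 <- mean((w$values[body] - ph$ct$values[body])^2)
  mse0 <- mean((ct_mod$values[body] - ph$ct$values[body])^2)
  expect_lt(mse1, 0.5 * mse0)
  # exported field grid is coarsened by the configured factor
  expect_equal(est$grid$size, dosewarpqa:::coarsen_grid(ph$ct$grid, 4)$size)
})

test_that("an extreme expansion still halves the mean field error", {
  # the 30 mm bladder expansion drags the gas-filled rectum by > 20 mm;
  # an unguided intensity registration cannot fully recover the thin
  # displaced gas interface, but its field error must still be far below
  # the unregistered baseline
  ph <- full_phantom()
  body <- ph$structures$masks$body != 0
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 30)))
  ct_mod <- warp_image(ph$ct, u, ph$ct$grid)
  phi_true <- invert_field(u, mask = body)
  est <- estimate_field(ph$ct, ct_mod, registration_params())
  err <- dvf_error(est, phi_true, body)
  base <- dvf_error(zero_field(ph$ct$grid, "plan_to_mod"), phi_true, body)
  expect_lt(err$mean_mm, 0.5 * base$mean_mm)
})

test_that("registration improves on the unregistered baseline for a rectum change", {
  # the gas-filled rectum is the hard case for an unguided intensity DIR:
  # the 790 HU interface saturates the demons force and the organ interior
  # is texture-poor, so improvement is real but partial
  ph <- full_phantom()
  body <- ph$structures$masks$body != 0
  u <- author_field(ph$structures,
                    scenario_presets("prostate_like")$rectum_med_expand)
  ct_mod <- warp_image(ph$ct, u, ph$ct$grid)
  phi_true <- invert_field(u, mask = body)
  est <- estimate_field(ph$ct, ct_mod, registration_params())
  err <- dvf_error(est, phi_true, body)
  base <- dvf_error(zero_field(ph$ct$grid, "plan_to_mod"), phi_true, body)
  expect_lt(err$mean_mm, 0.9 * base$mean_mm)
})

test_that("the degradation knob monotonically worsens the estimate", {
  ph <- small_phantom()
  body <- ph$structures$masks$body != 0
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  ct_mod <- warp_image(ph$ct, u, ph$ct$grid)
  phi_true <- invert_field(u, mask = body)
  errs <- vapply(c(0, 0.5, 1), function(d) {
    est <- estimate_field(ph$ct, ct_mod, registration_params(degrade_factor = d))
    dvf_error(est, phi_true, body)$mean_mm
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  # fully degraded is no better than not registering at all
  base <- dvf_error(zero_field(ph$ct$grid, "plan_to_mod"), phi_true, body)
  expect_gte(errs[3], base$mean_mm)
})

test_that("the oracle registration is the inverted truth", {
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  o <- register_with_oracle(u)
  expect_equal(o$direction, "plan_to_mod")
  z <- zero_field(ph$ct$grid, "mod_to_plan")
  oz <- register_with_oracle(z)
  expect_true(all(oz$disp == 0))
  expect_error(register_with_oracle(o), "mod_to_plan")
})

test_that("registration is deterministic under a fixed seed", {
  ph <- small_phantom()
  u <- author_field(ph$structures, list(deformation_spec("bladder", "expand", 7.5)))
  ct_mod <- warp_image(ph$ct, u, ph$ct$grid)
  p <- registration_params(degrade_factor = 0.5, seed = 9)
  e1 <- estimate_field(ph$ct, ct_mod, p)
  e2 <- estimate_field(ph$ct, ct_mod, p)
  expect_identical(e1$disp, e2$disp)
})
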