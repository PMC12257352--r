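test_that("the prostate phantom ships the expected structures with nested targets", {
  ph <- small_phantom()
  expect_setequal(names(ph$structures$masks),
                  c("body", "bladder", "rectum", "prostate", "CTV", "PTV",
                    "femur_L", "femur_R"))
  m <- ph$structures$masks
  expect_true(all(m$CTV <= m$PTV))
  expect_true(all(m$PTV <= m$body))
  for (nm in setdiff(names(m), "body"))
    expect_true(all(m[[nm]] <= m$body))
  expect_equal(ph$rx$total_dose_Gy, 60)
  expect_equal(ph$rx$n_fractions, 20L)
  expect_length(ph$rx$goal_set, 22)
})

test_that("the cervix phantom carries uterus, bowel and its prescription", {
  ph <- small_phantom("cervix_like")
  expect_true(all(c("uterus", "bowel", "CTV", "PTV") %in% names(ph$structures$masks)))
  expect_equal(ph$rx$total_dose_Gy, 45)
  expect_equal(ph$rx$n_fractions, 25L)
  # target centroid sits at the grid's geometric center
  co <- dosewarpqa:::grid_coord_arrays(ph$structures$grid)
  idx <- which(ph$structures$masks$uterus != 0)
  expect_lt(abs(mean(co$x[idx])), 4)
  expect_lt(abs(mean(co$y[idx])), 18)  # ellipsoid center offset is part of the anatomy
})

test_that("zero PTV margin makes PTV equal CTV; phantoms are deterministic", {
  cfg <- phantom_config(size = c(48, 48, 24), spacing = c(5, 5, 6),
                        ptv_margin_mm = 0, seed = 11)
  ph <- build_phantom(cfg)
  expect_identical(ph$structures$masks$PTV, ph$structures$masks$CTV)
  ph2 <- build_phantom(cfg)
  expect_identical(ph2$ct$values, ph$ct$values)
  expect_identical(ph2$structures$masks, ph$structures$masks)
})

test_that("margin expansion matches a brute-force distance check and is monotone", {
  mask <- array(FALSE, dim = c(9, 9, 9))
  mask[5, 5, 5] <- TRUE
  sp <- c(1, 1, 1)
  out <- expand_margin(mask, 2, sp)
  co <- dosewarpqa:::grid_coord_arrays(volume_grid(c(9, 9, 9), sp))
  brute <- sqrt((co$x - 4)^2 + (co$y - 4)^2 + (co$z - 4)^2) <= 2
  expect_equal(out, brute)
  expect_identical(expand_margin(mask, 0, sp), mask)
  ph <- small_phantom()
  m <- ph$structures$masks$prostate != 0
  prev <- m
  for (mm in c(2, 5, 9)) {
    cur <- expand_margin(m, mm, ph$structures$grid$spacing)
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("the fraction dose honors the prescription plateau and body cutoff", {
  ph <- small_phantom()
  d <- synth_fraction_dose(ph$structures, ph$rx, "imrt9")
  rx_fx <- ph$rx$total_dose_Gy / ph$rx$n_fractions
  expect_equal(sample_scalar(d, matrix(0, 1, 3)) / rx_fx, 1, tolerance = 0.02)
  ptv <- ph$structures$masks$PTV != 0
  expect_gte(max(d$values[ptv]) / rx_fx, 1)
  expect_lte(max(d$values[ptv]) / rx_fx, 1.07)
  expect_true(all(d$values[ph$structures$masks$body == 0] == 0))
  # course-dose invariant: PTV mean of n_fx fractions within [98%, 105%]
  course <- scale_to_course(d, ph$rx$n_fractions)
  expect_gte(mean(course$values[ptv]) / ph$rx$total_dose_Gy, 0.98)
  expect_lte(mean(course$values[ptv]) / ph$rx$total_dose_Gy, 1.05)
  expect_error(synth_fraction_dose(
    structure_set(list(body = ph$structures$masks$body,
                       PTV = array(0, ph$structures$grid$size)),
                  ph$structures$grid), ph$rx), "empty")
})

test_that("a vmat sweep has smoother angular falloff than nine discrete beams", {
  ph <- small_phantom()
  di <- synth_fraction_dose(ph$structures, ph$rx, "imrt9")
  dv <- synth_fraction_dose(ph$structures, ph$rx, "vmat")
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  pts <- cbind(60 * cos(th), 60 * sin(th), 0)
  var_imrt <- diff(range(sample_scalar(di, pts)))
  var_vmat <- diff(range(sample_scalar(dv, pts)))
  expect_lt(var_vmat, var_imrt)
})

test_that("shipped goal sets parse into the clinical goal grammar", {
  gp <- default_goal_set("prostate_like")
  expect_length(gp, 22)
  expect_true(all(vapply(gp, inherits, logical(1), "clinical_goal")))
  gc_ <- default_goal_set("cervix_like")
  expect_true(all(vapply(gc_, function(g) g$direction %in% c("less_than", "greater_than"),
                         logical(1))))
})
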