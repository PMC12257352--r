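test_that("metric and goal strings parse per the clinical grammar", {
  m <- parse_metric("D0.03cc")
  expect_equal(m$type, "D_cc")
  expect_equal(m$param, 0.03)
  expect_equal(parse_metric("V52.8Gy")$param, 52.8)
  expect_error(parse_metric("Q5%"), "parse")

  g <- parse_goal("rectum", "V60Gy < 3% (10%)")
  expect_equal(g$direction, "less_than")
  expect_equal(g$threshold, 3)
  expect_equal(g$variation, 10)
  expect_equal(g$report_unit, "%")
  g2 <- parse_goal("CTV", "D95% > 100%")
  expect_equal(g2$direction, "greater_than")
  expect_null(g2$variation)
  expect_equal(g2$report_unit, "Gy")
  g3 <- parse_goal("bowel", "V45Gy < 50cc")
  expect_equal(g3$threshold_unit, "cc")
})

test_that("uniform doses give trivial DVH metrics", {
  g <- volume_grid(c(10, 10, 10), c(10, 10, 10))  # 1 cc voxels
  mask <- array(TRUE, dim = c(10, 10, 10))
  d <- scalar_volume(array(60, dim = c(10, 10, 10)), g, "Gy")
  expect_equal(eval_metric(d, mask, "D95%"), 60)
  expect_equal(eval_metric(d, mask, "V60Gy"), 100)
  expect_equal(eval_metric(d, mask, "D0.03cc"), 60)
  d45 <- scalar_volume(array(45, dim = c(10, 10, 10)), g, "Gy")
  small_mask <- array(FALSE, dim = c(10, 10, 10)); small_mask[1, 1, 1] <- TRUE  # 1 cc
  expect_equal(eval_metric(d45, small_mask, "D0.03cc"), 45)
})

test_that("a linear 0-100 Gy dose gives the closed-form D95 and V50", {
  n <- 1000
  g <- volume_grid(c(n, 1, 1), c(10, 10, 10))
  mask <- array(TRUE, dim = c(n, 1, 1))
  d <- scalar_volume(array(seq(0, 100, length.out = n), dim = c(n, 1, 1)), g, "Gy")
  expect_equal(eval_metric(d, mask, "D95%"), 5, tolerance = 0.1)
  expect_equal(eval_metric(d, mask, "V50Gy"), 50, tolerance = 0.2)
  expect_equal(eval_metric(d, mask, "D100%"), min(d$values))
})

test_that("DVH metrics agree with an independent quantile oracle on random doses", {
  set.seed(12)
  g <- volume_grid(c(32, 32, 32), c(2, 2, 2.5))
  for (rep_i in 1:3) {
    vals <- array(stats::runif(32^3, 0, 70), dim = c(32, 32, 32))
    mask <- array(stats::runif(32^3) < 0.4, dim = c(32, 32, 32))
    d <- scalar_volume(vals, g, "Gy")
    for (v in c(20, 50, 95)) {
      got <- eval_metric(d, mask, sprintf("D%d%%", v))
      oracle <- stats::quantile(vals[mask], 1 - v / 100, names = FALSE, type = 4)
      expect_equal(got, oracle, tolerance = 0.1)
    }
    for (lvl in c(10, 35, 60)) {
      got <- eval_metric(d, mask, sprintf("V%dGy", lvl))
      expect_equal(got, 100 * sum(vals[mask] >= lvl) / sum(mask), tolerance = 1e-9)
    }
  }
})

test_that("D and V metrics are monotone in their parameters", {
  set.seed(13)
  g <- volume_grid(c(16, 16, 16), c(3, 3, 3))
  vals <- array(stats::runif(16^3, 0, 60), dim = rep(16, 3))
  mask <- array(TRUE, dim = rep(16, 3))
  d <- scalar_volume(vals, g, "Gy")
  dv <- vapply(c(5, 25, 50, 75, 95), function(v) eval_metric(d, mask, sprintf("D%g%%", v)),
               numeric(1))
  expect_true(all(diff(dv) <= 1e-9))
  vv <- vapply(c(5, 20, 40, 55), function(x) eval_metric(d, mask, sprintf("V%gGy", x)),
               numeric(1))
  expect_true(all(diff(vv) <= 1e-9))
  expect_error(eval_metric(d, mask, "D200cc"), "only")
})

test_that("course scaling reproduces the prescribed totals exactly", {
  g <- volume_grid(c(4, 4, 4), c(2, 2, 2))
  fx3 <- scalar_volume(array(3, dim = c(4, 4, 4)), g, "Gy")
  expect_identical(scale_to_course(fx3, 1)$values, fx3$values)
  expect_equal(unique(as.vector(scale_to_course(fx3, 20)$values)), 60)
  fx18 <- scalar_volume(array(1.8, dim = c(4, 4, 4)), g, "Gy")
  expect_equal(unique(as.vector(scale_to_course(fx18, 25)$values)), 45)
})

test_that("goal evaluation uses strict inequalities and variation fallbacks", {
  g <- volume_grid(c(10, 6, 1), c(10, 10, 10))
  masks <- list(body = array(TRUE, dim = c(10, 6, 1)),
                PTV = array(TRUE, dim = c(10, 6, 1)),
                rectum = array(TRUE, dim = c(10, 6, 1)))
  ss <- structure_set(masks, g)
  rx <- prescription_context(60, 20)
  # exactly at prescription: strict '>' fails on the tie
  d60 <- scalar_volume(array(60, dim = c(10, 6, 1)), g, "Gy")
  r <- eval_goal(parse_goal("PTV", "D95% > 100%"), d60, ss, rx)
  expect_false(r$met)
  # V60Gy = 5%: misses the 3% goal but stays within the 10% variation
  vals <- array(50, dim = c(10, 6, 1)); vals[1:3, 1, 1] <- 61  # 3/60 voxels = 5%
  dv <- scalar_volume(vals, g, "Gy")
  r2 <- eval_goal(parse_goal("rectum", "V60Gy < 3% (10%)"), dv, ss, rx)
  expect_equal(r2$value, 5)
  expect_false(r2$met)
  expect_true(r2$within_variation)
  # V45Gy < 50cc with 60 cc at or above 45 Gy: not met
  vals3 <- array(10, dim = c(10, 6, 1)); vals3[1:60] <- 46  # 60 voxels of 1 cc
  r3 <- eval_goal(parse_goal("rectum", "V45Gy < 50cc"), scalar_volume(vals3, g, "Gy"), ss, rx)
  expect_equal(r3$value, 60)
  expect_false(r3$met)
  # met implies within_variation
  r4 <- eval_goal(parse_goal("rectum", "V60Gy < 3% (10%)"),
                  scalar_volume(array(1, dim = c(10, 6, 1)), g, "Gy"), ss, rx)
  expect_true(r4$met && r4$within_variation)
})

test_that("goal discrepancy reproduces the closed-form integer percentages", {
  mk <- function(G, F_, a, b) {
    # a goals pass in the system but fail in truth; b the reverse
    sys <- matrix(TRUE, F_, G)
    tru <- matrix(TRUE, F_, G)
    flat_t <- rep(TRUE, G * F_); flat_t[seq_len(a)] <- FALSE
    tru <- matrix(flat_t, F_, G)
    flat_s <- rep(TRUE, G * F_)
    flat_s[a + seq_len(b)] <- FALSE
    sys <- matrix(flat_s, F_, G)
    goal_discrepancy(sys, tru)
  }
  expect_equal(mk(22, 9, 7, 3)$percentage, 5L)
  expect_equal(mk(22, 9, 10, 0)$percentage, 5L)
  expect_equal(mk(21, 11, 19, 2)$percentage, 9L)
  expect_equal(mk(21, 11, 5, 6)$percentage, 5L)
  expect_equal(mk(10, 4, 0, 0)$percentage, 0L)
  d <- mk(22, 9, 7, 3)
  expect_equal(d$a, 7); expect_equal(d$b, 3)
})

test_that("goal discrepancy is invariant to goal and fraction ordering", {
  set.seed(21)
  sys <- matrix(stats::runif(9 * 22) > 0.3, 9, 22)
  tru <- matrix(stats::runif(9 * 22) > 0.3, 9, 22)
  base <- goal_discrepancy(sys, tru)
  pg <- sample(22); pf <- sample(9)
  perm <- goal_discrepancy(sys[pf, pg], tru[pf, pg])
  expect_equal(perm$percentage_raw, base$percentage_raw)
  expect_error(goal_discrepancy(sys, tru[1:5, ]), "shape")
})

test_that("worst-per-goal picks the failing-direction extreme", {
  vals <- rbind(c(5, 7, 6), c(59.7, 57.9, 58.2))
  dirs <- c("less_than", "greater_than")
  expect_equal(worst_per_goal(vals, dirs), c(7, 57.9))
  expect_equal(worst_per_goal(vals[, 1, drop = FALSE], dirs), c(5, 59.7))
})
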