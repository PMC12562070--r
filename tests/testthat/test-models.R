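test_that("model specs pin the four marker sets and degrees", {
  specs <- spine_model_specs()
  expect_equal(lapply(specs, `[[`, "labels"),
               list(c("L1", "L5"), c("T10", "S1"), c("L1", "L3", "L5"),
                    c("L1", "L2", "L3", "L4", "L5")))
  for (s in specs) {
    expect_equal(s$degree, if (length(s$labels) == 2L) 1L else 2L)
  }
})

test_that("two-point models fit the exact line through their markers", {
  cap <- toy_capture(c("L1", "L5"), u = c(100, 0), v = c(12, 4))
  fit <- fit_model(cap, spine_model_specs()[[1]])
  expect_equal(unname(fit$coefficients), c(4, 0.08), tolerance = 1e-12)
  expect_equal(fit$eval_v[3], 8, tolerance = 1e-12)   # midpoint ordinate
  expect_equal(fit$eval_u, seq(0, 100, by = 25))
})

test_that("interpolating fits recover polynomial coefficients exactly", {
  u <- c(-80, 10, 95)
  cap <- toy_capture(c("L1", "L3", "L5"), u = u, v = u^2 / 1000)
  fit <- fit_model(cap, spine_model_specs()[[3]], shared_range = FALSE)
  expect_equal(unname(fit$coefficients), c(0, 0, 1e-3), tolerance = 1e-10)

  # five points on one quadratic: least squares reproduces it too
  u5 <- seq(-60, 140, by = 50)
  cap5 <- toy_capture(c("L1", "L2", "L3", "L4", "L5"),
                      u = u5, v = 2 + 0.3 * u5 - 0.002 * u5^2)
  fit5 <- fit_model(cap5, spine_model_specs()[[4]], shared_range = FALSE)
  expect_equal(unname(fit5$coefficients), c(2, 0.3, -0.002), tolerance = 1e-10)
})

test_that("quadratic fit of a circular arc stays within the dense-grid bound", {
  cap <- pose_capture(57.3 * 0.9)    # strong flexion: most curved regime
  fit <- fit_model(cap, spine_model_specs()[[4]])
  idx <- match(LUMBAR_LABELS, cap$points$label)
  u <- cap$points$u[idx]; v <- cap$points$v[idx]
  cc <- circumcircle(c(u[1], v[1]), c(u[3], v[3]), c(u[5], v[5]))
  # dense-grid oracle: best-possible quadratic approximation of the arc
  ug <- seq(fit$u_range[1], fit$u_range[2], length.out = 2000)
  vg <- cc$center[2] + sign(v[3] - cc$center[2]) *
    sqrt(cc$radius^2 - (ug - cc$center[1])^2)
  best <- stats::lm(vg ~ ug + I(ug^2))
  bound <- max(abs(stats::resid(best)))
  err <- max(abs(lumbarseg:::.polyval(fit$coefficients, ug) - vg))
  expect_lte(err, 3 * bound + 1e-9)
  expect_gt(bound, 0)
})

test_that("non-monotone or duplicated longitudinal positions are rejected", {
  cap <- toy_capture(c("L1", "L3", "L5"), u = c(100, 120, 0), v = c(1, 2, 3))
  expect_error(fit_model(cap, spine_model_specs()[[3]]), "non-monotone")
  cap2 <- toy_capture(c("L1", "L3", "L5"), u = c(100, 100, 0), v = c(1, 2, 3))
  expect_error(fit_model(cap2, spine_model_specs()[[3]]), "duplicate")
  expect_error(fit_model(toy_capture("L1", 1, 1), spine_model_specs()[[1]]),
               "lacks markers")
})

test_that("circle fit equals the closed-form circumcircle on 3-point sets", {
  expect_equal(fit_circle(c(0, 1, 0), c(1, 0, -1))$center, c(0, 0),
               tolerance = 1e-12)
  expect_equal(fit_circle(c(0, 1, 0), c(1, 0, -1))$radius, 1,
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    p <- matrix(rnorm(6, sd = 100), 3, 2)
    cc <- circumcircle(p[1, ], p[2, ], p[3, ])
    if (!is.finite(cc$radius) || cc$radius > 1e5) next
    fc <- fit_circle(p[, 1], p[, 2])
    expect_equal(fc$center, cc$center, tolerance = 1e-9)
    expect_equal(fc$radius, cc$radius, tolerance = 1e-9)
  }
})

test_that("circle fit recovers exact circles from 5 noiseless samples", {
  th <- c(0.3, 0.9, 1.4, 2.2, 2.9)
  u <- 3 + 50 * cos(th); v <- 7 + 50 * sin(th)
  fc <- fit_circle(u, v)
  expect_equal(fc$center, c(3, 7), tolerance = 1e-9)
  expect_equal(fc$radius, 50, tolerance = 1e-9)
})

test_that("collinear points signal a straight spine, distinct from failure", {
  u <- seq(0, 200, by = 50)
  fc <- fit_circle(u, 5 + 0.1 * u)
  expect_true(fc$collinear)
  cap <- toy_capture(LUMBAR_LABELS, u = rev(u), v = rev(5 + 0.1 * u))
  lr <- lordosis_angle(cap)
  expect_true(lr$collinear)
  expect_equal(lr$lordosis_angle, 0)
  expect_error(fit_circle(c(0, 1), c(1, 0)), ">= 3")
})

test_that("lordosis recovers commanded arc angles with the documented sign", {
  for (arc in c(60, 25, -20, -53)) {
    cap <- pose_capture(arc - STA_ARC_DEG)   # commanded absolute arc = arc
    lr <- lordosis_angle(cap)
    expect_equal(lr$lordosis_angle, arc, tolerance = 1e-6)
  }
  # relative lordosis of a standing capture against its own reference is 0
  sta <- lordosis_angle(pose_capture(0), sta_reference = STA_ARC_DEG)
  expect_equal(sta$relative_lordosis, 0, tolerance = 1e-9)
})

test_that("lordosis is invariant to pelvis rotation and rigid transforms", {
  geom <- std_geom()
  base <- generate_trial(exercise_protocol("STA", duration = 1,
                                           rel_ext = 20, rel_flex = 20), geom)
  rot <- transform_trial(base, rot_axis(c(0.3, 1, 0.2), 55), c(-300, 200, 90))
  caps <- lapply(list(base, rot), function(tr) {
    fr <- pelvis_frame(tr)
    pts <- project_sagittal(tr, fr, at = 1L)
    toy_capture(pts$label, pts$u, pts$v)
  })
  a1 <- lordosis_angle(caps[[1]])$lordosis_angle
  a2 <- lordosis_angle(caps[[2]])$lordosis_angle
  expect_equal(a1, a2, tolerance = 1e-9)

  # same intrinsic arc under a different pelvis tilt: identical angle
  tilted <- generate_trial(exercise_protocol("STA", duration = 1, rel_ext = 20,
                                             rel_flex = 20, pelvis_tilt = 40),
                           geom)
  frt <- pelvis_frame(tilted)
  pts <- project_sagittal(tilted, frt, at = 1L)
  a3 <- lordosis_angle(toy_capture(pts$label, pts$u, pts$v))$lordosis_angle
  expect_equal(a3, a1, tolerance = 1e-6)
})

test_that("relative lordosis is strictly monotone in the commanded arc", {
  rels <- seq(-18.3, 57.3, length.out = 25)
  got <- vapply(rels, function(r) {
    lordosis_angle(pose_capture(r),
                   sta_reference = STA_ARC_DEG)$relative_lordosis
  }, numeric(1))
  expect_equal(cor(got, rels, method = "spearman"), 1)
  expect_equal(got, rels, tolerance = 1e-6)
})

test_that("model curves correlate exactly on quadratic-consistent captures", {
  u5 <- seq(0, 240, by = 60)
  v5 <- 10 + 0.2 * u5 - 0.0015 * u5^2
  cap <- toy_capture(c("L5", "L4", "L3", "L2", "L1"), u = u5, v = v5)
  f3 <- fit_model(cap, spine_model_specs()[[3]])
  f4 <- fit_model(cap, spine_model_specs()[[4]])
  expect_equal(pearson_pair(f3, f4)$r, 1, tolerance = 1e-12)
})

test_that("pearson_pair matches a from-scratch covariance computation", {
  mkfit <- function(v, id) structure(list(model_id = id, eval_u = 1:5,
                                          eval_v = v),
                                     class = "spine_model_fit")
  vi <- c(2.0, 3.5, 1.2, 7.8, 5.1)
  vj <- c(1.1, 4.2, 0.3, 6.6, 6.0)
  # brute-force formula oracle
  r_hand <- sum((vi - mean(vi)) * (vj - mean(vj))) /
    sqrt(sum((vi - mean(vi))^2) * sum((vj - mean(vj))^2))
  expect_equal(pearson_pair(mkfit(vi, 1), mkfit(vj, 3))$r, r_hand,
               tolerance = 1e-12)
  # affine invariance with sign
  expect_equal(pearson_pair(mkfit(vi, 1), mkfit(2 * vi + 3, 2))$r, 1)
  expect_equal(pearson_pair(mkfit(vi, 1), mkfit(-0.5 * vi + 1, 2))$r, -1)
  expect_equal(pearson_pair(mkfit(vi, 1), mkfit(vi, 2))$r, 1)
  # zero variance: undefined, flagged, never coerced
  und <- pearson_pair(mkfit(vi, 1), mkfit(rep(4, 5), 2))
  expect_true(und$undefined)
  expect_true(is.na(und$r))
})
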