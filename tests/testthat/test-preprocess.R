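test_that("zero-phase filter has unit DC gain and the analytic response", {
  n <- 1200; t <- (0:(n - 1)) / 120
  const <- matrix(c(rep(500, n), rep(-250, n), rep(80, n)), n, 3)
  tr <- trial_recording("P", "STA", 120, list(M = const))
  expect_lt(max(abs(lowpass_filter(tr)$markers$M - const)), 1e-9)

  # forward-backward order-4 Butterworth: |H(f)|^2 = 1 / (1 + (f/fc)^8)
  gain_at <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    tr <- trial_recording("P", "STA", 120,
                          list(M = cbind(x, 0 * x, 0 * x)))
    y <- lowpass_filter(tr, cutoff = 5, order = 4)$markers$M[, 1]
    mid <- seq(round(n / 3), round(2 * n / 3))
    max(abs(y[mid])) / max(abs(x[mid]))
  }
  expect_equal(gain_at(5), 1 / (1 + (5 / 5)^8), tolerance = 0.01)
  expect_equal(gain_at(0.1), 1, tolerance = 0.01)
})

test_that("filter rejects gaps, short trials and super-Nyquist cutoffs", {
  tr <- noiseless_trial("STA")
  expect_error(lowpass_filter(tr, cutoff = 60), "Nyquist")
  short <- trial_recording("P", "STA", 120, list(M = matrix(1, 10, 3)))
  expect_error(lowpass_filter(short), "too short")
  gappy <- tr; gappy$markers$L3[100:105, ] <- NA_real_
  expect_error(lowpass_filter(gappy), "missing")
})

test_that("interior gaps in linear motion are spline-filled exactly", {
  n <- 100; t <- seq_len(n)
  lin <- cbind(2 * t + 5, -t, 0.5 * t + 100)
  tr <- trial_recording("P", "STA", 120, list(M = lin, K = lin + 50))
  tr$markers$M[40:44, ] <- NA_real_
  filled <- fill_gaps(tr, max_gap = 24)
  expect_lt(max(abs(filled$markers$M - lin)), 1e-6)
  expect_equal(nrow(filled$meta$gap_report), 0L)
})

test_that("gap filling is the identity on gap-free trials", {
  tr <- noiseless_trial("STA")
  expect_trials_equal(fill_gaps(tr), tr)
})

test_that("overlong gaps without lateral donors are reported, not filled", {
  n <- 200
  lin <- cbind(seq_len(n), seq_len(n), seq_len(n))
  tr <- trial_recording("P", "STA", 120, list(C7 = lin, T10 = lin + 10))
  tr$markers$C7[50:99, ] <- NA_real_
  filled <- fill_gaps(tr, max_gap = 24)
  expect_true(all(is.na(filled$markers$C7[50:99, 1])))
  rep <- filled$meta$gap_report
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$marker, "C7")
  expect_equal(rep$reason, "too_long")
  # boundary gap with no donors is an error naming the marker
  tr2 <- trial_recording("P", "STA", 120, list(C7 = lin, T10 = lin + 10))
  tr2$markers$C7[1:5, ] <- NA_real_
  expect_error(fill_gaps(tr2), "boundary gap.*C7")
})

test_that("lumbar reconstruction is exact under rigid motion", {
  tr <- noiseless_trial("STA", duration = 2)
  tr <- rotate_per_frame(tr, seq(0, 40, length.out = tr$frame_count),
                         translation = c(100, -50, 30))
  truth <- tr$markers$L3
  tr$markers$L3[60:109, ] <- NA_real_
  rec <- reconstruct_lumbar(tr, "L3")
  expect_lt(max(abs(rec$markers$L3 - truth)), 1e-6)
})

test_that("noisy lumbar reconstruction error stays within twice the noise SD", {
  sigma <- 2
  nm <- noise_model(soft_tissue_sd = sigma, gap_rate = 0, seed = 11)
  clean <- noiseless_trial("STA", duration = 5)
  noisy <- generate_trial(exercise_protocol("STA", duration = 5), std_geom(),
                          nm)
  truth <- clean$markers$L3
  noisy$markers$L3[200:249, ] <- NA_real_
  rec <- reconstruct_lumbar(noisy, "L3")
  err <- rec$markers$L3[200:249, ] - truth[200:249, ]
  rmse <- sqrt(mean(rowSums(err^2)))
  expect_lte(rmse, 2 * sigma)
})

test_that("reconstruction fails cleanly without donors or calibration", {
  tr <- noiseless_trial("STA", duration = 1)
  tr$markers$L3[50:60, ] <- NA_real_
  tr$markers$LL2[45:70, ] <- NA_real_
  expect_error(reconstruct_lumbar(tr, "L3"), "donors missing during the gap")
  tr2 <- noiseless_trial("STA", duration = 1)
  tr2$markers$L3[, ] <- NA_real_
  tr2$markers$L3[1, ] <- 0; tr2$markers$L3[120, ] <- 0
  tr2$markers$LL2[c(1, 120), ] <- NA_real_
  expect_error(reconstruct_lumbar(tr2, "L3"), "calibration")
  expect_error(reconstruct_lumbar(tr, "C7"), "L1..L5")
})

test_that("pelvis frame equals world axes in the axis-aligned pose", {
  tr <- noiseless_trial("STA", duration = 1)
  fr <- pelvis_frame(tr)
  expect_lt(max(abs(fr$ap - matrix(c(1, 0, 0), fr$n, 3, byrow = TRUE))), 1e-10)
  expect_lt(max(abs(fr$ml - matrix(c(0, 1, 0), fr$n, 3, byrow = TRUE))), 1e-10)
  expect_lt(max(abs(fr$long - matrix(c(0, 0, 1), fr$n, 3, byrow = TRUE))), 1e-10)
})

test_that("pelvis frame rotates with the pelvis and keeps +1 handedness", {
  tr <- noiseless_trial("STA", duration = 1)
  R <- rot_y(30)
  fr <- pelvis_frame(transform_trial(tr, R))
  fr0 <- pelvis_frame(tr)
  expect_lt(max(abs(fr$ap - fr0$ap %*% t(R))), 1e-9)
  expect_lt(max(abs(fr$long - fr0$long %*% t(R))), 1e-9)
  expect_lt(max(abs(fr$ml - fr0$ml)), 1e-9)   # rotation about ML itself

  # orthonormality and handedness, also for a mirrored marker set
  mirror <- tr
  mirror$markers <- lapply(mirror$markers, function(m) {
    m[, 2] <- -m[, 2]; m
  })
  for (f in list(fr, pelvis_frame(mirror))) {
    M <- cbind(f$ap[1, ], f$ml[1, ], f$long[1, ])
    expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-10)
    expect_equal(det(M), 1, tolerance = 1e-10)
  }
})

test_that("degenerate pelvis configurations are rejected", {
  tr <- noiseless_trial("STA", duration = 1)
  for (lab in c("LPSIS", "LASIS")) {
    tr$markers[[lab]] <- tr$markers[[ sub("^L", "R", lab) ]]
  }
  expect_error(pelvis_frame(tr), "degenerate")
})

test_that("sagittal projection is an in-plane isometry and mirror-symmetric", {
  tr <- noiseless_trial("STA", duration = 1)
  fr <- pelvis_frame(tr)
  sp <- project_sagittal(tr, fr, labels = SPINE_LABELS, at = 1L)
  # midsagittal markers: projected distances equal 3D distances
  for (pair in list(c("L1", "L5"), c("C7", "S1"), c("L2", "L4"))) {
    d3 <- sqrt(sum((tr$markers[[pair[1]]][1, ] - tr$markers[[pair[2]]][1, ])^2))
    a <- sp[sp$label == pair[1], ]; b <- sp[sp$label == pair[2], ]
    expect_equal(sqrt((a$u - b$u)^2 + (a$v - b$v)^2), d3, tolerance = 1e-9)
  }
  # lateral markers mirrored across the sagittal plane project identically
  lat <- project_sagittal(tr, fr, labels = c("LL2", "RL2"), at = 1L)
  expect_equal(lat$u[1], lat$u[2], tolerance = 1e-9)
  expect_equal(lat$v[1], lat$v[2], tolerance = 1e-9)
  expect_error(project_sagittal(tr, fr, labels = "NOPE"), "missing required")
})

test_that("global rigid motion leaves sagittal coordinates unchanged", {
  tr <- noiseless_trial("FE")
  R <- rot_axis(c(1, 2, 3), 37)
  tr2 <- transform_trial(tr, R, c(250, -400, 1250))
  at <- c(1L, 500L, 1500L)
  sp1 <- project_sagittal(tr, pelvis_frame(tr), at = at)
  sp2 <- project_sagittal(tr2, pelvis_frame(tr2), at = at)
  expect_lt(max(abs(sp1$u - sp2$u)), 1e-6)
  expect_lt(max(abs(sp1$v - sp2$v)), 1e-6)
})

test_that("projected noiseless lumbar points lie on the commanded circle", {
  cap <- pose_capture(20)
  idx <- match(LUMBAR_LABELS, cap$points$label)
  u <- cap$points$u[idx]; v <- cap$points$v[idx]
  cc <- circumcircle(c(u[1], v[1]), c(u[3], v[3]), c(u[5], v[5]))
  ang <- atan2(v - cc$center[2], u - cc$center[1])
  central <- abs(ang[1] - ang[5])
  central <- min(central, 2 * pi - central) * 180 / pi
  expect_equal(central, abs(STA_ARC_DEG + 20), tolerance = 1e-6)
})
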