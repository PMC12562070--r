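# torso angle against rotation oracles -------------------------------------

test_that("torso angle is zero when C7 is directly cranial of S1", {
  tr <- noiseless_trial("STA", duration = 1)
  fr <- pelvis_frame(tr)
  # place C7 straight above S1 along the pelvis longitudinal axis
  tr$markers$C7 <- tr$markers$S1 + 400 * fr$long
  expect_lt(max(abs(torso_angle(tr, fr))), 1e-9)
})

test_that("a 45 degree anterior lean reads -45 under the flexion-negative convention", {
  tr <- noiseless_trial("STA", duration = 1)
  fr <- pelvis_frame(tr)
  dir45 <- (fr$long[1, ] + fr$ap[1, ]) / sqrt(2)   # anterior lean
  tr$markers$C7 <- tr$markers$S1 +
    matrix(400 * dir45, tr$frame_count, 3, byrow = TRUE)
  expect_equal(torso_angle(tr, fr)[1], -45, tolerance = 1e-9)
  tr$markers$C7 <- tr$markers$S1
  expect_error(torso_angle(tr, fr), "zero-length")
})

test_that("torso-angle extrema counts match the commanded cycles", {
  tr <- noiseless_trial("FE")
  ang <- torso_angle(tr, pelvis_frame(tr))
  ex <- lumbarseg:::.find_extrema(ang)
  expect_equal(sum(ex$kind == "max"), 6L)   # extension extremes
  expect_equal(sum(ex$kind == "min"), 5L)   # flexion extremes
})

# cycle detection -----------------------------------------------------------

test_that("a clean five-cycle trial yields 4 flexion and 4 extension specs", {
  tr <- noiseless_trial("FE")
  cyc <- detect_cycles(torso_angle(tr, pelvis_frame(tr)))
  expect_length(cyc, 8L)
  expect_equal(sum(vapply(cyc, function(c) c$direction, "") == "flexion"), 4L)
  expect_equal(sum(vapply(cyc, function(c) c$direction, "") == "extension"), 4L)
  for (cs in cyc) {
    pf <- cs$phase_frames
    expect_equal(unname(pf[["0%"]]), cs$start_frame)
    expect_equal(unname(pf[["100%"]]), cs$end_frame)
    expect_true(all(diff(pf) > 0))
  }
  # flexion runs from an extension extreme (torso max) to a flexion extreme
  ang <- torso_angle(tr, pelvis_frame(tr))
  fl <- cyc[[1]]
  expect_gt(ang[fl$start_frame], ang[fl$end_frame])
})

test_that("cycle detection fails informatively on monotone series", {
  expect_error(detect_cycles(seq(0, 10, length.out = 500)), "extrema")
  tr <- noiseless_trial("FE")
  ang <- torso_angle(tr, pelvis_frame(tr))
  expect_error(detect_cycles(ang, n_keep = 6), "at least 7 full cycles")
})

test_that("cycle detection is invariant to a constant angle offset", {
  tr <- noiseless_trial("FE")
  ang <- torso_angle(tr, pelvis_frame(tr))
  c1 <- detect_cycles(ang)
  c2 <- detect_cycles(ang + 57.3)
  expect_identical(c1, c2)
})

test_that("detected extrema land within 2 frames of commanded extrema under noise", {
  for (seed in c(2, 8)) {
    nm <- noise_model(soft_tissue_sd = 2, gap_rate = 0, seed = seed)
    tr <- generate_trial(exercise_protocol("FE"), std_geom(), nm)
    tr <- preprocess_trial(tr)
    cyc <- detect_cycles(torso_angle(tr, pelvis_frame(tr)))
    found_ext <- sort(unique(c(
      vapply(cyc, function(c) c$start_frame, 0)[c(TRUE, FALSE)],
      vapply(cyc, function(c) c$end_frame, 0)[c(FALSE, TRUE)])))
    found_flex <- sort(unique(vapply(
      cyc[vapply(cyc, function(c) c$direction, "") == "flexion"],
      function(c) c$end_frame, 0)))
    truth_ext <- tr$meta$events$extension_extrema[2:6]
    truth_flex <- tr$meta$events$flexion_extrema[2:5]
    expect_true(all(abs(found_ext - truth_ext) <= 2))
    expect_true(all(abs(found_flex - truth_flex) <= 2))
  }
})

# static captures -----------------------------------------------------------

test_that("constant-pose static trials give evenly spaced captures", {
  tr <- noiseless_trial("STA")
  idx <- static_captures(torso_angle(tr, pelvis_frame(tr)))
  expect_length(idx, 4L)
  # centers of 4 equal subdivisions of the full 2400-frame window
  expect_lt(max(abs(idx - (0:3) * 2400 / 4 - 300)), 2)
  expect_lt(max(abs(diff(diff(idx)))), 2)
})

test_that("captures of transient-bounded holds stay inside the hold", {
  tr <- noiseless_trial("COB")
  idx <- static_captures(torso_angle(tr, pelvis_frame(tr)))
  hold <- tr$meta$events$hold
  expect_true(all(idx >= hold[1] & idx <= hold[2]))
})

test_that("flat-free series without a steady window error out", {
  expect_error(static_captures(seq(0, 100, length.out = 3), n = 4), "shorter")
})

# capture extraction --------------------------------------------------------

test_that("capture bookkeeping: counts, shared frames and logged drops", {
  tr <- noiseless_trial("FE")
  fr <- pelvis_frame(tr)
  cyc <- detect_cycles(torso_angle(tr, fr))
  got <- extract_captures(tr, fr, cycles = cyc)
  dirs <- vapply(got$captures, function(c) c$direction, "")
  expect_equal(sum(dirs == "flexion"), 20L)    # 4 cycles x 5 percentages
  expect_equal(sum(dirs == "extension"), 20L)
  expect_equal(nrow(got$dropped), 0L)

  # 0% flexion shares its frame (and points) with the preceding 100% extension
  caps <- got$captures
  f0 <- caps[[which(dirs == "flexion" & vapply(caps, `[[`, "", "phase") == "0%")[2]]]
  e100 <- caps[[which(dirs == "extension" &
                        vapply(caps, `[[`, "", "phase") == "100%")[1]]]
  expect_equal(f0$frame, e100$frame)
  expect_equal(f0$points, e100$points)

  # deleting L3 at one phase frame drops exactly that capture, with a reason
  f1 <- caps[[1]]$frame
  tr2 <- tr; tr2$markers$L3[f1, ] <- NA_real_
  got2 <- extract_captures(tr2, fr, cycles = cyc)
  expect_length(got2$captures, 39L)
  expect_equal(nrow(got2$dropped), 1L)
  expect_match(got2$dropped$reason, "L3")
})
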