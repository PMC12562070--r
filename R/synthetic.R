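#' Standing lumbar arc angle of the synthetic cohort
#'
#' Absolute circle-fit lumbar angle (L1-L5 central angle, degrees, flexed
#' positive / lordotic negative) commanded during neutral standing. All
#' exercise waveforms are expressed relative to this value, so the commanded
#' relative lordosis of a frame is `arc - STA_ARC_DEG`.
#' @export
STA_ARC_DEG <- -35

# canonical relative-lordosis extremes (deg) and posture parameters per
# exercise; dynamic extremes are the FE/F phase-extreme means of the study's
# report, statics the corresponding hold values
.exercise_table <- list(
  STA = list(is_dynamic = FALSE, rel_ext = 0,      rel_flex = 0,    base_lean = 0,   pelvis_tilt = 0,  pad = 0),
  FE  = list(is_dynamic = TRUE,  rel_ext = -13.74, rel_flex = 31.98, base_lean = 0,  pelvis_tilt = 0,  pad = 1),
  F   = list(is_dynamic = TRUE,  rel_ext = 34.94,  rel_flex = 57.30, base_lean = 10, pelvis_tilt = -15, pad = 1),
  COB = list(is_dynamic = FALSE, rel_ext = -17.91, rel_flex = -17.91, base_lean = -10, pelvis_tilt = 70, pad = 3),
  SHO = list(is_dynamic = FALSE, rel_ext = -14.98, rel_flex = -14.98, base_lean = -5, pelvis_tilt = 40, pad = 3),
  CUP = list(is_dynamic = FALSE, rel_ext = -18.30, rel_flex = -18.30, base_lean = -10, pelvis_tilt = 70, pad = 3)
)

#' Exercise protocol
#'
#' Describes one exercise of the capture session: static holds (STA, COB,
#' SHO, CUP) are maintained for 20 s; dynamic exercises (FE, F) run five
#' movement cycles. The relative-lordosis extremes default to the phase
#' extremes of the study design; `scale` shrinks them per participant
#' (flexibility), never enlarging them.
#'
#' @param exercise_id One of `"STA"`, `"FE"`, `"F"`, `"COB"`, `"SHO"`, `"CUP"`.
#' @param duration Hold (static) or cycling (dynamic) duration in seconds.
#' @param n_cycles Number of movement cycles (dynamics only).
#' @param scale Participant flexibility scale in (0, 1], multiplying the
#'   relative-lordosis extremes.
#' @param ... Overrides of the exercise's posture fields (`rel_ext`,
#'   `rel_flex`, `base_lean`, `pelvis_tilt`, `pad`), e.g. to command an
#'   arbitrary static pose for recovery sweeps.
#' @return An `exercise_protocol` list.
#' @export
exercise_protocol <- function(exercise_id, duration = 20, n_cycles = 5,
                              scale = 1, ...) {
  if (!exercise_id %in% names(.exercise_table)) {
    stop("unknown exercise_id: ", exercise_id)
  }
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  base <- .exercise_table[[exercise_id]]
  over <- list(...)
  unknown <- setdiff(names(over),
                     c("rel_ext", "rel_flex", "base_lean", "pelvis_tilt", "pad"))
  if (length(unknown)) stop("unknown protocol fields: ",
                            paste(unknown, collapse = ", "))
  base[names(over)] <- over
  if (!base$is_dynamic) n_cycles <- 0L
  if (base$is_dynamic && n_cycles < 1) stop("dynamic exercises need n_cycles >= 1")
  structure(
    c(list(exercise_id = exercise_id, duration = duration,
           n_cycles = as.integer(n_cycles), scale = scale), base),
    class = "exercise_protocol"
  )
}

#' Noise model for synthetic marker trajectories
#'
#' Isotropic i.i.d. Gaussian soft-tissue noise per marker per frame per axis,
#' plus random occlusion gaps. Identical seeds give bit-identical output.
#'
#' @param soft_tissue_sd Noise standard deviation in mm per axis (>= 0).
#' @param gap_rate Probability per marker per second of an occlusion starting.
#' @param gap_min,gap_max Occlusion length bounds in frames.
#' @param seed Integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(soft_tissue_sd = 2, gap_rate = 0.01,
                        gap_min = 5, gap_max = 20, seed = 1L) {
  if (!is.finite(soft_tissue_sd) || soft_tissue_sd < 0) {
    stop("soft_tissue_sd must be >= 0")
  }
  if (gap_rate < 0 || gap_rate > 1) stop("gap_rate must be in [0, 1]")
  structure(list(soft_tissue_sd = soft_tissue_sd, gap_rate = gap_rate,
                 gap_min = as.integer(gap_min), gap_max = as.integer(gap_max),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Participant body geometry
#'
#' Segment dimensions derived from standing height by fixed anatomical
#' fractions: the lumbar chain (arc length L1 to L5) is 0.16 of height; the
#' thoracic landmarks T10 and C7 sit 0.075 and 0.21 of height above L1 along
#' the thoracic direction. Pelvis marker positions are a rigid body scaled by
#' height.
#'
#' @param height Standing height in mm.
#' @return A `participant_geometry` list.
#' @export
participant_geometry <- function(height = 1700) {
  if (!is.finite(height) || height <= 0) stop("height must be > 0")
  w <- height / 1700
  structure(list(
    height = height,
    chain_length = 0.16 * height,
    t10_offset = 0.075 * height,
    c7_offset = 0.21 * height,
    lateral_halfwidth = 45 * w,
    s1_anchor = c(-80 * w, 0, 30 * w),
    pelvis_local = rbind(
      LPSIS = c(-70 * w,  45 * w, 0),
      RPSIS = c(-70 * w, -45 * w, 0),
      LASIS = c( 70 * w, 120 * w, 0),
      RASIS = c( 70 * w, -120 * w, 0),
      LTIP  = c( 0,      140 * w, 40 * w),
      RTIP  = c( 0,     -140 * w, 40 * w)
    ),
    origin = c(0, 0, 1000)
  ), class = "participant_geometry")
}

#' Spine pose parameters
#'
#' @param lumbar_arc_angle Central angle (deg, |angle| < 180) of the circular
#'   arc carrying L1..L5; flexed (posteriorly convex) positive. S1 continues
#'   the same circle one angular step below L5.
#' @param thoracic_tilt Orientation (deg) of the T10/C7 chain relative to the
#'   lumbar tangent at L1, anterior positive.
#' @param pelvis_tilt Pelvis rotation (deg) about the mediolateral axis in the
#'   world sagittal plane.
#' @param trunk_lean Tilt (deg) of the S1-L1 chord relative to the pelvis
#'   longitudinal axis, anterior positive.
#' @return A `spine_pose` list.
#' @export
spine_pose <- function(lumbar_arc_angle, thoracic_tilt = 0, pelvis_tilt = 0,
                       trunk_lean = 0) {
  vals <- c(lumbar_arc_angle, thoracic_tilt, pelvis_tilt, trunk_lean)
  if (any(!is.finite(vals))) stop("non-finite pose values")
  if (abs(lumbar_arc_angle) >= 180) stop("|lumbar_arc_angle| must be < 180")
  structure(list(lumbar_arc_angle = lumbar_arc_angle,
                 thoracic_tilt = thoracic_tilt,
                 pelvis_tilt = pelvis_tilt,
                 trunk_lean = trunk_lean),
            class = "spine_pose")
}

# Vectorised chain construction: all angle arguments are equal-length vectors
# (one element per frame, degrees). Returns a named list of n x 3 world-frame
# marker matrices. The lumbar landmarks lie exactly on a circular arc whose
# L1-L5 central angle equals `arc_deg`; S1 continues the arc one step below
# L5; the S1->L1 chord is tilted by `lean_deg` from the pelvis longitudinal
# axis; all spine markers sit in the pelvis midsagittal plane.
.build_chain_frames <- function(arc_deg, lean_deg, thor_deg, pelvis_tilt_deg,
                                geometry) {
  n <- length(arc_deg)
  L <- geometry$chain_length
  th <- arc_deg * pi / 180          # signed L1-L5 central angle
  Th <- 1.25 * th                   # S1-L1 total angle
  lean <- lean_deg * pi / 180
  # chord direction d and its anterior normal a, in pelvis-local sagittal
  # coords (x anterior, z up)
  d_x <- sin(lean); d_z <- cos(lean)
  a_x <- cos(lean); a_z <- -sin(lean)

  p0 <- geometry$s1_anchor
  step <- L / 4
  chain_names <- c("S1", "L5", "L4", "L3", "L2", "L1")
  small <- abs(th) < 1e-12
  kap <- ifelse(small, NA_real_, th / L)

  local <- list()
  for (i in seq_along(chain_names)) {
    t_i <- (i - 1) * step
    gam <- kap * t_i - Th / 2
    coef_d <- ifelse(small, t_i, (sin(gam) + sin(Th / 2)) / kap)
    coef_a <- ifelse(small, 0, (cos(Th / 2) - cos(gam)) / kap)
    local[[chain_names[i]]] <- cbind(
      p0[1] + coef_d * d_x + coef_a * a_x,
      rep(p0[2], n),
      p0[3] + coef_d * d_z + coef_a * a_z
    )
  }
  # thoracic chain: straight segment from L1 along the lumbar tangent at L1
  # rotated anteriorly by thoracic_tilt
  gamT <- Th / 2 + thor_deg * pi / 180
  dirT_x <- cos(gamT) * d_x + sin(gamT) * a_x
  dirT_z <- cos(gamT) * d_z + sin(gamT) * a_z
  L1p <- local[["L1"]]
  local[["T10"]] <- cbind(L1p[, 1] + geometry$t10_offset * dirT_x,
                          L1p[, 2],
                          L1p[, 3] + geometry$t10_offset * dirT_z)
  local[["C7"]] <- cbind(L1p[, 1] + geometry$c7_offset * dirT_x,
                         L1p[, 2],
                         L1p[, 3] + geometry$c7_offset * dirT_z)
  # lateral lumbar markers: PSIS-width offsets off L2 and L4
  hw <- geometry$lateral_halfwidth
  for (lv in c("L2", "L4")) {
    p <- local[[lv]]
    local[[paste0("L", lv)]] <- cbind(p[, 1], p[, 2] + hw, p[, 3])
    local[[paste0("R", lv)]] <- cbind(p[, 1], p[, 2] - hw, p[, 3])
  }
  for (pm in rownames(geometry$pelvis_local)) {
    v <- geometry$pelvis_local[pm, ]
    local[[pm]] <- cbind(rep(v[1], n), rep(v[2], n), rep(v[3], n))
  }
  # pose the whole body: rotation about the mediolateral (y) axis by
  # pelvis_tilt, then translation to the world origin
  al <- pelvis_tilt_deg * pi / 180
  ca <- cos(al); sa <- sin(al)
  org <- geometry$origin
  out <- lapply(local, function(m) {
    cbind(m[, 1] * ca + m[, 3] * sa + org[1],
          m[, 2] + org[2],
          -m[, 1] * sa + m[, 3] * ca + org[3])
  })
  out[ALL_LABELS]
}

#' Build the full marker set for one spine pose
#'
#' Places every landmark of the marker set for a single posture: the lumbar
#' markers (and S1) exactly on a circular arc of the commanded central angle,
#' equally spaced by arc length; T10 and C7 extending from L1 along the
#' thoracic direction; the pelvis markers as a rigid body posed by the pelvis
#' tilt. All spine markers lie in the pelvis midsagittal plane.
#'
#' @param pose A [spine_pose()].
#' @param geometry A [participant_geometry()].
#' @return Named list of 1 x 3 marker position matrices (mm, world frame).
#' @export
build_spine_chain <- function(pose, geometry) {
  stopifnot(inherits(pose, "spine_pose"), inherits(geometry, "participant_geometry"))
  .build_chain_frames(pose$lumbar_arc_angle, pose$trunk_lean,
                      pose$thoracic_tilt, pose$pelvis_tilt, geometry)
}

# commanded relative-lordosis waveform (deg) over the trial's frame grid,
# plus ground-truth event locations
.protocol_waveform <- function(protocol, rate) {
  s <- protocol$scale
  ext <- protocol$rel_ext * s
  flex <- protocol$rel_flex * s
  pad <- protocol$pad
  if (!protocol$is_dynamic) {
    n <- round((protocol$duration + 2 * pad) * rate)
    t <- (seq_len(n) - 1) / rate
    hold <- ext
    rel <- rep(hold, n)
    if (pad > 0) {
      ramp_in <- t < pad
      rel[ramp_in] <- hold * (1 - cos(pi * t[ramp_in] / pad)) / 2
      t_end <- (protocol$duration + 2 * pad) - t
      ramp_out <- t_end < pad
      rel[ramp_out] <- hold * (1 - cos(pi * t_end[ramp_out] / pad)) / 2
    }
    hold_frames <- which(t >= pad & t <= pad + protocol$duration)
    events <- list(hold = range(hold_frames))
  } else {
    # pure raised-cosine oscillation; the recording starts mid-range a
    # quarter-cycle before the first extension extreme, so all 6 extension
    # and 5 flexion extremes are interior and locally symmetric
    lead <- pad
    core <- protocol$duration
    n <- round((core + 2 * lead) * rate)
    t <- (seq_len(n) - 1) / rate
    f <- protocol$n_cycles / core
    mid <- (ext + flex) / 2
    A <- ext - mid                      # cosine peaks at the extension extreme
    rel <- mid + A * cos(2 * pi * f * (t - lead))
    ext_t <- lead + (0:protocol$n_cycles) / f
    flex_t <- lead + (seq_len(protocol$n_cycles) - 0.5) / f
    events <- list(
      extension_extrema = pmin(n, round(ext_t * rate) + 1L),
      flexion_extrema = pmin(n, round(flex_t * rate) + 1L)
    )
  }
  list(rel = rel, n = n, events = events)
}

#' Generate one synthetic trial
#'
#' Samples the protocol's pose waveform at the capture rate, builds the full
#' marker set for every frame, then applies Gaussian soft-tissue noise and
#' random occlusion gaps. Per-frame ground truth (commanded relative lordosis,
#' arc angle, lean, thoracic and pelvis tilt) and ground-truth event frames
#' are stored in `meta`.
#'
#' @param protocol An [exercise_protocol()].
#' @param geometry A [participant_geometry()].
#' @param noise A [noise_model()]; `NULL` for noiseless, gap-free output.
#' @param participant_id Participant identifier.
#' @param rate Sampling rate in Hz.
#' @return A [trial_recording()].
#' @export
generate_trial <- function(protocol, geometry = participant_geometry(),
                           noise = NULL, participant_id = "P01", rate = 120) {
  stopifnot(inherits(protocol, "exercise_protocol"))
  wf <- .protocol_waveform(protocol, rate)
  rel <- wf$rel
  arc <- STA_ARC_DEG + rel
  lean <- protocol$base_lean + 0.7 * rel
  thor <- 0.2 * rel
  ptilt <- rep(protocol$pelvis_tilt, wf$n)

  markers <- .build_chain_frames(arc, lean, thor, ptilt, geometry)

  gt <- data.frame(frame = seq_len(wf$n), rel_cmd = rel, arc_deg = arc,
                   lean_deg = lean, thoracic_deg = thor, pelvis_tilt_deg = ptilt)
  meta <- list(ground_truth = gt, events = wf$events,
               scale = protocol$scale, height = geometry$height)

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    set.seed(noise$seed)
    n <- wf$n
    if (noise$soft_tissue_sd > 0) {
      markers <- lapply(markers, function(m) {
        m + matrix(stats::rnorm(3 * n, sd = noise$soft_tissue_sd), n, 3)
      })
    }
    if (noise$gap_rate > 0) {
      p_frame <- noise$gap_rate / rate
      for (lab in names(markers)) {
        starts <- which(stats::runif(n) < p_frame)
        for (s0 in starts) {
          len <- sample(noise$gap_min:noise$gap_max, 1L)
          # keep trial boundaries valid so every gap is interior
          idx <- max(2L, s0):min(n - 1L, s0 + len - 1L)
          markers[[lab]][idx, ] <- NA_real_
        }
        if (all(is.na(markers[[lab]][2:(n - 1L), 1]))) {
          stop("gap model occluded the entire trajectory of ", lab)
        }
      }
    }
    meta$noise <- noise
  }
  trial_recording(participant_id, protocol$exercise_id, rate, markers, meta)
}

#' Generate a synthetic study cohort
#'
#' Samples per-participant geometry once (height from the study population's
#' sex-specific means and SDs, 6 male : 11 female proportions) and a
#' flexibility scale in `[0.6, 1]`, then generates each requested exercise
#' trial with an independent derived noise seed. Deterministic given `seed`.
#'
#' @param n_participants Number of participants (default 17).
#' @param exercises Character vector of exercise ids.
#' @param seed Integer master seed.
#' @param soft_tissue_sd Marker noise SD in mm.
#' @param gap_rate Occlusion start rate per marker per second.
#' @param rate Sampling rate in Hz.
#' @return List of [trial_recording()] objects, one per participant x exercise.
#' @export
generate_cohort <- function(n_participants = 17,
                            exercises = c("STA", "FE", "F", "COB", "SHO", "CUP"),
                            seed = 1L, soft_tissue_sd = 2, gap_rate = 0.01,
                            rate = 120) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  set.seed(seed)
  n_male <- round(n_participants * 6 / 17)
  sex <- c(rep("M", n_male), rep("F", n_participants - n_male))
  heights <- ifelse(sex == "M",
                    stats::rnorm(n_participants, 1784.7, 80.8),
                    stats::rnorm(n_participants, 1602.7, 65.8))
  scales <- stats::runif(n_participants, 0.6, 1)
  trial_seeds <- matrix(sample.int(.Machine$integer.max,
                                   n_participants * length(exercises)),
                        n_participants, length(exercises))
  trials <- list()
  for (p in seq_len(n_participants)) {
    geom <- participant_geometry(heights[p])
    pid <- sprintf("P%02d", p)
    for (e in seq_along(exercises)) {
      proto <- exercise_protocol(exercises[e], scale = scales[p])
      nm <- noise_model(soft_tissue_sd = soft_tissue_sd, gap_rate = gap_rate,
                        seed = trial_seeds[p, e])
      trials[[length(trials) + 1L]] <-
        generate_trial(proto, geom, nm, participant_id = pid, rate = rate)
    }
  }
  trials
}
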