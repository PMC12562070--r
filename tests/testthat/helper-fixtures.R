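# shared fixtures (built once per run) and independent oracles

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

std_geom <- function() participant_geometry(1700)

noiseless_trial <- function(exercise = "STA", ...) {
  key <- paste(c("noiseless", exercise, unlist(list(...))), collapse = "_")
  fixture(key, generate_trial(exercise_protocol(exercise, ...), std_geom()))
}

# small noisy cohort reused by several suites
small_cohort <- function() {
  fixture("small_cohort", generate_cohort(n_participants = 2, seed = 42))
}

# rotation about the world y (mediolateral) axis, degrees
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# arbitrary rotation from an axis-angle
rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# per-frame rigid motion (time-varying rotation about y plus translation);
# exact rigid motion of the whole marker set frame by frame
rotate_per_frame <- function(trial, degs, translation = c(0, 0, 0)) {
  n <- trial$frame_count
  stopifnot(length(degs) == n)
  ca <- cos(degs * pi / 180); sa <- sin(degs * pi / 180)
  trial$markers <- lapply(trial$markers, function(m) {
    cbind(m[, 1] * ca + m[, 3] * sa + translation[1],
          m[, 2] + translation[2],
          -m[, 1] * sa + m[, 3] * ca + translation[3])
  })
  trial
}

# closed-form circumcircle of three 2D points (perpendicular-bisector
# formula) -- independent oracle for the algebraic circle fit
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# capture_instant built directly from (label, u, v) points
toy_capture <- function(labels, u, v, participant = "T01", exercise = "TOY") {
  structure(list(participant_id = participant, exercise_id = exercise,
                 phase = "static1", direction = "static", cycle = NA_integer_,
                 frame = 1L,
                 points = data.frame(label = labels, u = u, v = v)),
            class = "capture_instant")
}

# capture from a commanded pose: noiseless single-pose trial run through
# pelvis frame + projection
pose_capture <- function(rel, geometry = std_geom()) {
  tr <- generate_trial(exercise_protocol("STA", duration = 1,
                                         rel_ext = rel, rel_flex = rel),
                       geometry)
  fr <- pelvis_frame(tr)
  pts <- project_sagittal(tr, fr, labels = SPINE_LABELS, at = 1L)
  toy_capture(pts$label, pts$u, pts$v, exercise = "POSE")
}

expect_trials_equal <- function(a, b) {
  testthat::expect_identical(names(a$markers), names(b$markers))
  for (lab in names(a$markers)) {
    testthat::expect_identical(a$markers[[lab]], b$markers[[lab]],
                               label = paste("marker", lab))
  }
}
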