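#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a low-pass Butterworth filter of the given
#' design order, per marker per axis. Zero-phase filtering preserves event
#' timing; the net amplitude response is the squared magnitude of the
#' single-pass filter, so the gain at the cutoff is 0.5.
#'
#' @param trial A gap-free [trial_recording()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter design order (default 4).
#' @return The filtered [trial_recording()].
#' @export
lowpass_filter <- function(trial, cutoff = 5, order = 4) {
  stopifnot(inherits(trial, "trial_recording"))
  nyq <- trial$rate / 2
  if (cutoff >= nyq) stop("cutoff (", cutoff, " Hz) must be below Nyquist (",
                          nyq, " Hz)")
  if (trial$frame_count <= 3 * order) {
    stop("trial too short to filter: ", trial$frame_count, " frames")
  }
  if (any(missing_map(trial))) {
    stop("trial has missing samples; fill gaps before filtering")
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  trial$markers <- lapply(trial$markers, function(m) {
    apply(m, 2, function(x) .zero_phase(x, bf))
  })
  trial
}

# forward-backward filtering with endpoint detrending and odd-reflection
# padding, so startup transients never reach the kept samples and constant
# trajectories pass through unchanged
.zero_phase <- function(x, bf) {
  n <- length(x)
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  xd <- x - line
  pad <- min(n - 1L, 120L)
  xp <- c(2 * xd[1] - xd[(pad + 1L):2], xd, 2 * xd[n] - xd[(n - 1L):(n - pad)])
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1L):(pad + n)] + line
}

# runs of NA frames for one marker: data.frame(start, end)
.na_runs <- function(miss) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Fill interior trajectory gaps by cubic spline interpolation
#'
#' Interior gaps up to `max_gap` frames are filled per axis by a cubic spline
#' over neighbouring valid samples. Longer gaps and boundary gaps of lumbar
#' markers are referred to [reconstruct_lumbar()]; boundary gaps of other
#' markers raise an error. Anything left unfilled is reported in
#' `meta$gap_report`, never silently interpolated.
#'
#' @param trial A [trial_recording()].
#' @param max_gap Longest gap (frames) eligible for spline filling.
#' @param window Valid frames used on each side of a gap for the spline.
#' @return The filled [trial_recording()], with `meta$gap_report` listing any
#'   gaps that remain.
#' @export
fill_gaps <- function(trial, max_gap = 24L, window = 10L) {
  stopifnot(inherits(trial, "trial_recording"))
  n <- trial$frame_count
  report <- list()
  for (lab in names(trial$markers)) {
    m <- trial$markers[[lab]]
    miss <- is.na(m[, 1])
    if (!any(miss)) next
    runs <- .na_runs(miss)
    for (r in seq_len(nrow(runs))) {
      g0 <- runs$start[r]; g1 <- runs$end[r]
      interior <- g0 > 1L && g1 < n
      if (interior && (g1 - g0 + 1L) <= max_gap) {
        left <- which(!miss[1:(g0 - 1L)])
        left <- utils::tail(left, window)
        right <- which(!miss[(g1 + 1L):n]) + g1
        right <- utils::head(right, window)
        support <- c(left, right)
        for (ax in 1:3) {
          m[g0:g1, ax] <- stats::spline(support, m[support, ax],
                                        xout = g0:g1, method = "fmm")$y
        }
        miss[g0:g1] <- FALSE
      } else {
        report[[length(report) + 1L]] <- data.frame(
          marker = lab, start = g0, end = g1,
          reason = if (!interior) "boundary" else "too_long")
      }
    }
    trial$markers[[lab]] <- m
  }
  unfilled <- if (length(report)) do.call(rbind, report) else
    data.frame(marker = character(), start = integer(), end = integer(),
               reason = character())
  # lumbar markers with remaining gaps can be rebuilt from lateral donors
  for (lab in intersect(unique(unfilled$marker), LUMBAR_LABELS)) {
    trial <- reconstruct_lumbar(trial, lab)
    unfilled <- unfilled[unfilled$marker != lab, ]
  }
  bad_boundary <- unfilled[unfilled$reason == "boundary", ]
  if (nrow(bad_boundary)) {
    stop("boundary gap with no donor markers: ",
         paste(sprintf("%s[%d-%d]", bad_boundary$marker, bad_boundary$start,
                       bad_boundary$end), collapse = ", "))
  }
  trial$meta$gap_report <- unfilled
  trial
}

# fixed donor table: bracketing lateral pair per lumbar target
.donor_table <- list(
  L1 = c("LL2", "RL2"), L2 = c("LL2", "RL2"), L3 = c("LL2", "RL2"),
  L4 = c("LL4", "RL4"), L5 = c("LL4", "RL4")
)

# orthonormal donor frame per frame: origin at the bracketing pair midpoint,
# axes from the pair's mediolateral line and the direction to the other
# lateral pair's midpoint (rigid under rigid body motion)
.donor_frames <- function(trial, donors, other_pair, frames) {
  Ld <- trial$markers[[donors[1]]][frames, , drop = FALSE]
  Rd <- trial$markers[[donors[2]]][frames, , drop = FALSE]
  Om <- (trial$markers[[other_pair[1]]][frames, , drop = FALSE] +
         trial$markers[[other_pair[2]]][frames, , drop = FALSE]) / 2
  origin <- (Ld + Rd) / 2
  e1 <- Rd - Ld
  e1 <- e1 / sqrt(rowSums(e1^2))
  v2 <- Om - origin
  v2 <- v2 - e1 * rowSums(v2 * e1)
  e2 <- v2 / sqrt(rowSums(v2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(origin = origin, e1 = e1, e2 = e2, e3 = e3)
}

#' Reconstruct a lumbar marker from its lateral donors
#'
#' Rebuilds missing samples of one lumbar marker as the bracketing lateral
#' pair's midpoint plus a constant offset vector, learned by least squares in
#' the donor frame over a calibration window where target and donors are
#' simultaneously valid. Donor table: L1/L2/L3 use LL2/RL2, L4/L5 use LL4/RL4;
#' the opposite lateral pair supplies the frame's second direction.
#'
#' @param trial A [trial_recording()].
#' @param target Lumbar marker label (`"L1"`..`"L5"`).
#' @return The [trial_recording()] with the target's gaps reconstructed.
#' @export
reconstruct_lumbar <- function(trial, target) {
  stopifnot(inherits(trial, "trial_recording"))
  if (!target %in% LUMBAR_LABELS) stop("target must be one of L1..L5")
  donors <- .donor_table[[target]]
  other <- setdiff(LATERAL_LABELS, donors)
  needed <- c(donors, other)
  absent <- setdiff(needed, names(trial$markers))
  if (length(absent)) stop("lateral donors missing from trial: ",
                           paste(absent, collapse = ", "))
  miss_t <- is.na(trial$markers[[target]][, 1])
  if (!any(miss_t)) return(trial)
  donors_ok <- !is.na(trial$markers[[donors[1]]][, 1]) &
    !is.na(trial$markers[[donors[2]]][, 1]) &
    !is.na(trial$markers[[other[1]]][, 1]) &
    !is.na(trial$markers[[other[2]]][, 1])
  calib <- which(!miss_t & donors_ok)
  if (length(calib) < 3L) {
    stop("no calibration window: target ", target,
         " and donors are never simultaneously valid")
  }
  gap <- which(miss_t)
  if (!all(donors_ok[gap])) {
    stop("donors missing during the gap of ", target, " at frames ",
         paste(utils::head(gap[!donors_ok[gap]], 5), collapse = ", "))
  }
  fr_c <- .donor_frames(trial, donors, other, calib)
  tgt <- trial$markers[[target]][calib, , drop = FALSE]
  d <- tgt - fr_c$origin
  # least-squares constant offset in donor-frame coordinates
  off <- c(mean(rowSums(d * fr_c$e1)), mean(rowSums(d * fr_c$e2)),
           mean(rowSums(d * fr_c$e3)))
  fr_g <- .donor_frames(trial, donors, other, gap)
  rec <- fr_g$origin + off[1] * fr_g$e1 + off[2] * fr_g$e2 + off[3] * fr_g$e3
  trial$markers[[target]][gap, ] <- rec
  trial
}

#' Per-frame pelvis anatomical coordinate system
#'
#' The mediolateral axis runs along the line through the midpoints of the
#' right and left pelvis markers (per side, the PSIS/ASIS midpoint); the
#' anteroposterior axis is the ASIS-midpoint minus PSIS-midpoint direction
#' orthogonalized against it; the longitudinal axis completes the
#' right-handed frame. The origin is the midpoint of the four PSIS/ASIS
#' markers. The sagittal plane is spanned by the longitudinal and
#' anteroposterior axes.
#'
#' @param trial A [trial_recording()] with pelvis markers present (gap-free).
#' @param ml_pair `"side_midpoints"` (default: PSIS/ASIS midpoint per side) or
#'   `"tip"` (iliac-crest TIP markers) as the mediolateral reference line.
#' @return A `pelvis_frames` list with `origin`, `ap`, `ml`, `long` (each an
#'   n x 3 matrix of unit vectors / points) and `n` frames.
#' @export
pelvis_frame <- function(trial, ml_pair = "side_midpoints") {
  stopifnot(inherits(trial, "trial_recording"))
  need <- c("LPSIS", "RPSIS", "LASIS", "RASIS")
  if (ml_pair == "tip") need <- c(need, "LTIP", "RTIP")
  check_required_labels(trial, need)
  g <- function(lab) trial$markers[[lab]]
  if (any(vapply(need, function(l) anyNA(g(l)), logical(1)))) {
    stop("pelvis markers contain missing samples; fill gaps first")
  }
  mid_psis <- (g("LPSIS") + g("RPSIS")) / 2
  mid_asis <- (g("LASIS") + g("RASIS")) / 2
  origin <- (mid_psis + mid_asis) / 2
  if (ml_pair == "side_midpoints") {
    left <- (g("LPSIS") + g("LASIS")) / 2
    right <- (g("RPSIS") + g("RASIS")) / 2
  } else if (ml_pair == "tip") {
    left <- g("LTIP"); right <- g("RTIP")
  } else stop("ml_pair must be 'side_midpoints' or 'tip'")
  ml <- left - right
  ml_n <- sqrt(rowSums(ml^2))
  ap0 <- mid_asis - mid_psis
  if (any(ml_n < 1e-9) || any(sqrt(rowSums(ap0^2)) < 1e-9)) {
    stop("degenerate pelvis marker configuration")
  }
  ml <- ml / ml_n
  ap <- ap0 - ml * rowSums(ap0 * ml)
  ap_n <- sqrt(rowSums(ap^2))
  if (any(ap_n < 1e-9)) stop("degenerate pelvis: collinear markers")
  ap <- ap / ap_n
  long <- cbind(ap[, 2] * ml[, 3] - ap[, 3] * ml[, 2],
                ap[, 3] * ml[, 1] - ap[, 1] * ml[, 3],
                ap[, 1] * ml[, 2] - ap[, 2] * ml[, 1])
  structure(list(origin = origin, ap = ap, ml = ml, long = long,
                 n = trial$frame_count),
            class = "pelvis_frames")
}

#' Project markers into the sagittal plane
#'
#' For each requested frame and marker, returns the pelvis-relative sagittal
#' coordinates: `u` along the longitudinal axis (the independent variable of
#' all polynomial fits) and `v` along the anteroposterior axis. The
#' mediolateral component is discarded.
#'
#' @param trial A [trial_recording()].
#' @param frames A `pelvis_frames` object from [pelvis_frame()].
#' @param labels Markers to project (default: all spine markers).
#' @param at Frame indices (default: all frames).
#' @return A data.frame with columns `frame`, `label`, `u`, `v` (mm).
#' @export
project_sagittal <- function(trial, frames, labels = SPINE_LABELS,
                             at = seq_len(trial$frame_count)) {
  stopifnot(inherits(trial, "trial_recording"),
            inherits(frames, "pelvis_frames"))
  check_required_labels(trial, labels)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    m <- trial$markers[[labels[i]]][at, , drop = FALSE]
    if (anyNA(m)) {
      stop("marker ", labels[i], " missing at requested frame(s) ",
           paste(utils::head(at[is.na(m[, 1])], 5), collapse = ", "))
    }
    d <- m - frames$origin[at, , drop = FALSE]
    out[[i]] <- data.frame(
      frame = at, label = labels[i],
      u = rowSums(d * frames$long[at, , drop = FALSE]),
      v = rowSums(d * frames$ap[at, , drop = FALSE]))
  }
  do.call(rbind, out)
}

#' Preprocess a trial for analysis
#'
#' Standard order: fill gaps (spline + lateral reconstruction), then
#' zero-phase low-pass filter.
#'
#' @param trial A [trial_recording()].
#' @param config A [default_config()].
#' @return The preprocessed [trial_recording()].
#' @export
preprocess_trial <- function(trial, config = default_config()) {
  trial <- fill_gaps(trial, max_gap = config$max_gap_frames)
  if (any(missing_map(trial))) {
    mm <- missing_map(trial)
    labs <- colnames(mm)[colSums(mm) > 0]
    stop("unfillable gaps remain in: ", paste(labs, collapse = ", "))
  }
  lowpass_filter(trial, cutoff = config$cutoff_hz, order = config$filter_order)
}
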