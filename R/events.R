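#' Sagittal torso angle series
#'
#' Signed angle (degrees) between the projected C7-to-S1 line and the pelvis
#' longitudinal axis, computed with the two-argument arctangent. Convention:
#' extension positive, flexion (anterior lean) negative; zero when C7 is
#' directly cranial of S1 along the pelvis longitudinal axis.
#'
#' @param trial A gap-free [trial_recording()] with C7 and S1.
#' @param frames A `pelvis_frames` object from [pelvis_frame()].
#' @return Numeric vector of angles, one per frame.
#' @export
torso_angle <- function(trial, frames) {
  check_required_labels(trial, c("C7", "S1"))
  sp <- project_sagittal(trial, frames, labels = c("C7", "S1"))
  c7 <- sp[sp$label == "C7", ]
  s1 <- sp[sp$label == "S1", ]
  du <- c7$u - s1$u
  dv <- c7$v - s1$v
  if (any(du^2 + dv^2 < 1e-12)) stop("zero-length C7-S1 vector")
  atan2(-dv, du) * 180 / pi
}

# alternating local extrema with a prominence threshold expressed as a
# fraction of the series' peak-to-peak range
.find_extrema <- function(x, prominence_frac = 0.25) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  s_nz <- s
  # carry the last nonzero slope through plateaus
  for (i in seq_len(n - 1L)[-1]) if (s_nz[i] == 0) s_nz[i] <- s_nz[i - 1L]
  turns <- which(diff(s_nz) != 0 & s_nz[-length(s_nz)] != 0) + 1L
  if (!length(turns)) return(data.frame(frame = integer(), kind = character()))
  kind <- ifelse(s_nz[turns - 1L] > 0, "max", "min")
  prom_min <- prominence_frac * diff(range(x))
  # alternation with prominence: greedily keep extrema whose excursion from
  # the previously kept one exceeds the threshold; on same-kind repeats keep
  # the more extreme
  keep_f <- integer(0); keep_k <- character(0)
  for (i in seq_along(turns)) {
    f <- turns[i]; k <- kind[i]
    if (!length(keep_f)) {
      keep_f <- f; keep_k <- k
    } else if (k == keep_k[length(keep_k)]) {
      better <- if (k == "max") x[f] > x[keep_f[length(keep_f)]] else
        x[f] < x[keep_f[length(keep_f)]]
      if (better) keep_f[length(keep_f)] <- f
    } else if (abs(x[f] - x[keep_f[length(keep_f)]]) >= prom_min) {
      keep_f <- c(keep_f, f); keep_k <- c(keep_k, k)
    } else {
      # small wiggle: merge into the previous extremum if more extreme
      prev <- keep_f[length(keep_f)]
      if ((keep_k[length(keep_k)] == "max" && x[f] > x[prev]) ||
          (keep_k[length(keep_k)] == "min" && x[f] < x[prev])) {
        keep_f[length(keep_f)] <- f
      }
    }
  }
  data.frame(frame = keep_f, kind = keep_k)
}

# nearest-frame rounding of fractional positions, ties rounding down
.round_half_down <- function(x) ceiling(x - 0.5)

# refine an extremum by the vertex of a local quadratic fit; slow movement
# cycles have flat extrema whose raw argmax wanders under noise, while the
# vertex of a fit over a sub-cycle window is stable to well under a frame
.refine_extremum <- function(x, f, lo, hi) {
  w <- max(2L, floor(0.4 * min(f - lo, hi - f)))
  idx <- max(1L, f - w):min(length(x), f + w)
  if (length(idx) < 5L) return(f)
  tt <- idx - f
  co <- stats::lm.fit(cbind(1, tt, tt^2), x[idx])$coefficients
  if (!is.finite(co[3]) || abs(co[3]) < 1e-12) return(f)
  vertex <- -co[2] / (2 * co[3])
  fr <- f + .round_half_down(vertex)
  min(max(fr, lo + 1L), hi - 1L)
}

#' Detect movement cycles from a torso-angle series
#'
#' Finds alternating torso-angle extrema (prominence-thresholded), builds
#' full cycles running extension extreme to extension extreme, drops the
#' first (familiarization) cycle, and keeps the next `n_keep`. Each cycle is
#' split at its flexion extreme into a flexion half (max extension to max
#' flexion) and an extension half (max flexion to max extension), with phase
#' frames at the requested percentages of each half's frame span.
#'
#' @param series Torso-angle vector from [torso_angle()].
#' @param n_keep Number of cycles to extract (default 4).
#' @param phase_percents Phase sampling percentages.
#' @param prominence_frac Extremum prominence threshold as a fraction of the
#'   series' peak-to-peak range.
#' @return List of `cycle_spec` lists: `direction` (`"flexion"`/`"extension"`),
#'   `cycle` (1-based kept-cycle index), `start_frame`, `end_frame`,
#'   `phase_frames` (named by percentage).
#' @export
detect_cycles <- function(series, n_keep = 4L,
                          phase_percents = c(0, 25, 50, 75, 100),
                          prominence_frac = 0.25) {
  ex <- .find_extrema(series, prominence_frac)
  if (nrow(ex) < 3L) {
    stop("cycle detection needs alternating extrema; found ", nrow(ex))
  }
  n <- length(series)
  # refine on an event-band smoothed copy: movement cycles are far slower
  # than the residual in-band noise, and a centered moving average moves no
  # symmetric extremum while suppressing the noise that makes flat
  # extrema wander
  gap <- if (nrow(ex) > 1L) stats::median(diff(ex$frame)) else n
  W <- as.integer(max(5, min(0.2 * gap, (n - 1) / 2)))
  if (W %% 2L == 0L) W <- W + 1L
  sm <- stats::filter(series, rep(1 / W, W), sides = 2)
  sm <- as.numeric(sm)
  na <- is.na(sm)
  sm[na] <- series[na]
  bounds <- c(1L, ex$frame, n)
  for (i in seq_len(nrow(ex))) {
    ex$frame[i] <- .refine_extremum(sm, ex$frame[i], bounds[i],
                                    bounds[i + 2L])
  }
  maxima <- ex$frame[ex$kind == "max"]   # extension extremes
  minima <- ex$frame[ex$kind == "min"]   # flexion extremes
  n_cycles <- length(maxima) - 1L
  if (n_cycles < n_keep + 1L) {
    stop("need at least ", n_keep + 1L, " full cycles (", n_keep,
         " kept after dropping the first); found ", max(0L, n_cycles),
         " from ", length(maxima), " extension and ", length(minima),
         " flexion extrema")
  }
  kept <- seq.int(2L, n_keep + 1L)
  specs <- list()
  half_spec <- function(direction, cycle, f0, f1) {
    pf <- .round_half_down(f0 + phase_percents / 100 * (f1 - f0))
    names(pf) <- paste0(phase_percents, "%")
    list(direction = direction, cycle = cycle,
         start_frame = f0, end_frame = f1, phase_frames = pf)
  }
  for (ci in seq_along(kept)) {
    c0 <- maxima[kept[ci]]
    c1 <- maxima[kept[ci] + 1L]
    mid <- minima[minima > c0 & minima < c1]
    if (length(mid) != 1L) {
      stop("cycle ", kept[ci], " has ", length(mid),
           " flexion extrema between its extension extremes")
    }
    specs[[length(specs) + 1L]] <- half_spec("flexion", ci, c0, mid)
    specs[[length(specs) + 1L]] <- half_spec("extension", ci, mid, c1)
  }
  specs
}

#' Capture frames for a stationary trial
#'
#' Identifies the steady-state hold as the longest span where the torso angle
#' stays within a tolerance band of its median, then returns `n` evenly
#' spaced frame indices at the centers of its `n` equal subdivisions, so
#' rise/fall transients (whose tails converge into the tolerance band) are
#' excluded.
#'
#' @param series Torso-angle vector from [torso_angle()].
#' @param n Number of captures (default 4).
#' @param tol_deg Tolerance band half-width in degrees.
#' @return Integer vector of `n` frame indices.
#' @export
static_captures <- function(series, n = 4L, tol_deg = 2) {
  inside <- abs(series - stats::median(series)) <= tol_deg
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(spans)) stop("no steady-state window found")
  spans$len <- spans$end - spans$start + 1L
  best <- spans[which.max(spans$len), ]
  if (best$len < n) stop("steady-state window shorter than ", n, " frames")
  .round_half_down(best$start + (seq_len(n) - 0.5) / n * (best$len - 1L))
}

#' Extract capture instants from a trial
#'
#' Packages the selected frames (cycle phases for dynamic trials, static
#' sample indices for stationary ones) with the sagittal-plane coordinates of
#' all spine markers. Captures with a missing marker are dropped with a
#' logged reason, never silently.
#'
#' @param trial A preprocessed (gap-free, filtered) [trial_recording()].
#' @param frames A `pelvis_frames` object.
#' @param cycles List of cycle specs from [detect_cycles()], or `NULL`.
#' @param static_frames Frame indices from [static_captures()], or `NULL`.
#' @return List with `captures` (list of `capture_instant`: `participant_id`,
#'   `exercise_id`, `phase`, `direction`, `cycle`, `frame`, `points` data.frame
#'   of label/u/v) and `dropped` (data.frame of dropped captures and reasons).
#' @export
extract_captures <- function(trial, frames, cycles = NULL,
                             static_frames = NULL) {
  req <- list()
  if (!is.null(static_frames)) {
    for (i in seq_along(static_frames)) {
      req[[length(req) + 1L]] <- list(phase = paste0("static", i),
                                      direction = "static", cycle = NA_integer_,
                                      frame = static_frames[i])
    }
  }
  for (cs in cycles) {
    for (pn in names(cs$phase_frames)) {
      req[[length(req) + 1L]] <- list(phase = pn, direction = cs$direction,
                                      cycle = cs$cycle,
                                      frame = cs$phase_frames[[pn]])
    }
  }
  captures <- list()
  dropped <- list()
  mm <- missing_map(trial)
  for (rq in req) {
    absent <- SPINE_LABELS[mm[rq$frame, SPINE_LABELS]]
    if (length(absent)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        phase = rq$phase, direction = rq$direction, frame = rq$frame,
        reason = paste("missing markers:", paste(absent, collapse = " ")))
      next
    }
    pts <- project_sagittal(trial, frames, labels = SPINE_LABELS,
                            at = rq$frame)
    captures[[length(captures) + 1L]] <- structure(
      list(participant_id = trial$participant_id,
           exercise_id = trial$exercise_id,
           phase = rq$phase, direction = rq$direction, cycle = rq$cycle,
           frame = rq$frame,
           points = pts[, c("label", "u", "v")]),
      class = "capture_instant")
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(phase = character(), direction = character(),
               frame = integer(), reason = character())
  list(captures = captures, dropped = dropped)
}
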