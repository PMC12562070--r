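#' Marker labels used by the full pipeline
#'
#' Spinous-process markers from C7 to S1, lateral lumbar markers at the L2 and
#' L4 levels, and the six pelvis markers (posterior superior iliac spine,
#' anterior superior iliac spine and iliac-crest tip, left and right).
#'
#' @format Character vectors of marker labels.
#' @name marker-labels
NULL

#' @rdname marker-labels
#' @export
SPINE_LABELS <- c("C7", "T10", "L1", "L2", "L3", "L4", "L5", "S1")

#' @rdname marker-labels
#' @export
LUMBAR_LABELS <- c("L1", "L2", "L3", "L4", "L5")

#' @rdname marker-labels
#' @export
LATERAL_LABELS <- c("LL2", "RL2", "LL4", "RL4")

#' @rdname marker-labels
#' @export
PELVIS_LABELS <- c("LPSIS", "RPSIS", "LASIS", "RASIS", "LTIP", "RTIP")

#' @rdname marker-labels
#' @export
ALL_LABELS <- c(SPINE_LABELS, LATERAL_LABELS, PELVIS_LABELS)

#' Construct a trial recording
#'
#' A `trial_recording` holds the labelled 3D marker trajectories of one trial
#' of one exercise for one participant. Coordinates are in millimetres;
#' missing (occluded) samples are `NA` rows, never zeros.
#'
#' @param participant_id Character scalar.
#' @param exercise_id One of `"STA"`, `"FE"`, `"F"`, `"COB"`, `"SHO"`, `"CUP"`
#'   (other tags are allowed for toy data).
#' @param rate Sampling rate in Hz (> 0).
#' @param markers Named list of numeric matrices, one per marker, each with
#'   `frame_count` rows and 3 columns (x, y, z in mm).
#' @param meta Free-form list of metadata (ground truth, gap reports, ...).
#'
#' @return An object of class `trial_recording` with fields
#'   `participant_id`, `exercise_id`, `rate`, `markers`, `frame_count`, `meta`.
#' @export
trial_recording <- function(participant_id, exercise_id, rate, markers,
                            meta = list()) {
  if (!is.list(markers) || length(markers) == 0L || is.null(names(markers)) ||
      any(!nzchar(names(markers)))) {
    stop("`markers` must be a non-empty named list of n x 3 matrices")
  }
  if (anyDuplicated(names(markers))) {
    stop("duplicate marker labels: ",
         paste(unique(names(markers)[duplicated(names(markers))]), collapse = ", "))
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L) stop("each marker trajectory must have 3 columns (x,y,z)")
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    stop("all marker trajectories must have the same number of frames")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a positive scalar (Hz)")
  }
  for (lab in names(markers)) {
    m <- markers[[lab]]
    bad <- is.infinite(m) | is.nan(m)
    if (any(bad)) stop("non-finite coordinates in marker ", lab)
    # a sample is either fully present or fully missing
    na_row <- rowSums(is.na(m))
    if (any(na_row %in% c(1L, 2L))) {
      stop("marker ", lab, " has partially missing samples; ",
           "a frame must be fully present or fully NA")
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         exercise_id = as.character(exercise_id),
         rate = rate,
         markers = markers,
         frame_count = unname(nf[1]),
         meta = meta),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  n_missing <- sum(vapply(x$markers, function(m) sum(is.na(m[, 1])), numeric(1)))
  cat("<trial_recording> participant", x$participant_id,
      "exercise", x$exercise_id, "\n")
  cat("  ", x$frame_count, "frames @", x$rate, "Hz;",
      length(x$markers), "markers;", n_missing, "missing samples\n")
  invisible(x)
}

#' Logical matrix of missing samples
#'
#' @param trial A `trial_recording`.
#' @return Logical matrix frames x markers; `TRUE` where the sample is missing.
#' @export
missing_map <- function(trial) {
  sapply(trial$markers, function(m) is.na(m[, 1]))
}

#' Check that a trial carries every label the pipeline needs
#'
#' @param trial A `trial_recording`.
#' @param labels Required labels (defaults to the full pipeline set).
#' @return Invisibly `TRUE`; errors listing absent labels otherwise.
#' @export
check_required_labels <- function(trial, labels = ALL_LABELS) {
  absent <- setdiff(labels, names(trial$markers))
  if (length(absent)) {
    stop("trial is missing required markers: ", paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' Apply a rigid transform to every marker of a trial
#'
#' Utility used throughout the test-suite to assert rigid-motion invariance of
#' pelvis-relative quantities.
#'
#' @param trial A `trial_recording`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector in mm.
#' @return The transformed `trial_recording`.
#' @export
transform_trial <- function(trial, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  trial$markers <- lapply(trial$markers, function(m) {
    out <- m %*% t(rotation)
    out[, 1] <- out[, 1] + translation[1]
    out[, 2] <- out[, 2] + translation[2]
    out[, 3] <- out[, 3] + translation[3]
    out
  })
  trial
}
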