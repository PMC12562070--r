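# Minimal C3D container support: Intel (processor type 84), float32 point
# data, POINT parameter group only. Covers the standard layout written by
# write_trial_c3d() and by common mocap exporters; integer-scaled or
# DEC/MIPS-ordered files are rejected explicitly rather than misread.

.c3d_block <- 512L

#' Write a trial to a C3D file
#'
#' Standard C3D layout: 512-byte header block, one parameter section holding
#' the POINT group (USED, FRAMES, RATE, SCALE, DATA_START, UNITS, LABELS),
#' then float32 frame data (x, y, z, residual per point). Missing samples are
#' stored with residual -1 per the C3D convention.
#'
#' @param trial A [trial_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial_c3d <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  labs <- names(trial$markers)
  npts <- length(labs)
  if (npts == 0L) stop("trial has no markers to write")
  n <- trial$frame_count
  if (n > 32767L) stop("C3D 16-bit frame counter overflow: ", n, " frames")

  lab_len <- max(nchar(labs), 4L)
  lab_chars <- vapply(labs, function(s) {
    substr(paste0(s, strrep(" ", lab_len)), 1, lab_len)
  }, character(1))

  # ---- parameter section ------------------------------------------------
  put_int8 <- function(x) as.raw(bitwAnd(as.integer(x), 255L))
  put_int16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
  put_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                                  endian = "little")
  entry_group <- function(name, id) {
    nm <- charToRaw(name)
    c(put_int8(length(nm)), put_int8(-id), nm, raw(2), put_int8(0))
  }
  entry_param <- function(name, gid, type, dims, data_raw) {
    nm <- charToRaw(name)
    c(put_int8(length(nm)), put_int8(gid), nm, raw(2), put_int8(type),
      put_int8(length(dims)),
      if (length(dims)) as.raw(dims) else raw(0),
      data_raw, put_int8(0))
  }
  fix_offsets <- function(entries) {
    # offset = bytes from the offset word to the next entry; 0 terminates
    out <- raw(0)
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      name_len <- as.integer(e[1]); if (name_len > 127L) name_len <- name_len - 256L
      pos <- 2L + abs(name_len)               # offset word location
      rest <- length(e) - (pos + 2L)          # bytes after the offset word
      off <- if (i == length(entries)) 0L else rest + 2L
      e[(pos + 1L):(pos + 2L)] <- put_int16(off)
      out <- c(out, e)
    }
    out
  }
  entries <- list(
    entry_group("POINT", 1L),
    entry_param("USED", 1L, 2L, integer(0), put_int16(npts)),
    entry_param("FRAMES", 1L, 2L, integer(0), put_int16(n)),
    entry_param("RATE", 1L, 4L, integer(0), put_f32(trial$rate)),
    entry_param("SCALE", 1L, 4L, integer(0), put_f32(-1)),
    entry_param("UNITS", 1L, -1L, 2L, charToRaw("mm")),
    entry_param("LABELS", 1L, -1L, c(lab_len, npts),
                charToRaw(paste(lab_chars, collapse = "")))
  )
  # DATA_START must be patched once the parameter section size is known
  body_wo_ds <- fix_offsets(entries)
  ds_entry_len <- length(entry_param("DATA_START", 1L, 2L, integer(0),
                                     put_int16(0)))
  param_bytes <- 4L + length(body_wo_ds) + ds_entry_len
  n_param_blocks <- as.integer(ceiling(param_bytes / .c3d_block))
  data_start_block <- 2L + n_param_blocks
  entries <- append(entries, list(
    entry_param("DATA_START", 1L, 2L, integer(0), put_int16(data_start_block))
  ), after = 5L)
  param_body <- fix_offsets(entries)
  param_raw <- c(put_int8(1), put_int8(0x50), put_int8(n_param_blocks),
                 put_int8(84), param_body)
  param_raw <- c(param_raw,
                 raw(n_param_blocks * .c3d_block - length(param_raw)))

  # ---- header block -----------------------------------------------------
  header <- c(
    put_int8(2), put_int8(0x50),
    put_int16(npts), put_int16(0L),
    put_int16(1L), put_int16(n),
    put_int16(10L), put_f32(-1),
    put_int16(data_start_block), put_int16(0L),
    put_f32(trial$rate)
  )
  header <- c(header, raw(.c3d_block - length(header)))

  # ---- data section: x,y,z,residual float32 per point per frame ---------
  coords <- array(NA_real_, c(4, npts, n))
  for (j in seq_len(npts)) {
    m <- trial$markers[[j]]
    miss <- is.na(m[, 1])
    coords[1:3, j, ] <- t(ifelse(is.na(m), 0, m))
    coords[4, j, ] <- ifelse(miss, -1, 0)
  }
  data_raw <- writeBin(as.numeric(coords), raw(), size = 4, endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, param_raw, data_raw), con)
  invisible(path)
}

#' Read a trial from a C3D file
#'
#' Supports Intel-ordered files with float32 point data. Points flagged
#' invalid (negative residual) become missing samples; metre units are
#' converted to mm. Unlabeled points raise an error listing their indices.
#'
#' @param path C3D file path.
#' @param participant_id,exercise_id Metadata to attach (C3D files carry
#'   neither).
#' @return A [trial_recording()].
#' @export
read_trial_c3d <- function(path, participant_id = "unknown",
                           exercise_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  get_int16 <- function(at) readBin(raw_all[at:(at + 1)], "integer", size = 2,
                                    endian = "little")
  get_f32 <- function(at) readBin(raw_all[at:(at + 3)], "double", size = 4,
                                  endian = "little")
  if (length(raw_all) < 2L * .c3d_block || as.integer(raw_all[2]) != 0x50) {
    stop("not a C3D file (bad magic byte)")
  }
  param_block <- as.integer(raw_all[1])
  hdr_npts <- get_int16(3L)
  first_frame <- get_int16(7L)
  last_frame <- get_int16(9L)
  hdr_rate <- get_f32(21L)

  p0 <- (param_block - 1L) * .c3d_block
  proc <- as.integer(raw_all[p0 + 4L])
  if (proc != 84L) {
    stop("unsupported C3D processor type ", proc, " (only Intel/84 supported)")
  }

  # walk parameter entries
  pos <- p0 + 5L
  params <- list()
  repeat {
    name_len <- as.integer(raw_all[pos])
    if (name_len > 127L) name_len <- name_len - 256L
    gid <- as.integer(raw_all[pos + 1L])
    if (gid > 127L) gid <- gid - 256L
    if (name_len == 0L || gid == 0L) break
    nm <- rawToChar(raw_all[(pos + 2L):(pos + 1L + abs(name_len))])
    off_at <- pos + 2L + abs(name_len)
    off <- get_int16(off_at)
    if (gid > 0L) {                       # parameter (group entries skipped)
      type <- as.integer(raw_all[off_at + 2L])
      if (type > 127L) type <- type - 256L
      ndim <- as.integer(raw_all[off_at + 3L])
      dims <- if (ndim > 0L) {
        as.integer(raw_all[(off_at + 4L):(off_at + 3L + ndim)])
      } else integer(0)
      nel <- if (length(dims)) prod(dims) else 1L
      dstart <- off_at + 4L + ndim
      data <- switch(as.character(type),
        "-1" = rawToChar(raw_all[dstart:(dstart + nel - 1L)]),
        "1" = as.integer(raw_all[dstart:(dstart + nel - 1L)]),
        "2" = readBin(raw_all[dstart:(dstart + 2L * nel - 1L)], "integer",
                      n = nel, size = 2, endian = "little"),
        "4" = readBin(raw_all[dstart:(dstart + 4L * nel - 1L)], "double",
                      n = nel, size = 4, endian = "little"),
        stop("unknown parameter type ", type, " for ", nm))
      params[[toupper(nm)]] <- list(data = data, dims = dims)
    }
    if (off == 0L) break
    pos <- off_at + off
  }

  used <- if (!is.null(params$USED)) params$USED$data[1] else hdr_npts
  if (is.na(used) || used <= 0L) stop("C3D file declares 0 points")
  scale <- if (!is.null(params$SCALE)) params$SCALE$data[1] else -1
  if (scale >= 0) stop("integer-scaled C3D data not supported (SCALE >= 0)")
  rate <- if (!is.null(params$RATE)) params$RATE$data[1] else hdr_rate
  nframes <- if (!is.null(params$FRAMES)) params$FRAMES$data[1] else {
    last_frame - first_frame + 1L
  }
  data_block <- if (!is.null(params$DATA_START)) params$DATA_START$data[1] else {
    get_int16(17L)
  }
  unit_scale <- 1
  if (!is.null(params$UNITS)) {
    u <- tolower(trimws(substr(params$UNITS$data, 1, 2)))
    if (startsWith(u, "m") && !startsWith(u, "mm")) unit_scale <- 1000
  }
  if (is.null(params$LABELS)) stop("C3D file has no POINT:LABELS parameter")
  lab_dims <- params$LABELS$dims
  lab_chars <- params$LABELS$data
  labels <- character(used)
  if (length(lab_dims) == 2L) {
    for (j in seq_len(min(used, lab_dims[2]))) {
      labels[j] <- trimws(substr(lab_chars, (j - 1L) * lab_dims[1] + 1L,
                                 j * lab_dims[1]))
    }
  }
  blank <- which(!nzchar(labels))
  if (length(blank)) {
    stop("unlabeled C3D points at indices: ", paste(blank, collapse = ", "))
  }

  d0 <- (data_block - 1L) * .c3d_block
  nel <- 4L * used * nframes
  vals <- readBin(raw_all[(d0 + 1L):(d0 + 4L * nel)], "double", n = nel,
                  size = 4, endian = "little")
  arr <- array(vals, c(4, used, nframes))
  markers <- list()
  for (j in seq_len(used)) {
    m <- t(arr[1:3, j, , drop = TRUE])
    if (nframes == 1L) m <- matrix(arr[1:3, j, 1], 1, 3)
    m[arr[4, j, ] < 0, ] <- NA_real_
    markers[[labels[j]]] <- m * unit_scale
  }
  trial_recording(participant_id, exercise_id, rate, markers)
}
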