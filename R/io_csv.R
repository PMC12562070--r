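#' Marker label normalization table
#'
#' Maps common Plug-in-Gait / Nexus label dialects onto the canonical labels
#' used by the pipeline. Any `"subject:"` prefix is stripped before lookup;
#' labels without an entry pass through unchanged.
#' @export
LABEL_ALIASES <- c(
  RPSI = "RPSIS", LPSI = "LPSIS", RASI = "RASIS", LASI = "LASIS",
  RPSI1 = "RPSIS", LPSI1 = "LPSIS",
  SACR = "S1", C7SP = "C7", T10SP = "T10",
  RIC = "RTIP", LIC = "LTIP"
)

.normalize_label <- function(label, label_map = LABEL_ALIASES) {
  label <- sub("^[^:]*:", "", trimws(label))
  mapped <- unname(label_map[label])
  ifelse(is.na(mapped), label, mapped)
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a trial to a Vicon-Nexus-style CSV file
#'
#' Layout (pinned by the sample fixture shipped with the package): line 1
#' `Trajectories,<participant>,<exercise>`; line 2 the capture rate in Hz;
#' line 3 the marker names, each over its X,Y,Z column triplet; line 4 the
#' `Frame,Sub Frame,X,Y,Z,...` column header; line 5 the per-column units;
#' then one row per frame. Missing samples are empty cells.
#'
#' @param trial A [trial_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  labs <- names(trial$markers)
  if (length(labs) == 0L) stop("trial has no markers to write")
  n <- trial$frame_count
  header1 <- paste("Trajectories", trial$participant_id, trial$exercise_id,
                   sep = ",")
  header3 <- paste(c("", "", as.vector(rbind(labs, "", ""))), collapse = ",")
  header4 <- paste(c("Frame", "Sub Frame", rep(c("X", "Y", "Z"), length(labs))),
                   collapse = ",")
  header5 <- paste(c("", "", rep("mm", 3 * length(labs))), collapse = ",")
  coords <- do.call(cbind, trial$markers)       # n x 3k
  body <- matrix(.fmt_num(coords), n, 3 * length(labs))
  rows <- paste(seq_len(n), 0,
                apply(body, 1, paste, collapse = ","), sep = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header1, format(trial$rate), header3, header4, header5, rows),
             con)
  invisible(path)
}

#' Read a trial from a Vicon-Nexus-style CSV file
#'
#' Inverse of [write_trial_csv()]. Empty cells become missing samples; labels
#' are normalized via `label_map`; metre units are converted to mm. Parse
#' failures (missing rate, duplicate labels, ragged rows, columns without a
#' marker name) raise errors naming the offending line.
#'
#' @param path CSV file path.
#' @param label_map Named character vector mapping dialect labels to canonical
#'   ones (default [LABEL_ALIASES]).
#' @return A [trial_recording()].
#' @export
read_trial_csv <- function(path, label_map = LABEL_ALIASES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("truncated file: fewer than 6 lines")
  h1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(toupper(h1[1]), "TRAJECTORIES")) {
    stop("line 1: expected a 'Trajectories' section header")
  }
  participant_id <- if (length(h1) >= 2 && nzchar(h1[2])) h1[2] else "unknown"
  exercise_id <- if (length(h1) >= 3 && nzchar(h1[3])) h1[3] else "unknown"
  rate <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(rate) || rate <= 0) stop("line 2: missing or invalid capture rate")

  name_cells <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  hdr_cells <- strsplit(lines[4], ",", fixed = TRUE)[[1]]
  ncol_total <- length(hdr_cells)
  if (ncol_total < 5L || (ncol_total - 2L) %% 3L != 0L) {
    stop("line 4: expected Frame, Sub Frame and X/Y/Z column triplets")
  }
  k <- (ncol_total - 2L) %/% 3L
  name_cells <- c(name_cells, rep("", ncol_total))[seq_len(ncol_total)]
  raw_labels <- name_cells[2L + 3L * (seq_len(k) - 1L) + 1L]
  if (any(!nzchar(trimws(raw_labels)))) {
    stop("line 3: column triplet(s) ",
         paste(which(!nzchar(trimws(raw_labels))), collapse = ", "),
         " have no marker name")
  }
  labels <- .normalize_label(raw_labels, label_map)
  if (anyDuplicated(labels)) {
    stop("line 3: duplicate marker labels after normalization: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  units_cells <- strsplit(lines[5], ",", fixed = TRUE)[[1]]
  units_cells <- c(units_cells, rep("", ncol_total))[seq_len(ncol_total)]
  unit_scale <- rep(1, k)
  for (j in seq_len(k)) {
    u <- tolower(trimws(units_cells[2L + 3L * (j - 1L) + 1L]))
    if (u == "m") unit_scale[j] <- 1000
    else if (!u %in% c("", "mm")) stop("line 5: unsupported unit '", u, "'")
  }

  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  if (n == 0L) stop("no frame rows found")
  cells <- strsplit(data_lines, ",", fixed = TRUE)
  nc <- lengths(cells)
  # trailing empty cells are dropped by strsplit; pad, but reject extras
  if (any(nc > ncol_total)) {
    stop("ragged frame row(s) at line(s) ",
         paste(5L + which(nc > ncol_total)[1], collapse = ", "),
         ": more cells than declared columns")
  }
  mat <- matrix("", n, ncol_total)
  for (i in seq_len(n)) mat[i, seq_len(nc[i])] <- cells[[i]]
  num <- suppressWarnings(matrix(as.numeric(mat[, -(1:2), drop = FALSE]),
                                 n, 3L * k))
  bad_text <- nzchar(trimws(mat[, -(1:2), drop = FALSE])) & is.na(num)
  if (any(bad_text)) {
    stop("non-numeric coordinate cell at line ",
         5L + which(rowSums(bad_text) > 0)[1])
  }
  markers <- list()
  for (j in seq_len(k)) {
    m <- num[, 3L * (j - 1L) + 1:3, drop = FALSE] * unit_scale[j]
    nna <- rowSums(is.na(m))
    if (any(nna %in% 1:2)) {
      stop("marker ", labels[j], ": partially missing sample at line ",
           5L + which(nna %in% 1:2)[1])
    }
    markers[[labels[j]]] <- m
  }
  trial_recording(participant_id, exercise_id, rate, markers)
}
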