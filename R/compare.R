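.pair_name <- function(i, j) paste0(i, "v", j)

# round half away from zero, for the formatted report
.round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Analyze one preprocessed trial into capture-level results
#'
#' Runs the capture side of the pipeline on one trial: pelvis frames, torso
#' angle, cycle or static capture detection, model fits, pairwise Pearson
#' correlations and circle-fit lordosis per capture.
#'
#' @param trial A raw [trial_recording()] (preprocessing is applied here).
#' @param config A [default_config()].
#' @return List with `correlations` (data.frame: one row per capture x model
#'   pair), `lordosis` (one row per capture; `relative_lordosis` is filled in
#'   by [run_pipeline()] once the participant's STA reference is known),
#'   `dropped` (dropped captures) and `undefined` (captures whose correlation
#'   was undefined).
#' @export
analyze_trial <- function(trial, config = default_config()) {
  trial <- preprocess_trial(trial, config)
  frames <- pelvis_frame(trial, ml_pair = config$ml_pair)
  angle <- torso_angle(trial, frames)
  proto <- .exercise_table[[trial$exercise_id]]
  is_dynamic <- !is.null(proto) && proto$is_dynamic
  if (is_dynamic) {
    cycles <- detect_cycles(angle, n_keep = config$n_cycles_extracted,
                            phase_percents = config$phase_percents,
                            prominence_frac = config$prominence_frac)
    got <- extract_captures(trial, frames, cycles = cycles)
  } else {
    statics <- static_captures(angle, n = config$n_static_captures,
                               tol_deg = config$steady_tol_deg)
    got <- extract_captures(trial, frames, static_frames = statics)
  }
  specs <- config$models
  cor_rows <- list(); lord_rows <- list(); undef <- list()
  for (cap in got$captures) {
    fits <- lapply(specs, fit_model, capture = cap,
                   n_eval = config$n_eval_points,
                   shared_range = config$shared_eval_range)
    for (a in seq_along(fits)) {
      for (b in seq_along(fits)) {
        if (a >= b) next
        pc <- pearson_pair(fits[[a]], fits[[b]])
        row <- data.frame(
          participant = cap$participant_id, exercise = cap$exercise_id,
          direction = cap$direction, phase = cap$phase, cycle = cap$cycle,
          frame = cap$frame, pair = .pair_name(pc$model_i, pc$model_j),
          r = pc$r)
        if (pc$undefined) undef[[length(undef) + 1L]] <- row
        else cor_rows[[length(cor_rows) + 1L]] <- row
      }
    }
    lr <- lordosis_angle(cap, collinear_tol = config$collinear_tol_mm)
    lord_rows[[length(lord_rows) + 1L]] <- data.frame(
      participant = cap$participant_id, exercise = cap$exercise_id,
      direction = cap$direction, phase = cap$phase, cycle = cap$cycle,
      frame = cap$frame, lordosis = lr$lordosis_angle,
      relative_lordosis = NA_real_)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(
    correlations = bind(cor_rows, data.frame(
      participant = character(), exercise = character(),
      direction = character(), phase = character(), cycle = integer(),
      frame = integer(), pair = character(), r = numeric())),
    lordosis = bind(lord_rows, data.frame(
      participant = character(), exercise = character(),
      direction = character(), phase = character(), cycle = integer(),
      frame = integer(), lordosis = numeric(),
      relative_lordosis = numeric())),
    dropped = got$dropped,
    undefined = bind(undef, NULL)
  )
}

.cell_key <- function(df) {
  ifelse(df$direction == "static", df$exercise,
         paste(df$exercise, df$direction, df$phase))
}

#' Aggregate capture-level results into the comparison report
#'
#' Per exercise (statics) or exercise x direction x phase percentage
#' (dynamics), computes mean, sample SD (n-1) and n of the per-capture
#' Pearson correlations for every model pair, and of the per-capture relative
#' lordosis. Empty cells are reported missing, never NaN-propagated.
#'
#' @param correlations Capture x pair correlation data.frame.
#' @param lordosis Capture-level lordosis data.frame (with
#'   `relative_lordosis` filled).
#' @return A `comparison_report` list with `correlations` and `lordosis`
#'   summary data.frames.
#' @export
aggregate_report <- function(correlations, lordosis) {
  correlations$cell <- .cell_key(correlations)
  lordosis$cell <- .cell_key(lordosis)
  agg <- function(df, value) {
    if (!nrow(df)) {
      return(data.frame(cell = character(), mean = numeric(), sd = numeric(),
                        n = integer()))
    }
    sp <- split(df[[value]], df$cell)
    data.frame(cell = names(sp),
               mean = vapply(sp, mean, numeric(1)),
               sd = vapply(sp, stats::sd, numeric(1)),
               n = vapply(sp, length, integer(1)),
               row.names = NULL)
  }
  cors <- do.call(rbind, lapply(split(correlations, correlations$pair),
                                function(d) {
                                  out <- agg(d, "r")
                                  out$pair <- d$pair[1]
                                  out
                                }))
  rownames(cors) <- NULL
  lord <- agg(lordosis[!is.na(lordosis$relative_lordosis), ],
              "relative_lordosis")
  structure(list(correlations = cors, lordosis = lord),
            class = "comparison_report")
}

# canonical Table-2-like row order for the known exercises
.cell_order <- function(cells) {
  pcts <- c("0%", "25%", "50%", "75%", "100%")
  canon <- c("STA",
             paste("FE flexion", pcts), paste("FE extension", pcts),
             paste("F flexion", pcts), paste("F extension", pcts),
             "COB", "SHO", "CUP")
  c(intersect(canon, cells), setdiff(cells, canon))
}

#' Format a comparison report as an aligned text table
#'
#' One row per exercise/phase cell, one `mean +/- sd` column per model pair
#' plus relative lumbar lordosis, values rounded to 2 decimals (half away
#' from zero).
#'
#' @param report A `comparison_report` from [aggregate_report()].
#' @return Character vector of text lines.
#' @export
format_report <- function(report) {
  cors <- report$correlations
  pairs <- sort(unique(cors$pair))
  cells <- .cell_order(unique(c(cors$cell, report$lordosis$cell)))
  fmt <- function(m, s) {
    ifelse(is.na(m), "-",
           sprintf("%.2f ± %.2f", .round_half_away(m),
                   .round_half_away(s)))
  }
  header <- c(sprintf("%-18s", "cell"),
              sprintf("%-14s", gsub("v", " vs ", pairs)),
              "rel. lordosis (deg)")
  lines <- paste(header, collapse = " ")
  for (cl in cells) {
    vals <- vapply(pairs, function(p) {
      row <- cors[cors$cell == cl & cors$pair == p, ]
      if (nrow(row)) fmt(row$mean, row$sd) else "-"
    }, character(1))
    lrow <- report$lordosis[report$lordosis$cell == cl, ]
    lv <- if (nrow(lrow)) {
      sprintf("%.2f ± %.2f", .round_half_away(lrow$mean),
              .round_half_away(lrow$sd))
    } else "-"
    lines <- c(lines, paste(c(sprintf("%-18s", cl),
                              sprintf("%-14s", vals), lv), collapse = " "))
  }
  lines
}

#' Run the full comparison pipeline over a set of trials
#'
#' Preprocesses and analyzes every trial, computes each participant's
#' standing (STA) lordosis reference as the mean over their static captures,
#' fills in relative lordosis, and aggregates the per-capture correlations
#' into the per-exercise/phase report. Stage errors are attributed to
#' (participant, exercise) in the log and the pipeline continues over the
#' remaining trials. Deterministic: no randomness is used after the trials
#' exist.
#'
#' @param trials List of [trial_recording()] objects (e.g. from
#'   [generate_cohort()] or the readers).
#' @param config A [default_config()].
#' @param out_dir Optional directory for artifacts (`report.csv`,
#'   `report.txt`, `captures.csv`, `run.log`).
#' @return A `pipeline_result` list: `report` (`comparison_report`),
#'   `correlations` and `lordosis` capture tables, `dropped`, `undefined`,
#'   `errors` (per-trial failure log).
#' @export
run_pipeline <- function(trials, config = default_config(), out_dir = NULL) {
  cors <- list(); lords <- list(); dropped <- list(); undef <- list()
  errors <- character(0)
  for (tr in trials) {
    res <- tryCatch(analyze_trial(tr, config), error = function(e) e)
    tag <- paste0(tr$participant_id, "/", tr$exercise_id)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(tag, ": ", conditionMessage(res)))
      next
    }
    cors[[tag]] <- res$correlations
    lords[[tag]] <- res$lordosis
    if (nrow(res$dropped)) {
      d <- res$dropped; d$participant <- tr$participant_id
      d$exercise <- tr$exercise_id
      dropped[[tag]] <- d
    }
    if (!is.null(res$undefined)) undef[[tag]] <- res$undefined
  }
  correlations <- do.call(rbind, c(cors, list(make.row.names = FALSE)))
  lordosis <- do.call(rbind, c(lords, list(make.row.names = FALSE)))
  # participant STA reference = mean lordosis over their static STA captures
  sta <- lordosis[lordosis$exercise == "STA", ]
  ref <- tapply(sta$lordosis, sta$participant, mean)
  lordosis$relative_lordosis <-
    lordosis$lordosis - unname(ref[lordosis$participant])
  report <- aggregate_report(correlations, lordosis)
  out <- structure(list(
    report = report, correlations = correlations, lordosis = lordosis,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    undefined = if (length(undef)) do.call(rbind, undef) else NULL,
    errors = errors, config = config), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' Write pipeline artifacts to a directory
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- result$report
  merged <- rep$correlations[, c("cell", "pair", "mean", "sd", "n")]
  lord <- rep$lordosis
  if (nrow(lord)) {
    lord$pair <- "lordosis"
    merged <- rbind(merged, lord[, c("cell", "pair", "mean", "sd", "n")])
  }
  utils::write.csv(merged, file.path(dir, "report.csv"), row.names = FALSE)
  writeLines(format_report(rep), file.path(dir, "report.txt"))
  # one row per capture, one column per model pair
  key <- c("participant", "exercise", "direction", "phase", "cycle", "frame")
  wide <- stats::reshape(result$correlations, idvar = key, timevar = "pair",
                         direction = "wide")
  names(wide) <- sub("^r\\.", "r_", names(wide))
  caps <- merge(wide, result$lordosis, by = key, all = TRUE)
  num <- vapply(caps, is.numeric, logical(1)) & names(caps) != "frame"
  caps[num] <- lapply(caps[num], signif, digits = 6)
  caps <- caps[order(caps$participant, caps$exercise, caps$direction,
                     caps$cycle, caps$frame), ]
  utils::write.csv(caps, file.path(dir, "captures.csv"), row.names = FALSE)
  log_lines <- c(
    paste("lumbarseg", as.character(utils::packageVersion("lumbarseg"))),
    paste("R", getRversion()),
    paste("captures:", nrow(result$lordosis)),
    paste("dropped:", if (is.null(result$dropped)) 0 else nrow(result$dropped)),
    paste("undefined correlations:",
          if (is.null(result$undefined)) 0 else nrow(result$undefined)),
    if (length(result$errors)) paste("ERROR", result$errors) else "no stage errors")
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
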