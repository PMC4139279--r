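#' Read an RR-interval series from CSV
#'
#' The dialect is plain comma-separated values with a header row, `.` decimal
#' point, times in seconds and RR intervals in milliseconds.  Required
#' columns: `time_s`, `rr_ms`.  Optional columns: `provenance`
#' (`original`/`reconstructed`), `anchor_eligible` (logical), `segment`
#' (integer id); absent flag columns default to original / eligible / one
#' contiguous segment.
#'
#' @param path file path.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return an [rr_series()].
#' @export
read_rr_series <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "rr_ms") %in% names(df))) {
    stop("missing required columns time_s, rr_ms in ", path)
  }
  for (col in c("time_s", "rr_ms")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        stop("non-numeric value in column '", col, "' at row ",
             which(is.na(num))[1])
      }
      df[[col]] <- num
    }
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  n <- nrow(df)
  seg <- if ("segment" %in% names(df)) as.integer(df$segment) else rep(1L, n)
  if (n > 1L) {
    same_seg <- seg[-1L] == seg[-n]
    bad <- same_seg & diff(df$time_s) <= 0
    if (any(bad)) {
      stop("malformed input: time_s not strictly increasing at row ",
           which(bad)[1] + 1L, " of ", path)
    }
  }
  rr_series(
    time_s = df$time_s, rr_ms = df$rr_ms,
    provenance = if ("provenance" %in% names(df)) df$provenance else rep("original", n),
    anchor_eligible = if ("anchor_eligible" %in% names(df)) as.logical(df$anchor_eligible) else rep(TRUE, n),
    segment = seg,
    subject_id = subject_id
  )
}

#' Write an RR-interval series to CSV
#'
#' Inverse of [read_rr_series()]; flag columns are always written so a
#' round-trip preserves the object.
#'
#' @param x an `rr_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(x, path) {
  stopifnot(inherits(x, "rr_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an occlusion schedule from CSV
#'
#' The events table holds one row per occlusion with columns `start_s`,
#' `end_s`, `phase`.  Phase boundaries come either from a companion phase
#' table (`phase_path`, columns `phase`, `start_s`, `end_s`) or from rows of
#' the same file with `kind == "phase"` when a `kind` column is present
#' (event rows then carry `kind == "event"`).
#'
#' @param path events CSV path.
#' @param phase_path optional companion phase-table CSV path.
#' @return an [occlusion_schedule()].
#' @export
read_occlusion_schedule <- function(path, phase_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("kind" %in% names(df)) {
    phases <- df[df$kind == "phase", c("phase", "start_s", "end_s")]
    events <- df[df$kind == "event", c("start_s", "end_s", "phase")]
  } else {
    events <- df[, c("start_s", "end_s", "phase")]
    if (is.null(phase_path)) stop("no phase table: supply phase_path or a 'kind' column")
    phases <- utils::read.csv(phase_path, stringsAsFactors = FALSE)[, c("phase", "start_s", "end_s")]
  }
  rownames(events) <- rownames(phases) <- NULL
  occlusion_schedule(events, phases)
}

#' Write an occlusion schedule to CSV
#'
#' Writes a single file with a `kind` column distinguishing phase rows from
#' event rows, readable by [read_occlusion_schedule()].
#'
#' @param sch an `occlusion_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occlusion_schedule <- function(sch, path) {
  ph <- data.frame(kind = "phase", start_s = sch$phases$start_s,
                   end_s = sch$phases$end_s, phase = sch$phases$phase)
  ev <- if (nrow(sch$events) > 0L) {
    data.frame(kind = "event", start_s = sch$events$start_s,
               end_s = sch$events$end_s, phase = sch$events$phase)
  } else NULL
  utils::write.csv(rbind(ph, ev), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read acid-base biomarker samples from CSV
#'
#' Columns: `time_s`, `pH`, `lactate` (mEq/L), `base_deficit` (mEq/L).
#' Values outside physiologic range (pH outside (6.5, 7.8), negative
#' lactate) are rejected.
#'
#' @param path file path.
#' @return data frame of class `biomarker_samples`.
#' @export
read_biomarkers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "pH", "lactate", "base_deficit")
  if (!all(req %in% names(df))) stop("missing biomarker columns in ", path)
  validate_biomarkers(df[, req])
}

#' Validate biomarker samples
#' @param df data frame with `time_s`, `pH`, `lactate`, `base_deficit`.
#' @return the validated data frame, classed `biomarker_samples`.
#' @export
validate_biomarkers <- function(df) {
  if (any(df$pH <= 6.5 | df$pH >= 7.8)) {
    stop("pH out of physiologic range at row ",
         which(df$pH <= 6.5 | df$pH >= 7.8)[1])
  }
  if (any(df$lactate < 0)) stop("negative lactate at row ", which(df$lactate < 0)[1])
  if (is.unsorted(df$time_s, strictly = TRUE)) stop("biomarker times not increasing")
  class(df) <- c("biomarker_samples", "data.frame")
  df
}

#' Write biomarker samples to CSV
#' @param df a `biomarker_samples` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a capacity-result table to CSV
#'
#' One row per (subject, phase, variant, T) combination with the absolute
#' AC/DC values in ms and the anchor counts behind them; duplicate keys are
#' an error.
#'
#' @param results data frame as produced by [capacity_spectrum()] /
#'   [run_full_analysis()], with columns `subject`, `phase`, `variant`, `T`,
#'   `s`, `AC_abs_ms`, `DC_abs_ms`, `n_anchors_dec`, `n_anchors_acc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_capacity_table <- function(results, path) {
  if (NROW(results) == 0L) stop("empty capacity table")
  cols <- c("subject", "phase", "variant", "T", "s",
            "AC_abs_ms", "DC_abs_ms", "n_anchors_dec", "n_anchors_acc")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(results$subject, results$phase, results$variant, results$T)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, phase, variant, T) key: ", key[anyDuplicated(key)])
  }
  extra <- setdiff(names(results), cols)
  utils::write.csv(results[, c(cols, extra)], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capacity-result table written by [write_capacity_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_capacity_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
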