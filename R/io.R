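#' Read a tri-axial recording from CSV
#'
#' The on-disk format is a long CSV with header
#' `time_s,acc_x,acc_y,acc_z` (time in seconds, acceleration in g). A column
#' map can adapt other headers. The sampling rate is inferred from the
#' median sample spacing and validated against a uniformity tolerance of
#' `1e-6` s.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param side Wrist side, `"left"` or `"right"`.
#' @param schema Named character vector mapping the canonical column names
#'   (`time_s`, `acc_x`, `acc_y`, `acc_z`) to the file's column names.
#' @return A [recording()] tibble.
#' @export
read_recording <- function(path,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           side = "right",
                           schema = c(time_s = "time_s", acc_x = "acc_x",
                                      acc_y = "acc_y", acc_z = "acc_z")) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Recording file lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pn_format_error")
  }
  df <- tibble::tibble(time_s = as.numeric(raw[[schema[["time_s"]]]]),
                       acc_x = as.numeric(raw[[schema[["acc_x"]]]]),
                       acc_y = as.numeric(raw[[schema[["acc_y"]]]]),
                       acc_z = as.numeric(raw[[schema[["acc_z"]]]]))
  if (nrow(df) < 2L) {
    abort("Recording must contain at least two samples.",
          class = "pn_validation_error")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    abort("Sample times must be strictly increasing (duplicate or reversed timestamps).",
          class = "pn_validation_error")
  }
  rate_hz <- 1 / median(dt)
  # Snap to the nominal pipeline rates when within tolerance.
  for (r in c(200, 50)) if (abs(rate_hz - r) < 0.01) rate_hz <- r
  recording(df, subject_id = subject_id, side = side, rate_hz = rate_hz)
}

#' Write a recording to CSV
#'
#' Values are written at full double precision so that write/read
#' round-trips are bit-identical.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  write_csv_full(as.data.frame(rec), path)
}

#' Read an interval annotation track from CSV
#'
#' Expected header: `start_s,end_s,label[,sub_class,prototype]`.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return An [annotation_track()] tibble.
#' @export
read_annotations <- function(path,
                             subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  annotation_track(raw, subject_id = subject_id)
}

#' @rdname read_annotations
#' @param track An [annotation_track()].
#' @export
write_annotations <- function(track, path) {
  write_csv_full(as.data.frame(track), path)
}

#' Assign class labels to analysis windows from an annotation track
#'
#' Each 2-s window receives the label of the class covering the majority
#' (> 50%) of its span. A sub-class (and its prototype flag) is assigned
#' only when a single sub-class covers at least `purity` of the span;
#' otherwise the window keeps `sub_class = "none"`. Windows with no
#' annotation coverage on the majority of their span are flagged `excluded`.
#' The rule is additive over interval coverage, so it is invariant to
#' interval order and to splitting an interval into abutting pieces.
#'
#' @param windows Tibble of windows with columns `window_start`,
#'   `window_end` (seconds), as produced by [window_segments()].
#' @param track An [annotation_track()] for the same subject.
#' @param purity Minimum fraction of the window a single sub-class must
#'   cover to be assigned (default 0.9).
#' @return `windows` with columns `label`, `sub_class`, `prototype`,
#'   `excluded` appended.
#' @export
label_windows <- function(windows, track, purity = 0.9) {
  n <- nrow(windows)
  label <- character(n)
  sub_class <- rep("none", n)
  prototype <- rep(FALSE, n)
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ws <- windows$window_start[i]
    we <- windows$window_end[i]
    len <- we - ws
    ov <- pmin(track$end_s, we) - pmax(track$start_s, ws)
    ov[ov < 0] <- 0
    cls_cov <- tapply(ov, track$label, sum)
    tre <- if ("tremor" %in% names(cls_cov)) cls_cov[["tremor"]] else 0
    non <- if ("non_tremor" %in% names(cls_cov)) cls_cov[["non_tremor"]] else 0
    if (max(tre, non) <= 0.5 * len) {
      excluded[i] <- TRUE
      label[i] <- NA_character_
      next
    }
    label[i] <- if (tre > non) "tremor" else "non_tremor"
    tagged <- track$sub_class != "none"
    if (any(tagged & ov > 0)) {
      sc_cov <- tapply(ov[tagged], track$sub_class[tagged], sum)
      best <- names(sc_cov)[which.max(sc_cov)]
      best_class <- if (best %in% tremor_sub_classes()) "tremor" else "non_tremor"
      if (sc_cov[[best]] >= purity * len && best_class == label[i]) {
        sub_class[i] <- best
        proto_cov <- sum(ov[tagged & track$sub_class == best & track$prototype])
        prototype[i] <- proto_cov >= purity * len
      }
    }
  }
  out <- tibble::as_tibble(windows)
  out$label <- label
  out$sub_class <- sub_class
  out$prototype <- prototype
  out$excluded <- excluded
  out
}

#' Serialise an evaluation report to JSON and CSV
#'
#' Writes `<stem>.json` (full report: per-fold metrics, aggregates,
#' stratified tables, agreement statistics, config echo) with
#' deterministic key order, plus `<stem>_folds.csv` with the per-fold
#' table.
#'
#' @param report An evaluation report, as returned by [evaluate_loso()].
#' @param stem Output path stem (no extension).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_folds.csv")
  payload <- list(
    aggregate = as.list(glance(report)),
    folds = tidy(report),
    stratified_sensitivity = report$stratified$sensitivity,
    stratified_specificity = report$stratified$specificity,
    agreement = report$agreement,
    config = report$config
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
    write_csv_full(as.data.frame(tidy(report)), csv_path)
    TRUE
  }, error = function(e) {
    abort(sprintf("Could not write report to '%s': %s", stem,
                  conditionMessage(e)))
  })
  invisible(c(json_path, csv_path))
}
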