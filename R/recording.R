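#' Sub-class taxonomy
#'
#' The pipeline recognises seven tremor movement sub-classes (`T1`--`T7`:
#' wrist/finger flexion--extension, elbow flexion--extension and
#' pronation--supination, each with the arm supported or free, plus tremor
#' during gait) and seven non-tremor activity sub-classes (`N1` gait, `N2`
#' postural transitions, `N3` running/exercising, `N4` driving bike/car,
#' `N5` "suspicious" periodic upper-limb activity, `N6` other upper-limb
#' activity, `N7` no upper-limb activity).
#'
#' @return Character vectors of valid sub-class tokens.
#' @export
tremor_sub_classes <- function() paste0("T", 1:7)

#' @rdname tremor_sub_classes
#' @export
non_tremor_sub_classes <- function() paste0("N", 1:7)

all_sub_classes <- function() c(tremor_sub_classes(), non_tremor_sub_classes())

#' Construct a validated tri-axial wrist recording
#'
#' A recording is a tibble with columns `time_s`, `acc_x`, `acc_y`, `acc_z`
#' (acceleration in g) carrying `subject_id`, `side` and `rate_hz` as
#' attributes. Sample times must be strictly increasing and uniformly spaced
#' at `1/rate_hz` within a tolerance of `1e-6` s.
#'
#' @param data Data frame with columns `time_s`, `acc_x`, `acc_y`, `acc_z`.
#' @param subject_id Subject identifier string.
#' @param side Wrist the device is worn on, `"left"` or `"right"`.
#' @param rate_hz Sampling rate in Hz (200 for raw device output, 50 after
#'   downsampling).
#' @return A `pn_recording` tibble.
#' @export
recording <- function(data, subject_id, side = c("left", "right"), rate_hz) {
  side <- match.arg(side)
  req <- c("time_s", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Recording is missing columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pn_format_error")
  }
  assert_scalar_number(rate_hz, "rate_hz")
  if (rate_hz <= 0) abort("`rate_hz` must be positive.")
  df <- tibble::as_tibble(data[req])
  if (!all(vapply(df, is.numeric, logical(1L)))) {
    abort("Recording columns must be numeric.", class = "pn_format_error")
  }
  if (anyNA(df)) abort("Recording contains missing values.",
                       class = "pn_validation_error")
  dt <- diff(df$time_s)
  if (nrow(df) > 1L) {
    if (any(dt <= 0)) {
      abort("Sample times must be strictly increasing.",
            class = "pn_validation_error")
    }
    if (any(abs(dt - 1 / rate_hz) > 1e-6)) {
      abort(sprintf("Sample spacing deviates from 1/%g s by more than 1e-6 s.",
                    rate_hz),
            class = "pn_validation_error")
    }
  }
  structure(df,
            class = c("pn_recording", class(df)),
            subject_id = as.character(subject_id),
            side = side,
            rate_hz = rate_hz)
}

#' @export
print.pn_recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, %s wrist, %g Hz, %.1f s (%d samples)\n",
              attr(x, "subject_id"), attr(x, "side"), attr(x, "rate_hz"),
              nrow(x) / attr(x, "rate_hz"), nrow(x)))
  NextMethod()
}

rec_subject <- function(rec) attr(rec, "subject_id")
rec_rate <- function(rec) attr(rec, "rate_hz")
rec_side <- function(rec) attr(rec, "side")

rec_matrix <- function(rec) {
  cbind(x = rec$acc_x, y = rec$acc_y, z = rec$acc_z)
}

rec_replace_acc <- function(rec, acc) {
  rec$acc_x <- acc[, 1L]
  rec$acc_y <- acc[, 2L]
  rec$acc_z <- acc[, 3L]
  rec
}

#' Construct a validated interval annotation track
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from recording
#' start, labelled `tremor` or `non_tremor`, optionally tagged with a
#' sub-class token (`T1`..`T7` for tremor, `N1`..`N7` for non-tremor,
#' `none` otherwise) and a prototype flag marking expert-selected
#' prototypical examples. Overlapping intervals sharing label, sub-class and
#' prototype flag are merged.
#'
#' @param data Data frame with columns `start_s`, `end_s`, `label` and
#'   optionally `sub_class`, `prototype`.
#' @param subject_id Subject identifier string.
#' @return A `pn_annotations` tibble sorted by `start_s`.
#' @export
annotation_track <- function(data, subject_id) {
  req <- c("start_s", "end_s", "label")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Annotation track is missing columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "pn_format_error")
  }
  df <- tibble::as_tibble(data)
  if (!"sub_class" %in% names(df)) df$sub_class <- "none"
  if (!"prototype" %in% names(df)) df$prototype <- FALSE
  df <- df[c("start_s", "end_s", "label", "sub_class", "prototype")]
  df$label <- as.character(df$label)
  df$sub_class <- as.character(df$sub_class)
  df$prototype <- as.logical(df$prototype)
  if (any(df$start_s >= df$end_s)) {
    abort("Annotation intervals must satisfy start_s < end_s.",
          class = "pn_validation_error")
  }
  bad_label <- setdiff(unique(df$label), c("tremor", "non_tremor"))
  if (length(bad_label) > 0L) {
    abort(sprintf("Unknown label(s): %s (valid: tremor, non_tremor).",
                  paste(bad_label, collapse = ", ")),
          class = "pn_validation_error")
  }
  valid_tokens <- c(all_sub_classes(), "none")
  bad <- setdiff(unique(df$sub_class), valid_tokens)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown sub-class token(s): %s. Valid tokens: %s.",
                  paste(bad, collapse = ", "),
                  paste(valid_tokens, collapse = ", ")),
          class = "pn_validation_error")
  }
  if (any(df$label == "tremor" & df$sub_class %in% non_tremor_sub_classes())) {
    abort("Tremor intervals cannot carry non-tremor sub-classes.",
          class = "pn_validation_error")
  }
  if (any(df$label == "non_tremor" & df$sub_class %in% tremor_sub_classes())) {
    abort("Non-tremor intervals cannot carry tremor sub-classes.",
          class = "pn_validation_error")
  }
  if (any(df$prototype & df$sub_class == "none")) {
    abort("Prototype intervals must carry a sub-class.",
          class = "pn_validation_error")
  }
  df <- merge_same_class_intervals(df)
  structure(df,
            class = c("pn_annotations", class(df)),
            subject_id = as.character(subject_id))
}

# Merge overlapping or touching intervals that share (label, sub_class,
# prototype); label_windows() is additive over coverage so this is purely a
# normalisation step.
merge_same_class_intervals <- function(df) {
  df <- df[order(df$start_s, df$end_s), , drop = FALSE]
  key <- paste(df$label, df$sub_class, df$prototype, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    part <- df[idx, , drop = FALSE]
    out <- part[1L, , drop = FALSE]
    if (nrow(part) > 1L) {
      for (i in 2L:nrow(part)) {
        j <- nrow(out)
        if (part$start_s[i] <= out$end_s[j]) {
          out$end_s[j] <- max(out$end_s[j], part$end_s[i])
        } else {
          out <- rbind(out, part[i, , drop = FALSE])
        }
      }
    }
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$start_s, out$end_s), , drop = FALSE]
  tibble::as_tibble(out)
}

#' @export
print.pn_annotations <- function(x, ...) {
  cat(sprintf("<annotations> subject %s, %d intervals (%.1f s tremor)\n",
              attr(x, "subject_id"), nrow(x),
              sum((x$end_s - x$start_s)[x$label == "tremor"])))
  NextMethod()
}
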