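## Plain-text interchange formats: hypnogram / annotations / cohort as
## CSV, EEG as a single-column CSV whose first line states the sampling
## rate. These are the dialects the synthetic generators write and the
## pipeline reads back.

#' Write / read a hypnogram as CSV
#'
#' Columns: `epoch` (0-based index) and `stage` (W/N1/N2/N3/REM).
#' Lights-off/on are carried in `# key: value` header comments.
#'
#' @param hyp a [hypnogram()].
#' @param path CSV path.
#' @return `path` (write) or a [hypnogram()] (read).
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_length_s: %g", hyp$epoch_length), con)
  writeLines(sprintf("# lights_off_s: %g", hyp$lights_off), con)
  writeLines(sprintf("# lights_on_s: %g", hyp$lights_on), con)
  write.csv(data.frame(epoch = seq_along(hyp$stages) - 1L, stage = hyp$stages),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_header_value <- function(lines, key) {
  hit <- grep(sprintf("^# %s:", key), lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  as.numeric(sub(sprintf("^# %s:\\s*", key), "", hit[1]))
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  df <- read.csv(text = paste(body, collapse = "\n"))
  df <- df[order(df$epoch), , drop = FALSE]
  el <- read_header_value(lines, "epoch_length_s") %||% 30
  hypnogram(df$stage, epoch_length = el,
            lights_off = read_header_value(lines, "lights_off_s") %||% 0,
            lights_on = read_header_value(lines, "lights_on_s") %||%
              (nrow(df) * el))
}

#' Write / read annotation intervals as CSV
#'
#' Columns: `start`, `end` (seconds from record start), `kind`
#' (arousal/artifact).
#'
#' @param ann an [annotation_set()].
#' @param path CSV path.
#' @export
write_annotations_csv <- function(ann, path) {
  write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  annotation_set(read.csv(path))
}

#' Write / read an EEG trace as a single-column CSV
#'
#' First line is a `# sampling_rate_hz: <fs>` comment, then a single
#' `eeg` column in µV.
#'
#' @param signal numeric samples (µV).
#' @param fs sampling rate in Hz.
#' @param path CSV path.
#' @return `path` (write) or `list(signal, fs)` (read).
#' @export
write_eeg_csv <- function(signal, fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %g", fs), con)
  writeLines("eeg", con)
  writeLines(format(signal, trim = TRUE, digits = 8, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  fs <- read_header_value(first, "sampling_rate_hz")
  if (is.null(fs)) stop_fmt("read_eeg_csv: %s lacks the sampling-rate header", path)
  df <- read.csv(con)
  list(signal = as.numeric(df$eeg), fs = fs)
}

#' Write / read a cohort table as CSV
#'
#' @param table cohort data frame (one row per participant).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path)
  if ("age_group" %in% names(df)) {
    df$age_group <- factor(df$age_group, levels = c("young", "old"))
  }
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}
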