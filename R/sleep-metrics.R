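# Indices (1-based) of epochs fully inside the lights-off window.
window_epochs <- function(hyp) {
  el <- hyp$epoch_length
  n <- length(hyp$stages)
  starts <- (seq_len(n) - 1) * el
  which(starts >= hyp$lights_off & starts + el <= hyp$lights_on)
}

#' Sleep architecture metrics from a hypnogram
#'
#' Total sleep time (TST), sleep onset latency (SOL), sleep efficiency and
#' REM percentage, computed over epochs fully inside the
#' lights-off/lights-on window. Sleep onset is the first epoch of any
#' non-wake stage.
#'
#' @param hypnogram a [hypnogram()].
#' @return list with `tst_min`, `sol_min`, `efficiency` (%),
#'   `rem_pct` (% of TST), `time_in_bed_min`. With no sleep epochs, SOL
#'   and REM% are `NA` and a warning is raised.
#' @export
stage_metrics <- function(hypnogram) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  idx <- window_epochs(hypnogram)
  st <- hypnogram$stages[idx]
  el_min <- hypnogram$epoch_length / 60
  tib_min <- (hypnogram$lights_on - hypnogram$lights_off) / 60
  sleep <- st != "W"
  tst <- sum(sleep) * el_min
  if (!any(sleep)) {
    warn_fmt("stage_metrics: no sleep epochs; SOL and REM%% undefined")
    sol <- NA_real_
    rem_pct <- NA_real_
  } else {
    sol <- (which(sleep)[1] - 1) * el_min
    rem_pct <- 100 * sum(st == "REM") * el_min / tst
  }
  list(tst_min = tst, sol_min = sol,
       efficiency = 100 * tst / tib_min,
       rem_pct = rem_pct, time_in_bed_min = tib_min)
}

#' REM-specific metrics
#'
#' REM onset latency (time from the first sleep epoch to the first REM
#' epoch), the number of arousal events overlapping REM epochs, and REM
#' episode durations (maximal REM runs, optionally merging runs separated
#' by at most `merge_window` non-REM epochs).
#'
#' @param hypnogram a [hypnogram()].
#' @param annotations an [annotation_set()].
#' @param merge_window gap tolerance in epochs when merging REM runs into
#'   episodes (default 0 = strict runs).
#' @return list with `rem_latency_min` (`NA` + warning when no REM),
#'   `rem_arousal_count`, `rem_episode_min` (numeric vector).
#' @export
rem_metrics <- function(hypnogram, annotations = annotation_set(),
                        merge_window = 0L) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  idx <- window_epochs(hypnogram)
  st <- hypnogram$stages[idx]
  el <- hypnogram$epoch_length
  el_min <- el / 60
  rem <- which(st == "REM")
  if (length(rem) == 0L) {
    warn_fmt("rem_metrics: no REM epochs in the record")
    return(list(rem_latency_min = NA_real_, rem_arousal_count = 0L,
                rem_episode_min = numeric(0)))
  }
  first_sleep <- which(st != "W")[1]
  latency <- (rem[1] - first_sleep) * el_min
  # arousal events overlapping any REM epoch (events, not epochs, counted)
  ar <- annotations[annotations$kind == "arousal", , drop = FALSE]
  count <- 0L
  if (nrow(ar)) {
    rem_start <- (idx[rem] - 1) * el
    rem_end <- rem_start + el
    for (k in seq_len(nrow(ar))) {
      if (any(ar$start[k] < rem_end & ar$end[k] > rem_start)) count <- count + 1L
    }
  }
  # episodes: maximal REM runs tolerating gaps <= merge_window epochs
  gaps <- diff(rem)
  new_episode <- c(TRUE, gaps > merge_window + 1L)
  episode_id <- cumsum(new_episode)
  durations <- as.numeric(tapply(rem, episode_id, length)) * el_min
  list(rem_latency_min = latency, rem_arousal_count = count,
       rem_episode_min = as.numeric(durations))
}

# Band power of each clean 4-s sub-segment of the given epochs.
# Returns a data.frame(epoch, power, clean).
epoch_segment_powers <- function(signal, fs, hyp, epochs, annotations, band,
                                 seg_seconds = 4, step_seconds = 2) {
  el <- hyp$epoch_length
  seg_len <- as.integer(round(seg_seconds * fs))
  w <- hamming_window(seg_len)
  n_one <- seg_len %/% 2 + 1L
  freq <- (seq_len(n_one) - 1) * fs / seg_len
  in_band <- freq >= band[1] & freq < band[2]
  df <- fs / seg_len
  offsets <- seq(0, el - seg_seconds, by = step_seconds)
  ann <- as.data.frame(annotations)
  out <- vector("list", length(epochs))
  for (j in seq_along(epochs)) {
    e <- epochs[j]
    e_start <- (e - 1) * el
    seg_start <- e_start + offsets
    seg_end <- seg_start + seg_seconds
    clean <- rep(TRUE, length(offsets))
    if (nrow(ann)) {
      for (k in seq_len(nrow(ann))) {
        clean <- clean & !(ann$start[k] < seg_end & ann$end[k] > seg_start)
      }
    }
    pw <- rep(NA_real_, length(offsets))
    for (s in which(clean)) {
      a <- as.integer(round(seg_start[s] * fs)) + 1L
      x <- signal[a:(a + seg_len - 1L)]
      pw[s] <- sum(segment_psd(x, w, fs)[in_band]) * df
    }
    out[[j]] <- data.frame(epoch = e, power = pw, clean = clean)
  }
  do.call(rbind, out)
}

#' Cumulative overnight band energy for a stage set
#'
#' The record is cut into consecutive bins (30 min by default) anchored at
#' lights-off. Within each bin, band power is the mean over clean 4-s
#' segments (2-s step, aligned to epoch starts) of the target-stage
#' epochs; segments overlapping any arousal/artifact annotation are
#' rejected. The bin's clean mean is weighted by the bin's stage time
#' (stage epochs / nominal epochs per bin) — the adjustment for the
#' proportion of rejected data — and the energy is the sum over bins.
#' Bins that contain stage epochs but no clean segment are flagged and
#' excluded from the sum with a warning. Setting `adjust = FALSE` sums the
#' unadjusted clean means instead.
#'
#' @param signal EEG samples (µV).
#' @param fs sampling rate (Hz).
#' @param hypnogram a [hypnogram()] time-aligned with the signal.
#' @param annotations an [annotation_set()].
#' @param stage_set stages to cumulate over (e.g. `"N3"` for SWE, `"REM"`
#'   for REM theta energy).
#' @param band `c(lo, hi)` Hz.
#' @param bin_minutes bin length (default 30).
#' @param adjust apply the stage-time weighting (default TRUE).
#' @return list with `energy` (µV²·bins; `NA` + warning when the record
#'   has no target-stage epoch), `bins` (per-bin series: mean power, clean
#'   segment count, stage epoch count, rejected fraction, flag) and
#'   `defined`.
#' @export
cumulative_band_energy <- function(signal, fs, hypnogram, annotations,
                                   stage_set, band, bin_minutes = 30,
                                   adjust = TRUE) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  if (length(signal) < length(hypnogram$stages) * hypnogram$epoch_length * fs) {
    stop_fmt("cumulative_band_energy: signal (%d samples) shorter than the hypnogram span (%g samples)",
             length(signal),
             length(hypnogram$stages) * hypnogram$epoch_length * fs)
  }
  idx <- window_epochs(hypnogram)
  target <- idx[hypnogram$stages[idx] %in% stage_set]
  el <- hypnogram$epoch_length
  epochs_per_bin <- bin_minutes * 60 / el
  if (length(target) == 0L) {
    warn_fmt("cumulative_band_energy: no %s epochs in the record; energy undefined",
             paste(stage_set, collapse = "/"))
    return(list(energy = NA_real_, bins = NULL, defined = FALSE))
  }
  seg <- epoch_segment_powers(signal, fs, hypnogram, target, annotations, band)
  epoch_bin <- floor(((seg$epoch - 1) * el - hypnogram$lights_off) / (bin_minutes * 60))
  bins <- sort(unique(epoch_bin))
  rows <- lapply(bins, function(b) {
    sb <- seg[epoch_bin == b, , drop = FALSE]
    n_clean <- sum(sb$clean)
    mean_power <- if (n_clean > 0) mean(sb$power[sb$clean]) else NA_real_
    n_stage <- length(unique(sb$epoch))
    data.frame(bin = b, start_min = b * bin_minutes,
               mean_power = mean_power,
               n_clean_segments = n_clean,
               n_stage_epochs = n_stage,
               rejected_fraction = 1 - n_clean / nrow(sb),
               flagged = n_clean == 0L)
  })
  bins_df <- do.call(rbind, rows)
  if (any(bins_df$flagged)) {
    warn_fmt("cumulative_band_energy: %d bin(s) with stage epochs but no clean segment excluded from the sum",
             sum(bins_df$flagged))
  }
  ok <- !bins_df$flagged
  contrib <- if (adjust) {
    bins_df$mean_power[ok] * bins_df$n_stage_epochs[ok] / epochs_per_bin
  } else {
    bins_df$mean_power[ok]
  }
  list(energy = sum(contrib), bins = bins_df, defined = TRUE)
}

#' All per-night sleep metrics
#'
#' Convenience wrapper combining [stage_metrics()], [rem_metrics()], slow
#' wave energy (cumulated 0.5–4 Hz power during SWS) and REM theta energy
#' (cumulated 4–8 Hz power during REM sleep).
#'
#' @inheritParams cumulative_band_energy
#' @param annotations an [annotation_set()].
#' @param swe_stages stage set defining SWS for SWE; `"N3"` by default,
#'   `c("N2","N3")` treats all deep NREM as SWS.
#' @return a named list of metrics (a `sleep_metrics` record).
#' @export
sleep_metrics <- function(signal, fs, hypnogram, annotations,
                          swe_stages = "N3") {
  sm <- stage_metrics(hypnogram)
  rm_ <- rem_metrics(hypnogram, annotations)
  swe <- cumulative_band_energy(signal, fs, hypnogram, annotations,
                                swe_stages, c(0.5, 4))
  theta <- cumulative_band_energy(signal, fs, hypnogram, annotations,
                                  "REM", c(4, 8))
  structure(list(
    tst_min = sm$tst_min, sol_min = sm$sol_min, efficiency = sm$efficiency,
    rem_pct = sm$rem_pct,
    swe = swe$energy, rem_theta_energy = theta$energy,
    rem_latency_min = rm_$rem_latency_min,
    rem_arousal_count = rm_$rem_arousal_count,
    rem_episode_min = rm_$rem_episode_min,
    swe_bins = swe$bins, theta_bins = theta$bins
  ), class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf(paste0("<sleep_metrics> TST %.1f min, SOL %.1f min, efficiency %.1f%%, ",
                     "REM %.1f%%\n  SWE %.4g, REM theta energy %.4g, REM latency %.1f min, ",
                     "%d REM arousals, %d REM episodes\n"),
              x$tst_min, x$sol_min, x$efficiency, x$rem_pct, x$swe,
              x$rem_theta_energy, x$rem_latency_min, x$rem_arousal_count,
              length(x$rem_episode_min)))
  invisible(x)
}
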