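SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Hypnogram object
#'
#' Sleep-stage sequence scored in fixed-length epochs (30 s by
#' convention), with the lights-off/lights-on window in seconds from
#' record start.
#'
#' @param stages character vector of per-epoch labels in
#'   `c("W","N1","N2","N3","REM")`.
#' @param epoch_length epoch duration in seconds.
#' @param lights_off,lights_on window bounds in seconds; defaults span the
#'   whole record.
#' @return a `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30,
                      lights_off = 0,
                      lights_on = length(stages) * epoch_length) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop_fmt("hypnogram: `stages` is empty")
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) stop_fmt("hypnogram: unknown stage label(s): %s",
                            paste(bad, collapse = ", "))
  rec_end <- length(stages) * epoch_length
  if (!(lights_off < lights_on && lights_on <= rec_end)) {
    stop_fmt("hypnogram: need lights_off < lights_on <= record end (%g s)", rec_end)
  }
  structure(list(stages = stages, epoch_length = epoch_length,
                 lights_off = lights_off, lights_on = lights_on),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat(sprintf("<hypnogram> %d epochs of %g s (%s)\n", length(x$stages),
              x$epoch_length,
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Annotation set (arousal / artifact intervals)
#'
#' @param intervals data frame with columns `start`, `end` (seconds from
#'   record start) and `kind` in `c("arousal","artifact")`; may be empty.
#' @return an `annotation_set` (a validated data frame).
#' @export
annotation_set <- function(intervals = data.frame(start = numeric(),
                                                  end = numeric(),
                                                  kind = character())) {
  intervals <- as.data.frame(intervals)
  if (!all(c("start", "end", "kind") %in% names(intervals))) {
    stop_fmt("annotation_set: need columns start, end, kind")
  }
  if (nrow(intervals)) {
    if (any(intervals$start >= intervals$end)) {
      stop_fmt("annotation_set: every interval needs start < end")
    }
    bad <- setdiff(unique(intervals$kind), c("arousal", "artifact"))
    if (length(bad)) stop_fmt("annotation_set: unknown kind(s): %s",
                              paste(bad, collapse = ", "))
  }
  class(intervals) <- c("annotation_set", "data.frame")
  intervals
}

#' Specification of a synthetic hypnogram
#'
#' @param time_in_bed minutes in bed.
#' @param epoch_length seconds per scored epoch (default 30).
#' @param stage_proportions named fractions over
#'   `c("W","N1","N2","N3","REM")` summing to 1. Defaults describe a
#'   healthy adult night (10% wake, 5% N1, 45% N2, 20% N3, 20% REM).
#' @param sleep_onset_epoch 0-based index of the first sleep epoch;
#'   everything before it is wake. `NULL` (default) places onset at half
#'   the wake budget, capped at 30 epochs (15 min).
#' @param rem_bout_plan optional data frame `start`, `length` (0-based
#'   start epoch, length in epochs) of non-overlapping REM bouts; by
#'   default four bouts carrying the REM target count are placed at 25%,
#'   45%, 65% and 85% of the post-onset period.
#' @param arousal_rate arousal events per hour in bed (10-s events).
#' @param artifact_fraction fraction of disjoint 4-s segments annotated as
#'   artifact.
#' @return a `hypnogram_spec`.
#' @export
hypnogram_spec <- function(time_in_bed = 480,
                           epoch_length = 30,
                           stage_proportions = c(W = 0.10, N1 = 0.05,
                                                 N2 = 0.45, N3 = 0.20,
                                                 REM = 0.20),
                           sleep_onset_epoch = NULL,
                           rem_bout_plan = NULL,
                           arousal_rate = 8,
                           artifact_fraction = 0.02) {
  n_sec <- time_in_bed * 60
  if (n_sec %% epoch_length != 0) {
    stop_fmt("hypnogram_spec: epoch_length (%g s) does not divide time_in_bed (%g min)",
             epoch_length, time_in_bed)
  }
  if (abs(sum(stage_proportions) - 1) > 1e-9) {
    stop_fmt("hypnogram_spec: stage proportions must sum to 1")
  }
  if (!setequal(names(stage_proportions), SLEEP_STAGES)) {
    stop_fmt("hypnogram_spec: stage_proportions must name exactly %s",
             paste(SLEEP_STAGES, collapse = ", "))
  }
  n_epochs <- as.integer(n_sec / epoch_length)
  if (is.null(sleep_onset_epoch)) {
    sleep_onset_epoch <- min(30L, floor(0.5 * stage_proportions[["W"]] * n_epochs))
  }
  if (sleep_onset_epoch >= n_epochs) {
    stop_fmt("hypnogram_spec: sleep_onset_epoch must be < total epochs (%d)", n_epochs)
  }
  structure(list(time_in_bed = time_in_bed, epoch_length = epoch_length,
                 stage_proportions = stage_proportions[SLEEP_STAGES],
                 sleep_onset_epoch = as.integer(sleep_onset_epoch),
                 rem_bout_plan = rem_bout_plan,
                 arousal_rate = arousal_rate,
                 artifact_fraction = artifact_fraction,
                 n_epochs = n_epochs),
            class = "hypnogram_spec")
}

#' Generate a synthetic hypnogram with annotations and ground truth
#'
#' Stage counts are fixed from the target proportions by largest-remainder
#' rounding, so realized proportions deviate by at most one epoch per
#' stage. REM sleep is laid out in bouts (plan or default four-bout plan);
#' wake before `sleep_onset_epoch` consumes the wake budget; remaining
#' stages fill the rest of the night in seeded random order. Arousal
#' (10 s) and artifact (4 s) intervals are placed uniformly in the
#' lights-off window.
#'
#' @param spec a [hypnogram_spec()].
#' @param seed integer seed.
#' @return list with `hypnogram`, `annotations` ([annotation_set()]) and
#'   `truth` (planted TST, SOL, efficiency, REM% computed by epoch
#'   counting).
#' @export
generate_hypnogram <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "hypnogram_spec"))
  n <- spec$n_epochs
  counts <- round_preserve_sum(spec$stage_proportions, n)
  names(counts) <- names(spec$stage_proportions)
  onset <- spec$sleep_onset_epoch
  if (counts["W"] < onset) {
    stop_fmt("generate_hypnogram: wake budget (%d epochs) smaller than sleep_onset_epoch (%d)",
             counts["W"], onset)
  }
  plan <- spec$rem_bout_plan
  if (is.null(plan)) {
    rem_total <- counts["REM"]
    bout_sizes <- round_preserve_sum(rep(0.25, 4), rem_total)
    anchors <- onset + round(c(0.25, 0.45, 0.65, 0.85) * (n - onset))
    plan <- data.frame(start = anchors, length = bout_sizes)
    plan <- plan[plan$length > 0, , drop = FALSE]
  }
  plan <- plan[order(plan$start), , drop = FALSE]
  if (nrow(plan) > 1) {
    ends <- plan$start + plan$length
    if (any(plan$start[-1] < ends[-nrow(plan)])) {
      stop_fmt("generate_hypnogram: REM bouts overlap")
    }
  }
  if (any(plan$start < onset) || any(plan$start + plan$length > n)) {
    stop_fmt("generate_hypnogram: REM bout outside the post-onset window")
  }
  stages <- rep(NA_character_, n)
  if (onset > 0) stages[seq_len(onset)] <- "W"
  for (k in seq_len(nrow(plan))) {
    stages[(plan$start[k] + 1L):(plan$start[k] + plan$length[k])] <- "REM"
  }
  n_rem_planned <- sum(stages == "REM", na.rm = TRUE)
  pool <- c(rep("W", max(0L, counts["W"] - onset)),
            rep("N1", counts["N1"]), rep("N2", counts["N2"]),
            rep("N3", counts["N3"]),
            rep("REM", max(0L, counts["REM"] - n_rem_planned)))
  free <- which(is.na(stages))
  if (length(pool) > length(free)) pool <- pool[seq_along(free)]
  with_seed(seed, {
    pool <- sample(pool)
    # first free post-onset epoch must be sleep, or SOL would exceed plan
    if (free[1] == onset + 1L && pool[1] == "W") {
      swap <- which(pool != "W")[1]
      if (!is.na(swap)) { tmp <- pool[1]; pool[1] <- pool[swap]; pool[swap] <- tmp }
    }
    stages[free] <- c(pool, rep("N2", length(free) - length(pool)))
    hyp <- hypnogram(stages, spec$epoch_length)
    tib_sec <- n * spec$epoch_length
    n_arousal <- round(spec$arousal_rate * tib_sec / 3600)
    ann <- data.frame(start = numeric(), end = numeric(), kind = character())
    if (n_arousal > 0) {
      starts <- sort(runif(n_arousal, 0, tib_sec - 10))
      ann <- rbind(ann, data.frame(start = starts, end = starts + 10,
                                   kind = "arousal"))
    }
    n_slots <- floor(tib_sec / 4)
    n_art <- round(spec$artifact_fraction * n_slots)
    if (n_art > 0) {
      slots <- sort(sample.int(n_slots, n_art))
      ann <- rbind(ann, data.frame(start = (slots - 1) * 4,
                                   end = (slots - 1) * 4 + 4,
                                   kind = "artifact"))
    }
    truth <- list(
      tst_min = sum(stages != "W") * spec$epoch_length / 60,
      sol_min = onset * spec$epoch_length / 60,
      efficiency = 100 * sum(stages != "W") / n,
      rem_pct = 100 * sum(stages == "REM") / sum(stages != "W"),
      stage_counts = table(factor(stages, levels = SLEEP_STAGES))
    )
    list(hypnogram = hyp, annotations = annotation_set(ann), truth = truth)
  })
}
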