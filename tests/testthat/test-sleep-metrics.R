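test_that("architecture metrics follow the stated arithmetic", {
  # 10 wake epochs then sleep: SOL = 5 min
  hyp <- stages_hyp(W = 10, N1 = 4, N2 = 26)
  sm <- stage_metrics(hyp)
  expect_equal(sm$sol_min, 5)
  expect_equal(sm$tst_min, 15)
  expect_equal(sm$efficiency, 100 * 15 / 20)
  # TST 420 of 480 min in bed -> efficiency 87.5%
  hyp2 <- stages_hyp(W = 120, N2 = 750, REM = 90)
  sm2 <- stage_metrics(hyp2)
  expect_equal(sm2$tst_min, 420)
  expect_equal(sm2$efficiency, 87.5)
  # 90 REM epochs of 840 sleep epochs -> 45/420 of TST
  expect_equal(sm2$rem_pct, 100 * 45 / 420, tolerance = 1e-10)
})

test_that("a sleepless record flags SOL as undefined", {
  expect_warning(sm <- stage_metrics(stages_hyp(W = 20)), "no sleep")
  expect_true(is.na(sm$sol_min))
  expect_equal(sm$tst_min, 0)
})

test_that("REM latency, arousal counts and episodes are computed from runs", {
  # sleep onset at epoch 11, first REM at epoch 191 -> latency 90 min
  hyp <- stages_hyp(W = 10, N2 = 180, REM = 20, N2 = 30, REM = 40, N2 = 20)
  rm_ <- rem_metrics(hyp)
  expect_equal(rm_$rem_latency_min, 90)
  # two strict runs of 20 and 40 epochs -> 10 and 20 minutes
  expect_equal(rm_$rem_episode_min, c(10, 20))
  # only arousals overlapping REM epochs count, as events
  ann <- annotation_set(data.frame(
    start = c(100, 190 * 30 + 5, 215 * 30), end = c(110, 190 * 30 + 15, 215 * 30 + 10),
    kind = "arousal"))
  expect_equal(rem_metrics(hyp, ann)$rem_arousal_count, 1)
  # merge window joins runs separated by short gaps
  expect_equal(rem_metrics(hyp, merge_window = 30)$rem_episode_min, 30)
})

test_that("a REM-free record yields NA latency and empty episodes", {
  expect_warning(rm_ <- rem_metrics(stages_hyp(W = 4, N2 = 16)), "no REM")
  expect_true(is.na(rm_$rem_latency_min))
  expect_equal(rm_$rem_arousal_count, 0L)
  expect_length(rm_$rem_episode_min, 0)
})

test_that("cumulative energy doubles when time in stage doubles", {
  fs <- 200
  spec <- stage_spectrum_spec()
  hyp1 <- stages_hyp(W = 4, N3 = 60, N2 = 56)    # 30 min N3
  hyp2 <- stages_hyp(W = 4, N3 = 120, N2 = 116)  # 60 min N3
  e1 <- generate_sleep_eeg(hyp1, spec, seed = 31)
  e2 <- generate_sleep_eeg(hyp2, spec, seed = 31)
  ann <- annotation_set()
  c1 <- cumulative_band_energy(e1$signal, fs, hyp1, ann, "N3", c(0.5, 4))
  c2 <- cumulative_band_energy(e2$signal, fs, hyp2, ann, "N3", c(0.5, 4))
  expect_lt(abs(c2$energy - 2 * c1$energy) / (2 * c1$energy), 0.02)
})

test_that("energies ignore the content of annotated spans", {
  fs <- 200
  hgen <- generate_hypnogram(hypnogram_spec(time_in_bed = 90,
                                            artifact_fraction = 0.05,
                                            arousal_rate = 10), seed = 41)
  eeg <- generate_sleep_eeg(hgen$hypnogram, stage_spectrum_spec(),
                            hgen$annotations, seed = 42)
  base <- cumulative_band_energy(eeg$signal, fs, hgen$hypnogram,
                                 hgen$annotations, "REM", c(4, 8))
  corrupted <- eeg$signal
  for (k in seq_len(nrow(hgen$annotations))) {
    a <- floor(hgen$annotations$start[k] * fs) + 1
    b <- min(length(corrupted), ceiling(hgen$annotations$end[k] * fs))
    corrupted[a:b] <- 1e6
  }
  after <- cumulative_band_energy(corrupted, fs, hgen$hypnogram,
                                  hgen$annotations, "REM", c(4, 8))
  expect_identical(after$energy, base$energy)
  expect_true(all(after$bins$mean_power == base$bins$mean_power))
})

test_that("a record without the target stage is explicitly undefined", {
  hyp <- stages_hyp(W = 4, N2 = 56)
  sig <- rnorm(60 * 30 * 200)
  expect_warning(res <- cumulative_band_energy(sig, 200, hyp, annotation_set(),
                                               "REM", c(4, 8)),
                 "undefined")
  expect_true(is.na(res$energy))
  expect_false(res$defined)
})

test_that("rejection adjustment removes the bias of half-artifact records", {
  fs <- 200
  hyp <- stages_hyp(W = 4, N3 = 56, N2 = 30, N3 = 30)
  spec <- stage_spectrum_spec()
  eeg_clean <- generate_sleep_eeg(hyp, spec, seed = 51)
  # half of all 4-s slots annotated as artifact
  n_slots <- floor(length(hyp$stages) * 30 / 4)
  slots <- seq(1, n_slots, by = 2)
  ann <- annotation_set(data.frame(start = (slots - 1) * 4,
                                   end = (slots - 1) * 4 + 4,
                                   kind = "artifact"))
  eeg_half <- generate_sleep_eeg(hyp, spec, annotations = ann, seed = 51)
  e_clean <- cumulative_band_energy(eeg_clean$signal, fs, hyp,
                                    annotation_set(), "N3", c(0.5, 4))
  e_half <- cumulative_band_energy(eeg_half$signal, fs, hyp, ann, "N3",
                                   c(0.5, 4))
  expect_lt(abs(e_half$energy - e_clean$energy) / e_clean$energy, 0.05)
  # without the adjustment the same record under-counts stage time
  expect_gt(mean(e_half$bins$rejected_fraction), 0.4)
})

test_that("the sleep_metrics record assembles all per-night outputs", {
  hgen <- generate_hypnogram(hypnogram_spec(time_in_bed = 90), seed = 61)
  eeg <- generate_sleep_eeg(hgen$hypnogram, stage_spectrum_spec(),
                            hgen$annotations, seed = 62)
  sm <- sleep_metrics(eeg$signal, eeg$fs, hgen$hypnogram, hgen$annotations)
  expect_s3_class(sm, "sleep_metrics")
  expect_equal(sm$tst_min, hgen$truth$tst_min)
  expect_true(sm$swe >= 0 && sm$rem_theta_energy >= 0)
  expect_true(all(c("mean_power", "rejected_fraction") %in% names(sm$swe_bins)))
})
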