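EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8),
                  alpha = c(8, 12), sigma = c(12, 16))

#' Stage-specific EEG spectrum specification
#'
#' Target band powers per sleep stage for the synthetic EEG generator.
#' Stage synthesis is band-limited Gaussian noise shaped per band, which
#' has analytically known band power (unlike AR fits to real EEG); a
#' white broadband floor can be added. The paper-free defaults are
#' plausible frontal-scalp values: dominant delta in N2/N3 (strongest in
#' N3), theta in REM, alpha in wake.
#'
#' @param powers data frame with columns `stage`, `band`, `power` (µV²);
#'   stages not listed for a band get zero power in that band.
#' @param noise_sd broadband white-noise SD (µV).
#' @param fs sampling rate in Hz (sleep EEG digitized at 200 Hz).
#' @param bands named list of `c(lo, hi)` Hz bands.
#' @return a `stage_spectrum_spec`.
#' @export
stage_spectrum_spec <- function(powers = NULL, noise_sd = 1, fs = 200,
                                bands = EEG_BANDS) {
  if (is.null(powers)) {
    powers <- data.frame(
      stage = c("W",     "W",    "N1",    "N2",    "N2",    "N3",    "REM"),
      band  = c("alpha", "theta", "theta", "delta", "sigma", "delta", "theta"),
      power = c(15,       5,       8,      60,      6,      200,      20)
    )
  }
  powers <- as.data.frame(powers)
  if (!all(c("stage", "band", "power") %in% names(powers))) {
    stop_fmt("stage_spectrum_spec: `powers` needs columns stage, band, power")
  }
  if (any(powers$power < 0)) stop_fmt("stage_spectrum_spec: powers must be nonnegative")
  bad <- setdiff(unique(powers$band), names(bands))
  if (length(bad)) stop_fmt("stage_spectrum_spec: unknown band(s): %s",
                            paste(bad, collapse = ", "))
  if (!is_scalar_num(noise_sd) || noise_sd < 0) {
    stop_fmt("stage_spectrum_spec: noise_sd must be nonnegative")
  }
  structure(list(powers = powers, noise_sd = noise_sd, fs = fs, bands = bands),
            class = "stage_spectrum_spec")
}

# Band-limited Gaussian noise of length n with sample variance exactly
# `power`: white noise masked to the band in the frequency domain, then
# rescaled. Returns zeros when power is 0.
band_noise <- function(n, fs, band, power) {
  if (power <= 0) return(numeric(n))
  f <- (seq_len(n) - 1) * fs / n
  keep <- (f >= band[1] & f < band[2]) | (f > fs - band[2] & f <= fs - band[1])
  z <- fft(rnorm(n))
  z[!keep] <- 0+0i
  x <- Re(fft(z, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * sqrt(power) / s
}

#' Generate a staged synthetic EEG signal
#'
#' For each contiguous run of a sleep stage in the hypnogram, the signal
#' is the sum of band-limited Gaussian noise components at the stage's
#' target band powers plus a white broadband floor. Artifact-annotated
#' spans are multiplied by 10 (an unambiguous high-amplitude signature;
#' their content is irrelevant because artifacts are excluded by
#' annotation downstream, not detected).
#'
#' @param hypnogram a [hypnogram()].
#' @param spec a [stage_spectrum_spec()] covering every stage present.
#' @param annotations optional [annotation_set()] whose artifact intervals
#'   receive the amplitude signature.
#' @param seed integer seed.
#' @return list with `signal` (µV), `fs`, and `truth` (the spec's target
#'   band powers per stage).
#' @export
generate_sleep_eeg <- function(hypnogram, spec, annotations = NULL, seed = 1L) {
  stopifnot(inherits(hypnogram, "hypnogram"), inherits(spec, "stage_spectrum_spec"))
  present <- unique(hypnogram$stages)
  # require explicit spectral coverage of every stage present: a silently
  # flat stage would corrupt downstream energy ground truth
  missing <- setdiff(present, unique(spec$powers$stage))
  if (length(missing)) {
    stop_fmt("generate_sleep_eeg: stage(s) %s present in the hypnogram but absent from the spectrum spec",
             paste(missing, collapse = ", "))
  }
  fs <- spec$fs
  spe <- as.integer(round(hypnogram$epoch_length * fs))
  n_total <- length(hypnogram$stages) * spe
  with_seed(seed, {
    sig <- numeric(n_total)
    runs <- rle(hypnogram$stages)
    pos <- 0L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k] * spe
      st <- runs$values[k]
      chunk <- if (spec$noise_sd > 0) rnorm(len, sd = spec$noise_sd) else numeric(len)
      rows <- spec$powers[spec$powers$stage == st, , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        chunk <- chunk + band_noise(len, fs, spec$bands[[rows$band[j]]],
                                    rows$power[j])
      }
      sig[(pos + 1L):(pos + len)] <- chunk
      pos <- pos + len
    }
    if (!is.null(annotations)) {
      art <- annotations[annotations$kind == "artifact", , drop = FALSE]
      for (k in seq_len(nrow(art))) {
        a <- max(1L, floor(art$start[k] * fs) + 1L)
        b <- min(n_total, ceiling(art$end[k] * fs))
        if (a <= b) sig[a:b] <- sig[a:b] * 10
      }
    }
    truth <- spec$powers
    list(signal = sig, fs = fs, truth = truth)
  })
}
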