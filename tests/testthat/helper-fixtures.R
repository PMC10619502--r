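# Shared fixture builders; everything is generated in code at test time.

# Small volume with a hand-placed mask: returns volume, mask, and the
# per-slice (slice, row, col, intensity) of the intended argmax.
toy_volume <- function(nx = 12, ny = 12, nz = 3, background = 100) {
  data <- array(background, dim = c(nx, ny, nz))
  mask <- array(FALSE, dim = c(nx, ny, nz))
  planted <- data.frame(slice = 1:nz, row = c(4, 5, 6), col = c(6, 6, 7),
                        intensity = c(120, 130, 125))
  for (k in 1:nz) {
    mask[3:7, 5:8, k] <- TRUE
    data[planted$row[k], planted$col[k], k] <- planted$intensity[k]
  }
  list(volume = lc_volume(data, voxel_size = c(1, 1, 1)), mask = mask,
       planted = planted)
}

# Random volume + random in-plane mask per slice, for oracle checks.
random_masked_volume <- function(seed, nx = 14, ny = 14, nz = 6) {
  set.seed(seed)
  data <- array(rnorm(nx * ny * nz, 100, 10), dim = c(nx, ny, nz))
  mask <- array(runif(nx * ny * nz) < 0.2, dim = c(nx, ny, nz))
  if (!any(mask)) mask[5, 5, 1] <- TRUE
  list(volume = lc_volume(data, voxel_size = c(1, 1, 1)), mask = mask)
}

# Hypnogram from a compact run-length description, e.g.
# stages_hyp(W = 10, N2 = 20, REM = 5, N2 = 3)
stages_hyp <- function(...) {
  runs <- c(...)
  hypnogram(rep(names(runs), runs))
}

# Brute-force in-mask per-slice maximum (independent of skeletonize_lc).
brute_force_skeleton <- function(volume, mask) {
  nz <- dim(volume$data)[3]
  out <- NULL
  for (i in seq_len(nz)) {
    m <- mask[, , i]
    if (!any(m)) next
    v <- volume$data[, , i]
    out <- rbind(out, data.frame(slice = i, intensity = max(v[m])))
  }
  out
}
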