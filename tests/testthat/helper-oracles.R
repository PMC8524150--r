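# Independent oracles used across tests.

# Exhaustive flood-fill labelling (8-connectivity) with an explicit stack;
# independent of the package's graph-based labelling.
floodFillLabel <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Per-component measurement via the covariance eigendecomposition;
# same definitions as the package, independent implementation.
oracleParticles <- function(mask, min_size_px = 15, min_roundness = 0.40) {
  lab <- floodFillLabel(mask)
  out <- data.frame(area = integer(), roundness = numeric())
  if (!max(lab)) return(out)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    n <- nrow(idx)
    xy <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
    S <- if (n == 1) diag(1 / 12, 2) else cov(xy) * (n - 1) / n + diag(1 / 12, 2)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    rnd <- min(sqrt(max(ev[2], 0) / ev[1]), 1)
    if (n > min_size_px && rnd > min_roundness)
      out <- rbind(out, data.frame(area = n, roundness = rnd))
  }
  out
}

# Stamp a filled disc into a logical mask (pixel-center membership).
stampDisc <- function(mask, cx, cy, r) {
  h <- nrow(mask); w <- ncol(mask)
  for (c in seq_len(w)) for (rr in seq_len(h)) {
    if ((c - 0.5 - cx)^2 + (rr - 0.5 - cy)^2 <= r^2) mask[rr, c] <- TRUE
  }
  mask
}

# Build a SectionImage whose stain channel equals 200 on the given mask.
maskImage <- function(mask, pixel_size = 0.001) {
  sectionImage(255 - ifelse(mask, 200, 0), pixel_size = pixel_size)
}

testBand <- function() calibrateThresholds(exemplar_peaks = c(150, 250))

# Minimal SC-only paradigm used to probe the staircase directly.
scOnlyConfig <- function(n_trials, ssd_initial = 450,
                         criterion = "inhibit_only") {
  paradigmConfig("pigeon", n_trials, fraction_go = 0, fraction_scd0 = 0.5,
                 fraction_scd300 = 0.5, ssd_initial = ssd_initial,
                 go_response_window = 5000, intertrial_interval = 5000,
                 staircase_success_criterion = criterion)
}

# Deterministic agent: fixed GO RT and stop latency, no RT2 noise.
fixedAgent <- function(go = 800, stop = 200, d = 165, base = 500) {
  raceAgent(go_mu = go, go_sigma = 0, go_tau = 0, stop_mean = stop,
            stop_sd = 0, change_mu = base, change_sigma = 0, change_tau = 0,
            d_mean = d, d_sd = 0, rt2_noise_sd = 0, change_error_rate = 0)
}
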