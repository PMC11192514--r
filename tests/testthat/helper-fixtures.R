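# shared fixture builders for the test suite

# minimal trial-summary table: one speaker, one vowel, specified init/mid
# distances laid out along the F1 axis from a median at the origin
make_summaries <- function(init_dev, mid_dev = init_dev, vowel = "eat",
                           speaker = "s1", condition = "speak") {
  n <- length(init_dev)
  data.frame(
    trial_id = sprintf("t%02d", seq_len(n)),
    pair_id = sprintf("p%02d", seq_len(n)),
    speaker_id = speaker, vowel = vowel, condition = condition,
    init_f1_mel = 1000 + init_dev, init_f2_mel = 1500,
    mid_f1_mel = 1000 + mid_dev, mid_f2_mel = 1500,
    usable = TRUE, error_flag = "clean", stringsAsFactors = FALSE)
}

# constant-formant track: F1/F2 fixed over the syllable
make_constant_track <- function(f1 = 700, f2 = 1700, dur = 0.2, sfreq = 1000,
                                trial_id = "t1") {
  tt <- seq(0, dur - 1e-9, by = 1 / sfreq)
  formant_track(trial_id, "s1", "eat", "speak", time = tt,
                f1 = rep(f1, length(tt)), f2 = rep(f2, length(tt)),
                onset = 0, offset = dur)
}

# noiseless epoch set with a Gaussian bump at a given latency on every
# vertex (amplitude per vertex given by `profile`)
make_bump_epochs <- function(n_trials = 4, profile = rep(1, 12), sfreq = 250,
                             peak_ms = 100, width_ms = 15, amp = 10,
                             condition = "speak", noise_sd = 0) {
  n_samp <- round(1100 * sfreq / 1000) + 1
  times <- -700 + (seq_len(n_samp) - 1) * 1000 / sfreq
  bump <- amp * exp(-0.5 * ((times - peak_ms) / width_ms)^2)
  arr <- array(0, dim = c(n_trials, length(profile), n_samp))
  for (k in seq_len(n_trials)) arr[k, , ] <- outer(profile, bump)
  if (noise_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim = dim(arr))
  epoch_set(arr, sfreq, condition)
}

# random connected graph on n vertices: a random spanning tree plus extras
random_connected_graph <- function(n, extra = n) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1, 1), integer(1)))
  more <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  rbind(edges, more)
}

# independent oracle for functional-ROI thresholds: the highest threshold
# (on the 1-point grid down from `start`) at which the seed's connected
# above-threshold component holds >= size vertices
oracle_roi_threshold <- function(amp, edges, size = 10, start = 0.33) {
  n <- length(amp)
  nb <- lapply(seq_len(n), function(v) integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  seed <- which.max(amp)
  comp_size <- function(thr) {
    ok <- amp >= thr * max(amp)
    if (!ok[seed]) return(0L)
    seen <- seed; frontier <- seed
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(nb[frontier])), seen)
      nxt <- nxt[ok[nxt]]
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen)
  }
  thr <- start
  while (thr >= 0.01 - 1e-12) {
    if (comp_size(thr) >= size) return(thr)
    thr <- round(thr - 0.01, 10)
  }
  NA_real_
}
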