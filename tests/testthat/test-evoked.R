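test_that("functional ROI growth follows the threshold-decrement rule", {
  lat <- vertex_lattice(6, 5)
  # smooth bump: plenty of connected suprathreshold vertices at 33%
  cx <- lat$coords
  amp <- exp(-((cx[, 1] - 3)^2 + (cx[, 2] - 3)^2) / 6)
  roi <- grow_functional_roi(amp, lat$edges)
  expect_length(roi$vertices, 10)
  expect_equal(roi$threshold_used, 0.33)
  expect_true(roi$seed %in% roi$vertices)
  expect_true(all(amp[roi$vertices] >= 0.33 * max(amp)))

  # only 5 vertices reach 33% of max: threshold must drop below 0.33
  amp2 <- rep(0.05, lat$n_vertices)
  amp2[c(8, 9, 10, 14, 15)] <- 1
  roi2 <- grow_functional_roi(amp2, lat$edges)
  expect_length(roi2$vertices, 10)
  expect_lt(roi2$threshold_used, 0.33)
  expect_true(all(amp2[roi2$vertices] >= roi2$threshold_used * max(amp2) - 1e-12))

  # uniform map: seed is the lowest id, growth greedy by lowest id
  amp3 <- rep(1, lat$n_vertices)
  roi3 <- grow_functional_roi(amp3, lat$edges)
  expect_equal(roi3$seed, 1)
  expect_length(roi3$vertices, 10)

  # isolated high-amplitude island smaller than the ROI: explicit failure
  edges4 <- rbind(c(1, 2), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 8),
                  c(8, 9), c(9, 10), c(10, 11), c(11, 12))
  amp4 <- c(10, 9, rep(0.001, 10))
  expect_error(grow_functional_roi(amp4, edges4, floor_threshold = 0.5),
               "cannot grow")
})

test_that("ROI growth matches the component-reachability oracle on random graphs", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(15:40, 1)
    edges <- random_connected_graph(n)
    amp <- runif(n)
    thr_oracle <- oracle_roi_threshold(amp, edges, size = 10)
    roi <- grow_functional_roi(amp, edges)
    expect_length(roi$vertices, 10)
    expect_equal(roi$threshold_used, thr_oracle)
    expect_true(all(amp[roi$vertices] >= roi$threshold_used * max(amp) - 1e-12))
    # connectivity of the grown region
    sub <- edges[edges[, 1] %in% roi$vertices & edges[, 2] %in% roi$vertices, ,
                 drop = FALSE]
    seen <- roi$seed
    repeat {
      nxt <- unique(c(sub[sub[, 1] %in% seen, 2], sub[sub[, 2] %in% seen, 1]))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    expect_setequal(seen, roi$vertices)
  }
})

test_that("ROI waveform is trial-averaged, vertex-RMS, baseline z-scored", {
  ep <- make_bump_epochs(n_trials = 3, profile = rep(2, 10), amp = 1)
  wf <- roi_waveform(ep, 1:10, zscore = FALSE)
  # all vertices share the constant-profile series: RMS equals that series
  expect_equal(max(wf$z), 2, tolerance = 1e-6)

  # one vertex at a, nine at zero -> RMS = a / sqrt(10)
  prof <- c(3, rep(0, 9))
  ep2 <- make_bump_epochs(n_trials = 2, profile = prof, amp = 1)
  wf2 <- roi_waveform(ep2, 1:10, zscore = FALSE)
  expect_equal(max(wf2$z), 3 / sqrt(10), tolerance = 1e-9)

  # z-scoring standardizes the baseline samples
  set.seed(42)
  ep3 <- make_bump_epochs(n_trials = 5, profile = runif(12, 0.5, 2), amp = 8,
                          noise_sd = 0.3)
  wf3 <- roi_waveform(ep3, 1:12)
  bl <- wf3$times >= -700 & wf3$times <= -400
  expect_equal(mean(wf3$z[bl]), 0, tolerance = 1e-10)
  expect_equal(sd(wf3$z[bl]), 1, tolerance = 1e-10)

  # noiseless baseline has SD 0: degenerate-baseline error
  expect_error(roi_waveform(ep, 1:10), "degenerate baseline")
})

test_that("ROI waveform is invariant to vertex relabeling and trial order", {
  set.seed(43)
  ep <- make_bump_epochs(n_trials = 6, profile = runif(12, 0.5, 2), amp = 5,
                         noise_sd = 0.2)
  wf <- roi_waveform(ep, 1:10)
  perm_tr <- sample(dim(ep$data)[1])
  ep_t <- epoch_set(ep$data[perm_tr, , ], ep$sfreq, ep$condition,
                    trial_ids = ep$trial_ids[perm_tr])
  expect_equal(roi_waveform(ep_t, 1:10)$z, wf$z)
  perm_v <- sample(12)
  ep_v <- epoch_set(ep$data[, perm_v, ], ep$sfreq, ep$condition)
  expect_equal(roi_waveform(ep_v, match(1:10, perm_v))$z, wf$z)
})

test_that("M100 peak detection takes the window maximum with earliest-tie rule", {
  sfreq <- 250
  times <- seq(-700, 400, by = 1000 / sfreq)
  z <- 10 * exp(-0.5 * ((times - 100) / 15)^2)
  pk <- find_m100_peak(list(z = z, times = times))
  expect_lt(abs(pk$latency - 100), 1000 / sfreq)
  expect_false(pk$no_peak)
  expect_false(pk$low_snr)

  z2 <- rep(0, length(times))
  z2[which.min(abs(times - 90))] <- 5
  z2[which.min(abs(times - 120))] <- 5
  pk2 <- find_m100_peak(list(z = z2, times = times))
  expect_equal(pk2$latency, times[which.min(abs(times - 90))])

  flat <- find_m100_peak(list(z = rep(1, length(times)), times = times))
  expect_true(flat$no_peak)
})

test_that("noise-only waveforms are usually flagged low-SNR at the default threshold", {
  set.seed(44)
  flagged <- vapply(1:40, function(i) {
    ep <- make_bump_epochs(n_trials = 8, profile = rep(0, 10), amp = 0,
                           noise_sd = 1)
    find_m100_peak(roi_waveform(ep, 1:10))$low_snr
  }, logical(1))
  expect_gt(mean(flagged), 0.8)
})

test_that("SIS is listen minus speak, antisymmetric, with enhancement flag", {
  s <- compute_sis(10, 4)
  expect_equal(s$sis, 6)
  expect_false(s$enhancement)
  s2 <- compute_sis(10, 12)
  expect_equal(s2$sis, -2)
  expect_true(s2$enhancement)
  set.seed(45)
  for (i in 1:10) {
    a <- rnorm(1, 10, 3); b <- rnorm(1, 8, 3)
    expect_equal(compute_sis(a, b)$sis + compute_sis(b, a)$sis, 0)
  }
  s3 <- compute_sis(10, 4, center = list(listen = 10, speak = 3),
                    peripheral = list(listen = 10, speak = 6))
  expect_equal(s3$falloff, (10 - 3) - (10 - 6))
  expect_error(compute_sis(10, NULL), "required")
})

test_that("noiseless suppression fraction is recovered from raw RMS peaks", {
  es <- evoked_spec(n_vertices = 12, edges = vertex_lattice(4, 3)$edges,
                    supp_frac = 0.5, falloff_slope = 0, noise_sd = 0,
                    listen_amp = 20)
  sim <- simulate_evoked(es, trial_distances = runif(20), rng_seed = 7)
  roi <- grow_functional_roi(
    abs(apply(sim$listen$data, c(2, 3), mean)[, 200]), es$edges)
  pk_l <- find_m100_peak(roi_waveform(sim$listen, roi, zscore = FALSE))
  pk_s <- find_m100_peak(roi_waveform(sim$speak, roi, zscore = FALSE))
  ratio <- (pk_l$amplitude - pk_s$amplitude) / pk_l$amplitude
  # M50/M200 tails overlap the window edges slightly; ratio matches the
  # generative 0.5 up to that morphology leakage
  expect_equal(ratio, 0.5, tolerance = 0.01)
})

test_that("laterality indices live in [-1, 1] with SIS clamping and exclusion", {
  expect_equal(laterality_index(5, 5, "latency")$index, 0)
  expect_equal(laterality_index(0, 3, "amplitude")$index, 1)
  li <- laterality_index(-1, 2, "sis")
  expect_equal(li$index, 1)   # negative SIS clamped to zero suppression
  ex <- laterality_index(-1, -2, "sis")
  expect_true(ex$excluded)
  expect_true(is.na(ex$index))
  expect_error(laterality_index(-1, 2, "latency"), "negative")
  set.seed(46)
  for (i in 1:20) {
    li <- laterality_index(runif(1, 0, 30), runif(1, 0, 30),
                           sample(c("latency", "amplitude", "sis"), 1))
    expect_true(li$excluded || (li$index >= -1 && li$index <= 1))
  }
})
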