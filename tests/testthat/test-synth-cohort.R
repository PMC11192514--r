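test_that("speaker trial simulation is deterministic and respects its spec", {
  sp <- speaker_spec("s1", "control", n_trials_per_word = 40, rng_seed = 9)
  t1 <- simulate_speaker_trials(sp)
  t2 <- simulate_speaker_trials(sp)
  expect_identical(t1$summaries, t2$summaries)
  expect_equal(nrow(t1$summaries), 40 * 3 * 2)   # speak + mirrored listen
  expect_equal(sum(t1$summaries$condition == "speak"), 120)
  # listen trials mirror speak acoustics
  spk <- t1$summaries[t1$summaries$condition == "speak", ]
  lis <- t1$summaries[t1$summaries$condition == "listen", ]
  m <- match(spk$pair_id, lis$pair_id)
  expect_equal(spk$init_f1_mel, lis$init_f1_mel[m])
  expect_equal(spk$mid_f2_mel, lis$mid_f2_mel[m])

  expect_error(speaker_spec("x", sigma_init = -1), "sigma_init")
  expect_error(speaker_spec("x", centering_gain = 1.5), "centering_gain")
  expect_error(speaker_spec("x", error_rate = 1), "error_rate")
  expect_error(speaker_spec("x", sigma_mid = NaN), "sigma_mid")
})

test_that("perfect centering gain collapses mid-window points onto the median", {
  sp <- speaker_spec("s1", centering_gain = 1, sigma_mid = 0,
                     n_trials_per_word = 30, rng_seed = 10)
  tr <- simulate_speaker_trials(sp)
  d <- trial_distances(tr$summaries[tr$summaries$condition == "speak", ])
  expect_true(all(d$mid_dist < 1e-9))
})

test_that("materialized tracks reproduce the generated window points", {
  sp <- speaker_spec("s1", n_trials_per_word = 5, rng_seed = 11)
  tr <- simulate_speaker_trials(sp, tracks = TRUE)
  for (i in seq_len(6)) {
    s <- summarize_trial(tr$tracks[[i]])
    j <- match(s$trial_id, tr$summaries$trial_id)
    expect_equal(s$init_f1_mel, tr$summaries$init_f1_mel[j], tolerance = 1e-9)
    expect_equal(s$mid_f2_mel, tr$summaries$mid_f2_mel[j], tolerance = 1e-9)
  }
})

test_that("g = 0 with matched noise makes forward and reversed centering equal in expectation", {
  # Monte-Carlo oracle: with no corrective gain and sigma_mid = sigma_init
  # the two windows are exchangeable, so the mean difference over many
  # trials is ~0 within MC error
  diffs <- vapply(1:8, function(r) {
    sp <- speaker_spec(sprintf("s%d", r), centering_gain = 0, sigma_init = 25,
                       sigma_mid = 25, n_trials_per_word = 700, rng_seed = 100 + r)
    smm <- simulate_speaker_trials(sp)$summaries
    d <- trial_distances(smm[smm$condition == "speak", ])
    cf <- centering(d, "forward", mode = "median_split")
    cr <- centering(d, "reversed", mode = "median_split")
    cf$centering - cr$centering
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 0.5)
})

test_that("expected centering increases strictly with the gain under shared seeds", {
  gains <- c(0, 0.25, 0.5, 0.75, 1)
  cen <- vapply(gains, function(g) {
    vals <- vapply(1:5, function(r) {
      sp <- speaker_spec("s", centering_gain = g, n_trials_per_word = 200,
                         rng_seed = 300 + r)   # same seeds across gains
      smm <- simulate_speaker_trials(sp)$summaries
      d <- trial_distances(smm[smm$condition == "speak", ])
      centering(d, "forward", n = 60)$centering
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(cen) > 0))
})

test_that("evoked simulation honors its degenerate contracts", {
  es0 <- evoked_spec(n_vertices = 12, edges = vertex_lattice(4, 3)$edges,
                     supp_frac = 0, falloff_slope = 0, noise_sd = 0)
  sim0 <- simulate_evoked(es0, runif(10), rng_seed = 1)
  expect_identical(sim0$speak$data, sim0$listen$data)

  es <- evoked_spec(n_vertices = 12, edges = vertex_lattice(4, 3)$edges,
                    supp_frac = 0.5, falloff_slope = 0, noise_sd = 0)
  sim <- simulate_evoked(es, runif(10), rng_seed = 1)
  # M100 sample: vertex-mean speak amplitude = half the listen amplitude
  # M50/M200 tails contribute ~0.2% unsuppressed signal at 100 ms
  i100 <- which.min(abs(sim$listen$times - 100))
  expect_equal(mean(sim$speak$data[, , i100]),
               0.5 * mean(sim$listen$data[, , i100]), tolerance = 5e-3)
  expect_error(evoked_spec(sfreq = -1), "sfreq")
  expect_error(evoked_spec(supp_frac = 1.2), "supp_frac")
})

test_that("per-trial suppression scaling is clipped to [0, 1]", {
  es <- evoked_spec(n_vertices = 12, edges = vertex_lattice(4, 3)$edges,
                    supp_frac = 0.9, falloff_slope = 2, noise_sd = 0)
  sim <- simulate_evoked(es, runif(30), rng_seed = 2)
  expect_true(all(sim$scaling >= 0 & sim$scaling <= 1))
  expect_true(any(sim$scaling == 1))  # peripheral trials hit the clip
})

test_that("rank normalization maps distances to [0, 1] within vowel", {
  d <- c(5, 1, 3, 10, 2, 8)
  v <- c("a", "a", "a", "b", "b", "b")
  r <- rank_normalize(d, v)
  expect_equal(r[1:3], c(1, 0, 0.5))
  expect_equal(r[4:6], c(1, 0, 0.5))
  expect_equal(rank_normalize(3), 0.5)
})

test_that("lesion simulation matches the ellipsoid membership test", {
  ls <- lesion_spec(grid_shape = c(16, 16, 16),
                    roi_boxes = list(A = list(min = c(2, 2, 2), max = c(7, 7, 7))),
                    lesion_center = c(8, 8, 8), lesion_radii = c(4, 3, 5))
  vols <- simulate_lesion(ls)
  # brute-force voxel enumeration oracle
  cnt <- 0
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    inside <- ((i - 8) / 4)^2 + ((j - 8) / 3)^2 + ((k - 8) / 5)^2 <= 1
    cnt <- cnt + inside
    expect_equal(vols$lesion$grid[i, j, k], as.integer(inside))
  }
  expect_equal(sum(vols$lesion$grid), cnt)

  # zero radius -> empty lesion, everything spared
  ls0 <- lesion_spec(lesion_radii = c(0, 0, 0))
  v0 <- simulate_lesion(ls0)
  expect_equal(sum(v0$lesion$grid), 0)
  p0 <- lesion_profile(v0$lesion, v0$rois)
  expect_true(all(p0$percent_spared == 100))

  # ellipsoid covering a ROI box entirely -> 0% spared
  ls1 <- lesion_spec(grid_shape = c(20, 20, 20),
                     roi_boxes = list(A = list(min = c(9, 9, 9),
                                               max = c(11, 11, 11))),
                     lesion_center = c(10, 10, 10), lesion_radii = c(8, 8, 8))
  v1 <- simulate_lesion(ls1)
  p1 <- lesion_profile(v1$lesion, v1$rois)
  expect_equal(unname(p1$percent_spared["A"]), 0)

  expect_error(lesion_spec(roi_boxes = list(A = list(min = c(0, 1, 1),
                                                     max = c(2, 2, 2)))),
               "fit within")
})

test_that("a fixed master seed reproduces the cohort bit-identically", {
  c1 <- simulate_cohort(n_per_group = 2, n_trials_per_word = 20, rng_seed = 77)
  c2 <- simulate_cohort(n_per_group = 2, n_trials_per_word = 20, rng_seed = 77)
  expect_identical(c1$summaries, c2$summaries)
  expect_identical(c1$participants, c2$participants)
  c3 <- simulate_cohort(n_per_group = 2, n_trials_per_word = 20, rng_seed = 78)
  expect_false(identical(c1$summaries, c3$summaries))
  expect_equal(nrow(c1$participants), 4)
  expect_equal(sum(c1$participants$group == "aphasia"), 2)
  expect_true(all(vapply(c1$speakers[c1$participants$group == "aphasia"],
                         function(s) inherits(s$lesion_spec, "lesion_spec"),
                         logical(1))))
})
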