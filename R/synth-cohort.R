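# Default vowel medians (mel) for the three stimulus words, typical adult
# American English values for /i/ ("eat"), /E/ ("Ed"), /ae/ ("add").
default_vowel_medians <- function() {
  hz <- list(eat = c(300, 2300), Ed = c(550, 1800), add = c(700, 1650))
  lapply(hz, hz_to_mel)
}

#' Specification of one synthetic speaker's formant behavior
#'
#' Generative model per trial: a latent feedforward deviation
#' `eps ~ N(0, sigma_init^2 I)` in the mel F1-F2 plane carries through the
#' syllable unless corrected, and each analysis window adds its own
#' articulatory/measurement noise:
#' `init = median + eps + nu1` and `mid = median + (1 - g) * eps + nu2`,
#' with `nu1, nu2 ~ N(0, sigma_mid^2 I)` independent. `g = 0` means no
#' feedback correction — the two windows are then exchangeable, so any
#' apparent centering is pure regression to the median — while `g = 1`
#' removes the planned deviation entirely by mid-utterance.
#'
#' Defaults were calibrated so a default cohort reproduces group-mean
#' peripheral distances of about 62 mels (initial) and 42 mels (mid), i.e.
#' centering of about 20 mels (a 32% reduction).
#'
#' @param speaker_id Speaker label.
#' @param group `"control"` or `"aphasia"`.
#' @param vowel_medians Named list of `(F1_mel, F2_mel)` centers.
#' @param sigma_init SD of the latent feedforward deviation, mels (>= 0).
#' @param centering_gain Fraction of the latent deviation removed by
#'   mid-utterance, in `[0, 1]`.
#' @param sigma_mid SD of the independent per-window noise, mels (>= 0).
#' @param n_trials_per_word Speak trials per word (listen trials mirror
#'   them).
#' @param error_rate Probability a speak trial is marked errorful, in
#'   `[0, 1)`.
#' @param rng_seed Integer seed making the speaker's trials reproducible.
#' @return Object of class `speaker_spec`.
#' @export
speaker_spec <- function(speaker_id, group = c("control", "aphasia"),
                         vowel_medians = default_vowel_medians(),
                         sigma_init = 25.2, centering_gain = 0.22,
                         sigma_mid = 12, n_trials_per_word = 200,
                         error_rate = 0.005, rng_seed = 1L) {
  group <- match.arg(group)
  num_ok <- function(x) length(x) == 1 && is.finite(x)
  if (!num_ok(sigma_init) || sigma_init < 0) stop("sigma_init must be finite, >= 0")
  if (!num_ok(sigma_mid) || sigma_mid < 0) stop("sigma_mid must be finite, >= 0")
  if (!num_ok(centering_gain) || centering_gain < 0 || centering_gain > 1)
    stop("centering_gain must be in [0, 1]")
  if (!num_ok(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  if (!num_ok(n_trials_per_word) || n_trials_per_word < 1)
    stop("n_trials_per_word must be >= 1")
  if (any(!is.finite(unlist(vowel_medians)))) stop("vowel medians must be finite")
  structure(list(speaker_id = as.character(speaker_id), group = group,
                 vowel_medians = vowel_medians, sigma_init = sigma_init,
                 centering_gain = centering_gain, sigma_mid = sigma_mid,
                 n_trials_per_word = as.integer(n_trials_per_word),
                 error_rate = error_rate, rng_seed = as.integer(rng_seed)),
            class = "speaker_spec")
}

#' Simulate one speaker's formant trials
#'
#' Draws speak trials per vowel under the [speaker_spec()] generative
#' model, mirrors each as a listen trial with identical acoustics, flags
#' errorful speak trials with probability `error_rate`, and (optionally)
#' materializes full formant tracks whose windowed summaries recover the
#' generated points exactly. Output is deterministic given `rng_seed`.
#'
#' @param spec A [speaker_spec()].
#' @param tracks If `TRUE`, also return a list of [formant_track()] objects
#'   (piecewise-linear trajectories: initial value over the first 50 ms, a
#'   linear transition, then the mid value over the rest of the syllable).
#' @param syllable_s Voiced syllable duration in seconds (default 0.25).
#' @param track_sfreq Track sampling rate in Hz (default 200).
#' @return List: `summaries` (a trial-summary data.frame with `pair_id`,
#'   windowed mel points, `error_flag`, and the ground-truth
#'   `true_init_dist`), `annotations` (pairing/error table for
#'   [reject_error_trials()]), and `tracks` (or `NULL`).
#' @export
simulate_speaker_trials <- function(spec, tracks = FALSE, syllable_s = 0.25,
                                    track_sfreq = 200) {
  stopifnot(inherits(spec, "speaker_spec"))
  set.seed(spec$rng_seed)
  vowels <- names(spec$vowel_medians)
  n <- spec$n_trials_per_word
  rows <- list()
  g <- spec$centering_gain
  for (v in vowels) {
    mu <- spec$vowel_medians[[v]]
    e1 <- stats::rnorm(n, 0, spec$sigma_init)
    e2 <- stats::rnorm(n, 0, spec$sigma_init)
    i1 <- mu[1] + e1 + stats::rnorm(n, 0, spec$sigma_mid)
    i2 <- mu[2] + e2 + stats::rnorm(n, 0, spec$sigma_mid)
    m1 <- mu[1] + (1 - g) * e1 + stats::rnorm(n, 0, spec$sigma_mid)
    m2 <- mu[2] + (1 - g) * e2 + stats::rnorm(n, 0, spec$sigma_mid)
    err <- stats::runif(n) < spec$error_rate
    err_cat <- ifelse(err, sample(c("omission", "misselection", "distortion",
                                    "other_word"), n, replace = TRUE), "clean")
    rows[[v]] <- data.frame(
      pair_id = sprintf("%s_%s_%03d", spec$speaker_id, v, seq_len(n)),
      speaker_id = spec$speaker_id, vowel = v,
      init_f1_mel = i1, init_f2_mel = i2,
      mid_f1_mel = m1, mid_f2_mel = m2,
      true_init_dist = sqrt((i1 - mu[1])^2 + (i2 - mu[2])^2),
      error_flag = err_cat, stringsAsFactors = FALSE)
  }
  sp <- do.call(rbind, rows)
  rownames(sp) <- NULL
  mk <- function(cond, flag) {
    data.frame(trial_id = paste0(sp$pair_id, "_", cond), pair_id = sp$pair_id,
               speaker_id = sp$speaker_id, vowel = sp$vowel, condition = cond,
               init_f1_mel = sp$init_f1_mel, init_f2_mel = sp$init_f2_mel,
               mid_f1_mel = sp$mid_f1_mel, mid_f2_mel = sp$mid_f2_mel,
               usable = TRUE, error_flag = flag,
               true_init_dist = sp$true_init_dist, stringsAsFactors = FALSE)
  }
  # listen trials replay the recorded audio, so acoustics mirror speak;
  # listen-side artifacts are not part of this generator (flag stays clean)
  summaries <- rbind(mk("speak", sp$error_flag), mk("listen", "clean"))
  annotations <- summaries[, c("trial_id", "pair_id", "condition", "error_flag")]
  trk <- NULL
  if (tracks) {
    trk <- lapply(seq_len(nrow(summaries)), function(i) {
      r <- summaries[i, ]
      tt <- seq(0, syllable_s - 1e-9, by = 1 / track_sfreq)
      t_init_end <- 0.05
      t_mid_start <- 0.25 * syllable_s
      wt <- pmin(pmax((tt - t_init_end) / (t_mid_start - t_init_end), 0), 1)
      f1 <- mel_to_hz((1 - wt) * r$init_f1_mel + wt * r$mid_f1_mel)
      f2 <- mel_to_hz((1 - wt) * r$init_f2_mel + wt * r$mid_f2_mel)
      formant_track(r$trial_id, r$speaker_id, r$vowel, r$condition,
                    time = tt, f1 = f1, f2 = f2, onset = 0, offset = syllable_s,
                    error_flag = r$error_flag)
    })
  }
  list(summaries = summaries, annotations = annotations, tracks = trk)
}

#' Build a rectangular vertex lattice graph
#'
#' A simple abstract stand-in for a cortical mesh patch: an `nx` by `ny`
#' grid with 4-neighbor connectivity.
#'
#' @param nx,ny Lattice dimensions.
#' @return List: `n_vertices`, `edges` (2-column matrix), `coords`.
#' @export
vertex_lattice <- function(nx = 6, ny = 5) {
  id <- function(i, j) (j - 1) * nx + i
  edges <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) edges[[length(edges) + 1]] <- c(id(i, j), id(i + 1, j))
    if (j < ny) edges[[length(edges) + 1]] <- c(id(i, j), id(i, j + 1))
  }
  coords <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  list(n_vertices = nx * ny, edges = do.call(rbind, edges), coords = coords)
}

# BFS graph distances from a source vertex
graph_bfs_dist <- function(nb, from, n) {
  d <- rep(Inf, n); d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nb[frontier])), which(is.finite(d)))
    if (!length(nxt)) break
    d[nxt] <- d[frontier[1]] + 1
    # all frontier vertices share the same distance in BFS layers
    frontier <- nxt
  }
  d
}

#' Specification of synthetic source-space evoked responses
#'
#' Evoked epochs have the canonical M50/M100/M200 morphology (Gaussian
#' components) riding on a smooth spatial bump over a vertex graph, plus
#' i.i.d. Gaussian sensor noise. Listen trials carry the full M100
#' amplitude; each speak trial's M100 component is scaled by
#' `clip(1 - supp_frac + falloff_slope * d, 0, 1)` where `d` is that
#' trial's within-vowel rank-normalized initial formant distance in
#' `[0, 1]` — so suppression is strongest for the most typical (center)
#' productions and weakens toward the periphery.
#'
#' @param n_vertices Number of vertices (default 30, a 6 x 5 lattice).
#' @param edges 2-column adjacency matrix (defaults to the lattice).
#' @param listen_amp M100 source amplitude in the listen condition.
#' @param supp_frac Mean speak-condition suppression fraction, in `[0, 1]`.
#' @param falloff_slope Suppression lost per unit normalized distance
#'   (>= 0 gives SIS fall-off from center to periphery).
#' @param latencies Component latencies in ms (M50, M100, M200).
#' @param component_widths Gaussian SDs in ms.
#' @param component_amps Relative component amplitudes (M100 = 1).
#' @param noise_sd SD of additive noise, source units.
#' @param sfreq Sampling rate, Hz.
#' @param epoch_bounds,baseline_bounds Epoch and baseline intervals, ms.
#' @param bump_center Vertex at the top of the spatial bump (default: a
#'   graph-central vertex).
#' @param bump_sd Spatial bump width in graph-distance units.
#' @return Object of class `evoked_spec`.
#' @export
evoked_spec <- function(n_vertices = 30, edges = vertex_lattice(6, 5)$edges,
                        listen_amp = 50, supp_frac = 0.5, falloff_slope = 0,
                        latencies = c(m50 = 50, m100 = 100, m200 = 200),
                        component_widths = c(12, 18, 30),
                        component_amps = c(0.4, 1, 0.5),
                        noise_sd = 1, sfreq = 250,
                        epoch_bounds = c(-700, 400),
                        baseline_bounds = c(-700, -400),
                        bump_center = NULL, bump_sd = 1.5) {
  if (!is.finite(sfreq) || sfreq <= 0) stop("sfreq must be > 0")
  if (supp_frac < 0 || supp_frac > 1) stop("supp_frac must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nb <- edge_neighbors(edges, n_vertices)
  if (is.null(bump_center)) {
    ecc <- vapply(seq_len(n_vertices), function(v)
      max(graph_bfs_dist(nb, v, n_vertices)), numeric(1))
    bump_center <- which.min(ecc)
  }
  structure(list(n_vertices = n_vertices, edges = edges,
                 listen_amp = listen_amp, supp_frac = supp_frac,
                 falloff_slope = falloff_slope, latencies = latencies,
                 component_widths = component_widths,
                 component_amps = component_amps, noise_sd = noise_sd,
                 sfreq = sfreq, epoch_bounds = epoch_bounds,
                 baseline_bounds = baseline_bounds,
                 bump_center = bump_center, bump_sd = bump_sd),
            class = "evoked_spec")
}

#' Rank-normalize distances within vowel to \[0, 1\]
#'
#' The typicality covariate for suppression: `(rank - 1) / (n - 1)` with
#' mid-ranks for ties, computed within each vowel (scale-free, matching the
#' center/peripheral ranking logic). A vowel with a single trial maps to
#' 0.5.
#'
#' @param distances Numeric vector of initial distances.
#' @param vowel Vowel label per trial (single vowel assumed if `NULL`).
#' @return Numeric vector in `[0, 1]`.
#' @export
rank_normalize <- function(distances, vowel = NULL) {
  if (is.null(vowel)) vowel <- rep("v", length(distances))
  out <- numeric(length(distances))
  for (v in unique(vowel)) {
    i <- vowel == v
    n <- sum(i)
    out[i] <- if (n == 1) 0.5 else (rank(distances[i]) - 1) / (n - 1)
  }
  out
}

#' Simulate speak and listen evoked epochs
#'
#' @param spec An [evoked_spec()].
#' @param trial_distances Per-trial initial formant distances (one per
#'   speak trial); their within-vowel normalized ranks drive the per-trial
#'   suppression scaling.
#' @param vowel Optional vowel label per trial for within-vowel ranking.
#' @param hemisphere `"left"` or `"right"`.
#' @param rng_seed Integer seed.
#' @param trial_ids Optional trial id vector (shared by both conditions).
#' @return List with `speak` and `listen` [epoch_set()]s (aligned trials)
#'   and `scaling` (the per-trial speak M100 scale factors).
#' @export
simulate_evoked <- function(spec, trial_distances, vowel = NULL,
                            hemisphere = "left", rng_seed = 1L,
                            trial_ids = NULL) {
  stopifnot(inherits(spec, "evoked_spec"))
  n_tr <- length(trial_distances)
  if (n_tr < 1) stop("need at least one trial")
  set.seed(rng_seed)
  d_norm <- rank_normalize(trial_distances, vowel)
  scaling <- pmin(pmax(1 - spec$supp_frac + spec$falloff_slope * d_norm, 0), 1)
  n_samp <- round((spec$epoch_bounds[2] - spec$epoch_bounds[1]) * spec$sfreq / 1000) + 1
  times <- spec$epoch_bounds[1] + (seq_len(n_samp) - 1) * 1000 / spec$sfreq
  gauss <- function(lat, wid) exp(-0.5 * ((times - lat) / wid)^2)
  comp <- mapply(gauss, spec$latencies, spec$component_widths)  # samples x 3
  other <- comp[, c(1, 3)] %*% spec$component_amps[c(1, 3)]
  m100 <- comp[, 2] * spec$component_amps[2]
  nb <- edge_neighbors(spec$edges, spec$n_vertices)
  gd <- graph_bfs_dist(nb, spec$bump_center, spec$n_vertices)
  profile <- exp(-0.5 * (gd / spec$bump_sd)^2)
  mk_array <- function(scales) {
    arr <- array(0, dim = c(n_tr, spec$n_vertices, n_samp))
    for (k in seq_len(n_tr)) {
      sig <- spec$listen_amp * outer(profile, as.numeric(other + scales[k] * m100))
      arr[k, , ] <- sig
    }
    if (spec$noise_sd > 0)
      arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sd), dim = dim(arr))
    arr
  }
  listen_arr <- mk_array(rep(1, n_tr))
  speak_arr <- mk_array(scaling)
  list(
    speak = epoch_set(speak_arr, spec$sfreq, "speak", hemisphere,
                      spec$epoch_bounds, spec$baseline_bounds, trial_ids),
    listen = epoch_set(listen_arr, spec$sfreq, "listen", hemisphere,
                       spec$epoch_bounds, spec$baseline_bounds, trial_ids),
    scaling = scaling)
}

#' Specification of a synthetic lesion and ROI geometry
#'
#' An ellipsoidal lesion over box-shaped atlas ROIs on a shared voxel grid;
#' a deliberately simple geometry with exactly countable overlaps.
#'
#' @param grid_shape Length-3 integer voxel grid shape.
#' @param voxel_mm Length-3 voxel size in mm.
#' @param roi_boxes Named list; each element `list(min = c(i, j, k),
#'   max = c(i, j, k))` in voxel indices (inclusive).
#' @param lesion_center Ellipsoid center, voxel coordinates.
#' @param lesion_radii Ellipsoid radii in voxels (a radius of 0 yields an
#'   empty lesion).
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(grid_shape = c(24, 24, 24), voxel_mm = c(1, 1, 1),
                        roi_boxes = list(
                          IFO = list(min = c(3, 3, 3), max = c(8, 8, 8)),
                          STG = list(min = c(12, 12, 12), max = c(19, 19, 19))),
                        lesion_center = c(10, 10, 10),
                        lesion_radii = c(6, 5, 5)) {
  if (any(voxel_mm <= 0)) stop("voxel_mm must be > 0")
  for (nm in names(roi_boxes)) {
    b <- roi_boxes[[nm]]
    if (any(b$min < 1) || any(b$max > grid_shape) || any(b$min > b$max))
      stop(sprintf("ROI box '%s' does not fit within the grid", nm))
  }
  if (any(lesion_radii < 0)) stop("lesion radii must be >= 0")
  if (any(lesion_center - lesion_radii < 0.5) ||
      any(lesion_center + lesion_radii > grid_shape + 0.5))
    stop("lesion ellipsoid does not fit within the grid")
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 roi_boxes = roi_boxes, lesion_center = lesion_center,
                 lesion_radii = lesion_radii),
            class = "lesion_spec")
}

#' Simulate lesion and ROI masks
#'
#' Voxel (i, j, k) belongs to the lesion iff
#' `sum(((idx - center) / radii)^2) <= 1` (empty if any radius is 0); ROI
#' boxes are filled inclusively. All masks are [binary_volume()]s on the
#' shared grid and can be written to NIfTI with [write_volume_nifti()].
#'
#' @param spec A [lesion_spec()].
#' @param space_label Space label for the produced volumes.
#' @return List: `lesion` ([binary_volume()]) and `rois` (named list of
#'   [binary_volume()]s).
#' @export
simulate_lesion <- function(spec, space_label = "synthetic") {
  stopifnot(inherits(spec, "lesion_spec"))
  gs <- spec$grid_shape
  idx <- expand.grid(i = seq_len(gs[1]), j = seq_len(gs[2]), k = seq_len(gs[3]))
  if (any(spec$lesion_radii == 0)) {
    inside <- rep(FALSE, nrow(idx))
  } else {
    inside <- ((idx$i - spec$lesion_center[1]) / spec$lesion_radii[1])^2 +
              ((idx$j - spec$lesion_center[2]) / spec$lesion_radii[2])^2 +
              ((idx$k - spec$lesion_center[3]) / spec$lesion_radii[3])^2 <= 1
  }
  lesion <- binary_volume(array(as.integer(inside), dim = gs),
                          spec$voxel_mm, space_label)
  rois <- lapply(spec$roi_boxes, function(b) {
    g <- array(0L, dim = gs)
    g[b$min[1]:b$max[1], b$min[2]:b$max[2], b$min[3]:b$max[3]] <- 1L
    binary_volume(g, spec$voxel_mm, space_label)
  })
  list(lesion = lesion, rois = rois)
}

#' Simulate a full study cohort
#'
#' Builds a control and an aphasia group of synthetic speakers (formant
#' trials with speak/listen pairing and error dropout) plus, for the
#' aphasia group, per-speaker lesion geometries whose ellipsoid radii vary
#' across speakers. Defaults mirror the study design: 15 speakers per
#' group, 3 words x 200 trials x 2 conditions; all counts are
#' configurable. The cohort is bit-reproducible for a fixed `rng_seed`.
#'
#' @param n_per_group Speakers per group (default 15).
#' @param n_trials_per_word Speak trials per word (default 200).
#' @param centering_gain,sigma_init,sigma_mid Generator parameters shared
#'   by all speakers (see [speaker_spec()]).
#' @param error_rate_control,error_rate_aphasia Speak-trial error
#'   probabilities per group.
#' @param rng_seed Integer master seed; per-speaker seeds are derived from
#'   it.
#' @param tracks Materialize full formant tracks (slow; default FALSE).
#' @return List of class `synthetic_cohort`: `speakers` (list with per-
#'   speaker `spec`, `summaries`, `annotations`, and for aphasia
#'   `lesion_spec`), `summaries` (combined trial table), `participants`
#'   (one row per speaker: id, group, generative parameters).
#' @export
simulate_cohort <- function(n_per_group = 15, n_trials_per_word = 200,
                            centering_gain = 0.22, sigma_init = 25.2,
                            sigma_mid = 12, error_rate_control = 0.005,
                            error_rate_aphasia = 0.1, rng_seed = 1L,
                            tracks = FALSE) {
  set.seed(rng_seed)
  speakers <- list()
  part_rows <- list()
  all_sum <- list()
  sid <- 0
  for (grp in c("control", "aphasia")) {
    err <- if (grp == "control") error_rate_control else error_rate_aphasia
    for (k in seq_len(n_per_group)) {
      sid <- sid + 1
      id <- sprintf("%s%02d", if (grp == "control") "c" else "s", k)
      # per-speaker vowel-space offset (individual anatomy / voice)
      med <- lapply(default_vowel_medians(), function(m)
        m + stats::rnorm(2, 0, 15))
      seed_k <- (rng_seed * 1000L + sid) %% .Machine$integer.max
      spk <- speaker_spec(id, grp, vowel_medians = med,
                          sigma_init = sigma_init,
                          centering_gain = centering_gain,
                          sigma_mid = sigma_mid,
                          n_trials_per_word = n_trials_per_word,
                          error_rate = err, rng_seed = seed_k)
      trials <- simulate_speaker_trials(spk, tracks = tracks)
      entry <- list(spec = spk, summaries = trials$summaries,
                    annotations = trials$annotations, tracks = trials$tracks)
      if (grp == "aphasia") {
        set.seed(seed_k + 7L)
        # center jitter is +/-2 around (10,10,10) on a 24^3 grid, so radii
        # up to 6 always fit
        radii <- stats::runif(3, 2, 6)
        entry$lesion_spec <- lesion_spec(lesion_center = c(10, 10, 10) +
                                           round(stats::runif(3, -2, 2)),
                                         lesion_radii = radii)
      }
      speakers[[id]] <- entry
      all_sum[[id]] <- trials$summaries
      part_rows[[id]] <- data.frame(
        speaker_id = id, group = grp, centering_gain = centering_gain,
        sigma_init = sigma_init, sigma_mid = sigma_mid, error_rate = err,
        n_trials_per_word = n_trials_per_word, stringsAsFactors = FALSE)
    }
  }
  structure(list(speakers = speakers,
                 summaries = do.call(rbind, c(all_sum, make.row.names = FALSE)),
                 participants = do.call(rbind, c(part_rows,
                                                 make.row.names = FALSE)),
                 rng_seed = rng_seed),
            class = "synthetic_cohort")
}
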