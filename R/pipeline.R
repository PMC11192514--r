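#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. Defaults
#' mirror the study design (15 speakers per group, 3 words x 200 trials x 2
#' conditions, 125-trial center/peripheral subsets); the evoked stage runs
#' on a reduced vertex graph and trial count so a full cohort completes in
#' minutes. Every field can be overridden, or the whole config read from a
#' YAML file with [read_config()].
#'
#' @param ... Named overrides of any top-level or `evoked` field.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_per_group = 15,
    n_trials_per_word = 200,
    centering_gain = 0.22,
    sigma_init = 25.2,
    sigma_mid = 12,
    error_rate_control = 0.005,
    error_rate_aphasia = 0.1,
    n_subset = 125,
    seed = 1L,
    alpha = 0.05,
    search_window = c(70, 180),
    evoked = list(n_vertices = 30, listen_amp = 50, supp_frac = 0.5,
                  falloff_slope = 0.25, noise_sd = 1, sfreq = 250,
                  n_trials = 100),
    out_dir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "evoked") cfg$evoked <- utils::modifyList(cfg$evoked, dots$evoked)
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# short stable fingerprint of a config (polynomial hash of its serialized
# bytes, mod 2^31; enough to spot a changed configuration in a log)
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Acoustic analysis for one speaker
#'
#' Rejects errorful speak/listen pairs, computes windowed distances to the
#' per-vowel medians (speak trials), and returns forward and time-reversed
#' centering plus variability summaries.
#'
#' @param summaries One speaker's trial summary table (both conditions).
#' @param annotations Pairing/error annotations for
#'   [reject_error_trials()].
#' @param n_subset Center/peripheral subset size (e.g. 125); reduced
#'   automatically is *not* done — an insufficient trial count errors.
#' @return List: `speak` (usable speak summaries with distances),
#'   `centering` (two rows: forward and reversed), `var_init_all`,
#'   `n_pairs`, `error_counts`.
#' @export
analyze_speaker_acoustics <- function(summaries, annotations, n_subset = 125) {
  kept <- reject_error_trials(annotations)
  speak <- summaries[summaries$condition == "speak" &
                     summaries$pair_id %in% kept$pairs, , drop = FALSE]
  speak <- trial_distances(speak)
  cen_f <- centering(speak, "forward", n = n_subset)
  cen_r <- centering(speak, "reversed", n = n_subset)
  list(speak = speak,
       centering = rbind(cen_f, cen_r),
       var_init_all = unname(variability(speak, "initial")),
       n_pairs = length(kept$pairs),
       error_counts = kept$error_counts)
}

#' Evoked analysis for one speaker and hemisphere
#'
#' Simulates source-space epochs driven by the speaker's usable speak-trial
#' distances, then runs the full evoked pipeline: functional ROI growth on
#' the amplitude map at the listen M100 latency, baseline z-scored RMS
#' waveforms, M100 peaks per condition, SIS, and the median-split SIS
#' fall-off (center half minus peripheral half, listen halves paired to the
#' speak halves).
#'
#' @param speak Usable speak summaries with `init_dist` (from
#'   [analyze_speaker_acoustics()]).
#' @param espec An [evoked_spec()].
#' @param hemisphere `"left"` or `"right"`.
#' @param rng_seed Seed for the epoch simulation.
#' @param search_window M100 search window, ms.
#' @param n_trials Number of speak trials to carry into the evoked stage
#'   (a deterministic balanced subsample keeps runtime bounded); `NULL`
#'   uses all.
#' @return One-row data.frame: peaks, SIS, halves, fall-off, ROI threshold.
#' @export
analyze_speaker_evoked <- function(speak, espec, hemisphere = "left",
                                   rng_seed = 1L, search_window = c(70, 180),
                                   n_trials = NULL) {
  if (!is.null(n_trials) && nrow(speak) > n_trials) {
    # evenly spaced subsample within vowel by trial order (deterministic)
    keep <- unlist(lapply(split(seq_len(nrow(speak)), speak$vowel), function(i) {
      k <- max(2, round(n_trials * length(i) / nrow(speak)))
      i[unique(round(seq(1, length(i), length.out = k)))]
    }))
    speak <- speak[sort(keep), , drop = FALSE]
  }
  sim <- simulate_evoked(espec, speak$init_dist, vowel = speak$vowel,
                         hemisphere = hemisphere, rng_seed = rng_seed,
                         trial_ids = speak$trial_id)
  # amplitude map at the listen M100 latency: vertex-mean evoked
  ev <- apply(sim$listen$data, c(2, 3), mean)
  rms_all <- sqrt(colMeans(ev^2))
  win <- sim$listen$times >= search_window[1] & sim$listen$times <= search_window[2]
  peak_samp <- which(win)[which.max(rms_all[win])]
  amp_map <- abs(ev[, peak_samp])
  roi <- grow_functional_roi(amp_map, espec$edges)
  wf_l <- roi_waveform(sim$listen, roi)
  wf_s <- roi_waveform(sim$speak, roi)
  pk_l <- find_m100_peak(wf_l, search_window)
  pk_s <- find_m100_peak(wf_s, search_window)
  halves <- partition_trials(speak, mode = "median_split")
  half_peak <- function(lab) {
    ids <- halves$trial_id[halves$subset_label == lab]
    list(listen = find_m100_peak(roi_waveform(subset_epochs(sim$listen, ids), roi),
                                 search_window),
         speak = find_m100_peak(roi_waveform(subset_epochs(sim$speak, ids), roi),
                                search_window))
  }
  ctr <- half_peak("center"); per <- half_peak("peripheral")
  sis <- compute_sis(pk_l, pk_s, center = ctr, peripheral = per)
  data.frame(speaker_id = speak$speaker_id[1], hemisphere = hemisphere,
             listen_latency = pk_l$latency, speak_latency = pk_s$latency,
             listen_amplitude = pk_l$amplitude, speak_amplitude = pk_s$amplitude,
             sis = sis$sis, enhancement = sis$enhancement,
             sis_center = sis$sis_center, sis_peripheral = sis$sis_peripheral,
             falloff = sis$falloff, roi_threshold = roi$threshold_used,
             low_snr = pk_l$low_snr || pk_s$low_snr,
             stringsAsFactors = FALSE)
}

#' Run the end-to-end synthetic-cohort pipeline
#'
#' Simulates a cohort, then per speaker: error rejection and pairing,
#' acoustic centering (forward and time-reversed), evoked analysis in both
#' hemispheres (M100, SIS, fall-off), and for the aphasia group a lesion
#' profile. Finishes with the study-level statistics: the time-direction
#' centering ANOVA, the Group x Hemisphere SIS ANOVA, the left-hemisphere
#' fall-off ANOVA restricted to suppressors, group t tests, laterality
#' indices, and lesion-behavior correlations. Writes per-stage CSVs, a JSON
#' summary, and a log with the seed and config hash when `out_dir` is set;
#' reruns with the same config and seed are bit-identical.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return List of class `pipeline_result`: `centering`, `evoked`,
#'   `lesion`, `laterality`, `anova` (list of tables), `tests`,
#'   `correlations`, `summary` (flat named list), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  cohort <- simulate_cohort(
    n_per_group = config$n_per_group,
    n_trials_per_word = config$n_trials_per_word,
    centering_gain = config$centering_gain,
    sigma_init = config$sigma_init, sigma_mid = config$sigma_mid,
    error_rate_control = config$error_rate_control,
    error_rate_aphasia = config$error_rate_aphasia,
    rng_seed = config$seed)

  ev <- config$evoked
  espec <- evoked_spec(n_vertices = ev$n_vertices,
                       edges = vertex_lattice(6, ceiling(ev$n_vertices / 6))$edges,
                       listen_amp = ev$listen_amp, supp_frac = ev$supp_frac,
                       falloff_slope = ev$falloff_slope, noise_sd = ev$noise_sd,
                       sfreq = ev$sfreq)

  cen_rows <- list(); ev_rows <- list(); les_rows <- list(); lat_rows <- list()
  for (id in names(cohort$speakers)) {
    spk <- cohort$speakers[[id]]
    grp <- spk$spec$group
    ac <- tryCatch(
      analyze_speaker_acoustics(spk$summaries, spk$annotations,
                                n_subset = config$n_subset),
      error = function(e) stop(sprintf("acoustics stage failed for %s: %s",
                                       id, conditionMessage(e))))
    cc <- ac$centering
    cc$group <- grp
    cc$var_init_all <- ac$var_init_all
    cc$n_pairs <- ac$n_pairs
    cen_rows[[id]] <- cc
    per_hemi <- list()
    for (h in c("left", "right")) {
      seed_h <- (config$seed * 10000L + match(id, names(cohort$speakers)) * 2L +
                 (h == "right")) %% .Machine$integer.max
      per_hemi[[h]] <- tryCatch(
        analyze_speaker_evoked(ac$speak, espec, hemisphere = h,
                               rng_seed = seed_h,
                               search_window = config$search_window,
                               n_trials = ev$n_trials),
        error = function(e) stop(sprintf("evoked stage failed for %s/%s: %s",
                                         id, h, conditionMessage(e))))
      per_hemi[[h]]$group <- grp
    }
    ev_rows[[id]] <- rbind(per_hemi$left, per_hemi$right)
    li_lat <- laterality_index(per_hemi$left$listen_latency,
                               per_hemi$right$listen_latency, "latency")
    li_amp <- laterality_index(per_hemi$left$listen_amplitude,
                               per_hemi$right$listen_amplitude, "amplitude")
    li_sis <- laterality_index(per_hemi$left$sis, per_hemi$right$sis, "sis")
    lat_rows[[id]] <- data.frame(
      speaker_id = id, group = grp,
      latency_li = li_lat$index, amplitude_li = li_amp$index,
      sis_li = li_sis$index, sis_li_excluded = li_sis$excluded,
      stringsAsFactors = FALSE)
    if (grp == "aphasia") {
      vols <- simulate_lesion(spk$lesion_spec)
      prof <- lesion_profile(vols$lesion, vols$rois)
      les_rows[[id]] <- data.frame(
        speaker_id = id, total_volume = prof$total_volume,
        ifo_spared_pct = prof$percent_spared[["IFO"]],
        stg_spared_pct = prof$percent_spared[["STG"]],
        stringsAsFactors = FALSE)
    }
  }
  cen <- do.call(rbind, c(cen_rows, make.row.names = FALSE))
  evk <- do.call(rbind, c(ev_rows, make.row.names = FALSE))
  lat <- do.call(rbind, c(lat_rows, make.row.names = FALSE))
  les <- do.call(rbind, c(les_rows, make.row.names = FALSE))

  # study-level statistics
  cen_long <- data.frame(subject = cen$speaker_id, group = cen$group,
                         direction = cen$direction, value = cen$centering)
  an_dir <- mixed_anova_type3(cen_long, dv = "value", subject = "subject",
                              within = "direction", between = "group")
  sis_long <- data.frame(subject = evk$speaker_id, group = evk$group,
                         hemisphere = evk$hemisphere, value = evk$sis)
  an_sis <- mixed_anova_type3(sis_long, dv = "value", subject = "subject",
                              within = "hemisphere", between = "group")
  left <- evk[evk$hemisphere == "left" & evk$sis > 0, ]
  fall_long <- rbind(
    data.frame(subject = left$speaker_id, group = left$group,
               trial_type = "center", value = left$sis_center),
    data.frame(subject = left$speaker_id, group = left$group,
               trial_type = "peripheral", value = left$sis_peripheral))
  an_fall <- mixed_anova_type3(fall_long, dv = "value", subject = "subject",
                               within = "trial_type", between = "group")

  fwd <- cen[cen$direction == "forward", ]
  t_cen <- t_tests(fwd$centering[fwd$group == "control"],
                   fwd$centering[fwd$group == "aphasia"])
  cor_var_cen <- correlate(fwd$var_init, fwd$centering, "pearson")
  correlations <- list(var_init_vs_centering = cor_var_cen)
  if (!is.null(les) && nrow(les) >= 4) {
    aph_left <- evk[evk$hemisphere == "left" & evk$group == "aphasia", ]
    m <- match(les$speaker_id, aph_left$speaker_id)
    correlations$ifo_vs_left_sis <-
      correlate(les$ifo_spared_pct, aph_left$sis[m], "spearman")
    fa <- fwd[match(les$speaker_id, fwd$speaker_id), ]
    correlations$ifo_vs_centering <-
      correlate(les$ifo_spared_pct, fa$centering, "spearman")
  }

  summary_list <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_speakers = length(cohort$speakers),
    mean_centering_forward = mean(fwd$centering),
    mean_centering_reversed = mean(cen$centering[cen$direction == "reversed"]),
    mean_pct_reduction = mean(fwd$pct_reduction),
    mean_var_init_peripheral = mean(fwd$var_init),
    mean_var_mid_peripheral = mean(fwd$var_mid),
    mean_sis_left = mean(evk$sis[evk$hemisphere == "left"]),
    mean_sis_right = mean(evk$sis[evk$hemisphere == "right"]),
    mean_falloff_left = mean(evk$falloff[evk$hemisphere == "left"]),
    time_direction_F = an_dir$F[an_dir$term == "direction"],
    time_direction_p = an_dir$p[an_dir$term == "direction"],
    falloff_trialtype_F = an_fall$F[an_fall$term == "trial_type"],
    falloff_trialtype_p = an_fall$p[an_fall$term == "trial_type"],
    group_centering_t = t_cen$statistic, group_centering_p = t_cen$p)

  res <- structure(list(centering = cen, evoked = evk, lesion = les,
                        laterality = lat,
                        anova = list(time_direction = an_dir, sis = an_sis,
                                     falloff_left = an_fall),
                        tests = list(group_centering = t_cen),
                        correlations = correlations,
                        summary = summary_list, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    utils::write.csv(cen, file.path(od, "centering.csv"), row.names = FALSE)
    utils::write.csv(evk, file.path(od, "evoked.csv"), row.names = FALSE)
    utils::write.csv(lat, file.path(od, "laterality.csv"), row.names = FALSE)
    if (!is.null(les))
      utils::write.csv(les, file.path(od, "lesion.csv"), row.names = FALSE)
    for (nm in names(res$anova))
      utils::write.csv(res$anova[[nm]], file.path(od, paste0("anova_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(summary_list, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("censis pipeline run %s", format(Sys.time())),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("n_per_group: %d", config$n_per_group),
                 sprintf("n_trials_per_word: %d", config$n_trials_per_word)),
               file.path(od, "run.log"))
  }
  res
}
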