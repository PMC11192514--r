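#' Build an epoch set container
#'
#' Source-space evoked epochs for one condition and hemisphere: a numeric
#' array of `trials x vertices x samples` plus timing metadata. Epochs run
#' from `epoch_bounds[1]` to `epoch_bounds[2]` ms relative to sound onset;
#' the pre-stimulus baseline interval is used for z-scoring ROI waveforms.
#'
#' @param data 3-D numeric array, trials x vertices x samples.
#' @param sfreq Sampling frequency in Hz (> 0).
#' @param condition `"speak"` or `"listen"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param epoch_bounds Length-2 numeric, ms (default `c(-700, 400)`).
#' @param baseline_bounds Length-2 numeric, ms, within the epoch
#'   (default `c(-700, -400)`).
#' @param trial_ids Character vector of trial ids (defaults to row index).
#' @return An object of class `epoch_set`; `$times` holds sample times in ms.
#' @export
epoch_set <- function(data, sfreq, condition, hemisphere = "left",
                      epoch_bounds = c(-700, 400),
                      baseline_bounds = c(-700, -400),
                      trial_ids = NULL) {
  condition <- match.arg(condition, c("speak", "listen"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a trials x vertices x samples array")
  if (!is.finite(sfreq) || sfreq <= 0) stop("`sfreq` must be > 0")
  if (baseline_bounds[1] < epoch_bounds[1] || baseline_bounds[2] > epoch_bounds[2])
    stop("baseline interval must lie within the epoch")
  n_samp <- dim(data)[3]
  times <- epoch_bounds[1] + (seq_len(n_samp) - 1) * 1000 / sfreq
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(dim(data)[1]))
  stopifnot(length(trial_ids) == dim(data)[1])
  structure(list(data = data, sfreq = sfreq, condition = condition,
                 hemisphere = hemisphere, epoch_bounds = epoch_bounds,
                 baseline_bounds = baseline_bounds, times = times,
                 trial_ids = as.character(trial_ids)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s/%s: %d trials x %d vertices x %d samples @ %g Hz, [%g, %g] ms\n",
              x$condition, x$hemisphere, d[1], d[2], d[3], x$sfreq,
              x$epoch_bounds[1], x$epoch_bounds[2]))
  invisible(x)
}

# neighbor list from a 2-column undirected edge matrix over vertices 1..n
edge_neighbors <- function(edges, n_vertices) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("`edges` must be a 2-column matrix")
  if (any(edges < 1) || any(edges > n_vertices)) stop("edge endpoint out of range")
  nb <- vector("list", n_vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Grow a functional ROI around the peak-amplitude vertex
#'
#' Selects the highest-amplitude vertex (optionally within a mask, e.g. the
#' lateral surface) as a seed, then grows a connected region of
#' `size` vertices restricted to vertices whose amplitude is at least
#' `start_threshold` of the map maximum. Growth is greedy: at each step the
#' highest-amplitude above-threshold vertex adjacent to the current region
#' is added (ties broken by lowest vertex id). If `size` connected vertices
#' cannot be captured at the starting threshold, the threshold is lowered by
#' one percentage point and growth restarted, down to `floor_threshold`.
#'
#' @param amplitude_map Numeric vector: per-vertex amplitude at the peak
#'   latency.
#' @param edges 2-column integer matrix of undirected vertex adjacencies.
#' @param size ROI size in vertices (default 10).
#' @param start_threshold Starting amplitude threshold as a fraction of the
#'   map maximum (default 0.33).
#' @param floor_threshold Lowest threshold tried (default 0.01).
#' @param seed_mask Optional logical/integer vector restricting the seed
#'   choice (not the growth) to a subset of vertices.
#' @return List of class `functional_roi`: `seed`, `vertices` (sorted ids,
#'   length `size`), `threshold_used`.
#' @export
grow_functional_roi <- function(amplitude_map, edges, size = 10,
                                start_threshold = 0.33, floor_threshold = 0.01,
                                seed_mask = NULL) {
  n <- length(amplitude_map)
  if (n < size) stop(sprintf("need >= %d vertices", size))
  if (any(!is.finite(amplitude_map))) stop("amplitude map must be finite")
  nb <- edge_neighbors(edges, n)
  cand <- seq_len(n)
  if (!is.null(seed_mask)) cand <- cand[seed_mask[cand] > 0 | seed_mask[cand] == TRUE]
  seed <- cand[which.max(amplitude_map[cand])]   # which.max -> lowest id on ties
  maxamp <- max(amplitude_map)
  thr <- start_threshold
  repeat {
    ok <- amplitude_map >= thr * maxamp
    region <- seed
    repeat {
      if (length(region) == size) {
        return(structure(list(seed = seed, vertices = sort(region),
                              threshold_used = thr),
                         class = "functional_roi"))
      }
      frontier <- setdiff(unique(unlist(nb[region])), region)
      frontier <- frontier[ok[frontier]]
      if (length(frontier) == 0) break
      best <- frontier[order(-amplitude_map[frontier], frontier)][1]
      region <- c(region, best)
    }
    thr <- round(thr - 0.01, 10)
    if (thr < floor_threshold - 1e-12)
      stop(sprintf("cannot grow %d connected vertices even at %.0f%% threshold",
                   size, 100 * floor_threshold))
  }
}

#' Baseline z-scored RMS waveform of a functional ROI
#'
#' Order of operations: average over trials per vertex, take the root mean
#' square across the ROI vertices at each sample, then z-score the resulting
#' series against its own baseline interval (mean and SD of the baseline
#' samples).
#'
#' @param epochs An [epoch_set()].
#' @param roi A [grow_functional_roi()] result, or an integer vector of
#'   vertex ids.
#' @param zscore If `FALSE`, return the raw RMS series (useful for noiseless
#'   simulations whose baseline SD is 0).
#' @return List of class `roi_waveform`: `z` (or raw) series, `times` (ms),
#'   `condition`, `hemisphere`, `baseline_mean`, `baseline_sd`.
#' @export
roi_waveform <- function(epochs, roi, zscore = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  verts <- if (inherits(roi, "functional_roi")) roi$vertices else as.integer(roi)
  if (any(verts < 1) || any(verts > dim(epochs$data)[2]))
    stop("roi vertices not present in epochs")
  # trials x vertices x samples -> vertex-mean evoked -> RMS over vertices
  evoked <- apply(epochs$data[, verts, , drop = FALSE], c(2, 3), mean)
  rms <- sqrt(colMeans(evoked^2))
  bl <- epochs$times >= epochs$baseline_bounds[1] &
        epochs$times <= epochs$baseline_bounds[2]
  mu <- mean(rms[bl]); sdv <- stats::sd(rms[bl])
  if (zscore) {
    if (!is.finite(sdv) || sdv == 0)
      stop("degenerate baseline: SD of baseline RMS is 0")
    series <- (rms - mu) / sdv
  } else {
    series <- rms
  }
  structure(list(z = series, times = epochs$times, condition = epochs$condition,
                 hemisphere = epochs$hemisphere, baseline_mean = mu,
                 baseline_sd = sdv, zscored = zscore),
            class = "roi_waveform")
}

#' Find the M100 peak of an ROI waveform
#'
#' The M100 is the peak auditory cortical response roughly 100 ms after
#' sound onset. The peak is the maximum of the (z-scored) waveform within
#' the search window; ties go to the earliest sample. A flat window yields a
#' no-peak flag; a peak below `low_snr_z` is returned but flagged low-SNR.
#'
#' @param waveform A [roi_waveform()] (or list with `z` and `times`).
#' @param search_window Length-2 numeric, ms (default `c(70, 180)`).
#' @param low_snr_z Amplitude (z units) below which the peak is flagged
#'   low-SNR (default 3.5, calibrated so that noise-only waveforms are
#'   usually flagged).
#' @return List of class `m100_peak`: `latency` (ms), `amplitude`,
#'   `no_peak`, `low_snr`.
#' @export
find_m100_peak <- function(waveform, search_window = c(70, 180), low_snr_z = 3.5) {
  z <- waveform$z; times <- waveform$times
  idx <- which(times >= search_window[1] & times <= search_window[2])
  if (length(idx) == 0) stop("search window outside epoch")
  w <- z[idx]
  if (diff(range(w)) == 0) {
    return(structure(list(latency = NA_real_, amplitude = NA_real_,
                          no_peak = TRUE, low_snr = TRUE), class = "m100_peak"))
  }
  i <- idx[which.max(w)]   # earliest sample on exact ties
  structure(list(latency = times[i], amplitude = z[i], no_peak = FALSE,
                 low_snr = z[i] < low_snr_z),
            class = "m100_peak")
}

#' Speaking-induced suppression from listen and speak M100 peaks
#'
#' SIS is the listen-minus-speak difference in M100 peak amplitude (z
#' units): positive values indicate suppression of the response to
#' self-produced speech, negative values speaking-induced enhancement.
#' When center-half and peripheral-half peak pairs are supplied, the
#' fall-off of SIS from center to periphery (`sis_center - sis_peripheral`)
#' indexes cortical sensitivity to acoustic typicality.
#'
#' @param listen_peak,speak_peak Peak amplitudes (numbers or
#'   [find_m100_peak()] results) for all trials.
#' @param center,peripheral Optional lists `list(listen =, speak =)` of peak
#'   amplitudes for the median-split halves.
#' @return List of class `sis_result`: `listen_peak`, `speak_peak`, `sis`,
#'   `enhancement` (`sis < 0`), and when halves are given `sis_center`,
#'   `sis_peripheral`, `falloff`.
#' @export
compute_sis <- function(listen_peak, speak_peak, center = NULL, peripheral = NULL) {
  amp <- function(x) if (is.list(x)) x$amplitude else x
  lp <- amp(listen_peak); sp <- amp(speak_peak)
  if (is.null(lp) || is.null(sp) || !is.finite(lp) || !is.finite(sp))
    stop("both listen and speak peaks are required")
  res <- list(listen_peak = lp, speak_peak = sp, sis = lp - sp,
              enhancement = (lp - sp) < 0)
  if (!is.null(center) && !is.null(peripheral)) {
    sc <- amp(center$listen) - amp(center$speak)
    spp <- amp(peripheral$listen) - amp(peripheral$speak)
    res$sis_center <- sc
    res$sis_peripheral <- spp
    res$falloff <- sc - spp
  }
  structure(res, class = "sis_result")
}

#' Hemispheric laterality index
#'
#' `(right - left) / (right + left)`, in `[-1, 1]`; negative values indicate
#' left-lateralization. For `kind = "sis"`, negative values (enhancement)
#' are clamped to 0 before the index is formed; if the denominator is then
#' 0 the participant is excluded (a distinguished result, not a number).
#' Latencies and amplitudes must be non-negative.
#'
#' @param left,right Finite numeric values for the two hemispheres.
#' @param kind `"latency"`, `"amplitude"`, or `"sis"`.
#' @return List of class `laterality_index`: `index` (NA when excluded),
#'   `excluded`, `kind`.
#' @export
laterality_index <- function(left, right, kind = c("latency", "amplitude", "sis")) {
  kind <- match.arg(kind)
  if (!is.finite(left) || !is.finite(right)) stop("inputs must be finite")
  if (kind == "sis") {
    left <- max(left, 0)
    right <- max(right, 0)
  } else if (left < 0 || right < 0) {
    stop(sprintf("negative %s is not meaningful", kind))
  }
  denom <- right + left
  if (denom == 0) {
    return(structure(list(index = NA_real_, excluded = TRUE, kind = kind),
                     class = "laterality_index"))
  }
  structure(list(index = (right - left) / denom, excluded = FALSE, kind = kind),
            class = "laterality_index")
}
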