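#' Construct a formant track for one trial
#'
#' A formant track holds the F1/F2 trajectory of one spoken (or played-back)
#' syllable, with voicing onset/offset and an error annotation. Times are in
#' seconds from voicing onset; formants in Hz.
#'
#' @param trial_id Trial label (unique within a speaker/condition).
#' @param speaker_id Speaker label.
#' @param vowel Vowel (or word) label.
#' @param condition `"speak"` or `"listen"`.
#' @param time Numeric vector, seconds from voicing onset, strictly increasing.
#' @param f1,f2 Numeric vectors of formant frequencies in Hz, same length as
#'   `time`; finite and > 0.
#' @param onset,offset Voicing onset/offset in seconds (`offset > onset`).
#' @param error_flag Error category, `"clean"` if none.
#' @return An object of class `formant_track`.
#' @export
formant_track <- function(trial_id, speaker_id, vowel, condition,
                          time, f1, f2, onset = 0, offset = max(time),
                          error_flag = "clean") {
  condition <- match.arg(condition, c("speak", "listen"))
  stopifnot(length(time) == length(f1), length(time) == length(f2))
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("`time` must be finite and strictly increasing")
  if (any(!is.finite(f1)) || any(!is.finite(f2)) || any(f1 <= 0) || any(f2 <= 0))
    stop("formant values must be finite and > 0")
  if (!is.finite(onset) || !is.finite(offset) || offset <= onset)
    stop("`offset` must exceed `onset`")
  structure(
    list(trial_id = as.character(trial_id), speaker_id = as.character(speaker_id),
         vowel = as.character(vowel), condition = condition,
         time = as.numeric(time), f1 = as.numeric(f1), f2 = as.numeric(f2),
         onset = as.numeric(onset), offset = as.numeric(offset),
         error_flag = as.character(error_flag)),
    class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  cat(sprintf("<formant_track> %s/%s %s [%s], %d samples, %.0f ms voiced\n",
              x$speaker_id, x$trial_id, x$vowel, x$condition,
              length(x$time), 1000 * (x$offset - x$onset)))
  invisible(x)
}

#' Summarize a formant track into windowed mel-space points
#'
#' Computes the mean (F1, F2) position, in mels, over two analysis windows:
#' an initial window from voicing onset to `init_ms` (default 50 ms),
#' reflecting the feedforward command, and a mid-utterance window spanning
#' the middle 50% of the voiced trajectory, by which time auditory feedback
#' can have influenced production. Windows are half-open `[start, end)` in
#' time from onset; a track whose voiced duration is shorter than the
#' initial window (or with fewer than 4 samples) is flagged unusable rather
#' than dropped.
#'
#' @param track A [formant_track()].
#' @param init_ms Length of the initial window in ms (default 50).
#' @return One-row data.frame: trial/speaker/vowel/condition identifiers,
#'   `init_f1_mel`, `init_f2_mel`, `mid_f1_mel`, `mid_f2_mel`, `usable`,
#'   `error_flag`.
#' @export
summarize_trial <- function(track, init_ms = 50) {
  stopifnot(inherits(track, "formant_track"))
  tt <- track$time - track$onset
  dur <- track$offset - track$onset
  # half-open [start, end) windows; 1-ns tolerance absorbs floating-point
  # representation error at exact boundaries (sample spacing is >= ms scale)
  tol <- 1e-9
  voiced <- tt >= -tol & tt < dur + tol
  usable <- dur >= init_ms / 1000 && sum(voiced) >= 4
  init_idx <- voiced & tt < init_ms / 1000 - tol
  mid_idx <- voiced & tt >= 0.25 * dur - tol & tt < 0.75 * dur - tol
  win_mean <- function(idx, f) {
    if (!any(idx)) return(NA_real_)
    mean(hz_to_mel(f[idx]))
  }
  if (!any(init_idx) || !any(mid_idx)) usable <- FALSE
  data.frame(
    trial_id = track$trial_id, speaker_id = track$speaker_id,
    vowel = track$vowel, condition = track$condition,
    init_f1_mel = win_mean(init_idx, track$f1),
    init_f2_mel = win_mean(init_idx, track$f2),
    mid_f1_mel = win_mean(mid_idx, track$f1),
    mid_f2_mel = win_mean(mid_idx, track$f2),
    usable = usable, error_flag = track$error_flag,
    stringsAsFactors = FALSE)
}

#' Per-speaker, per-vowel median formant positions
#'
#' The component-wise median F1/F2 position of each speaker's productions of
#' each vowel, computed separately in the initial and mid-utterance windows.
#' These medians define the center of each vowel's distribution; each
#' window's distances are always measured against that window's own median.
#'
#' @param summaries Data.frame from [summarize_trial()] rows (usable trials
#'   are used; unusable rows are ignored).
#' @return Data.frame with `speaker_id`, `vowel`, `window`
#'   (`"initial"`/`"mid"`), `f1_mel`, `f2_mel`.
#' @export
vowel_medians <- function(summaries) {
  s <- summaries[summaries$usable, , drop = FALSE]
  if (nrow(s) == 0) stop("no usable trials")
  key <- interaction(s$speaker_id, s$vowel, drop = TRUE)
  res <- lapply(split(s, key), function(d) {
    data.frame(
      speaker_id = rep(d$speaker_id[1], 2), vowel = rep(d$vowel[1], 2),
      window = c("initial", "mid"),
      f1_mel = c(stats::median(d$init_f1_mel), stats::median(d$mid_f1_mel)),
      f2_mel = c(stats::median(d$init_f2_mel), stats::median(d$mid_f2_mel)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Euclidean mel distances of each trial to its vowel medians
#'
#' Adds `init_dist` and `mid_dist` columns: the Euclidean distance, in mels,
#' from each trial's windowed (F1, F2) point to the speaker's per-vowel
#' median for that window. Greater mean distance indicates a broader
#' formant distribution (more variable production).
#'
#' @param summaries Data.frame of trial summaries.
#' @param medians Optional precomputed [vowel_medians()] table (defaults to
#'   medians of `summaries` itself; pass speak-trial medians explicitly when
#'   scoring listen trials against speak distributions).
#' @return `summaries` with `init_dist` and `mid_dist` columns (NA for
#'   unusable trials).
#' @export
trial_distances <- function(summaries, medians = vowel_medians(summaries)) {
  med_init <- medians[medians$window == "initial", ]
  med_mid <- medians[medians$window == "mid", ]
  key <- function(sp, v) paste(sp, v, sep = "\r")
  ki <- key(med_init$speaker_id, med_init$vowel)
  km <- key(med_mid$speaker_id, med_mid$vowel)
  ks <- key(summaries$speaker_id, summaries$vowel)
  ii <- match(ks, ki); im <- match(ks, km)
  if (any(is.na(ii) & summaries$usable))
    stop("missing median for some speaker/vowel")
  summaries$init_dist <- sqrt((summaries$init_f1_mel - med_init$f1_mel[ii])^2 +
                              (summaries$init_f2_mel - med_init$f2_mel[ii])^2)
  summaries$mid_dist <- sqrt((summaries$mid_f1_mel - med_mid$f1_mel[im])^2 +
                             (summaries$mid_f2_mel - med_mid$f2_mel[im])^2)
  summaries$init_dist[!summaries$usable] <- NA_real_
  summaries$mid_dist[!summaries$usable] <- NA_real_
  summaries
}

# Per-vowel subset quotas: n trials split evenly over vowels, any remainder
# going to vowels in lexicographic order.
vowel_quotas <- function(vowels, n) {
  vowels <- sort(unique(vowels))
  q <- rep(n %/% length(vowels), length(vowels))
  r <- n %% length(vowels)
  if (r > 0) q[seq_len(r)] <- q[seq_len(r)] + 1
  stats::setNames(q, vowels)
}

#' Partition trials into center and peripheral subsets
#'
#' Labels each speaker's usable trials by typicality. In `"n_subset"` mode
#' the `n` trials with the smallest distances (to the per-vowel median, in
#' the chosen window) are `center` and the `n` largest are `peripheral`,
#' sampling the vowels equally; remaining trials are `neither`. In
#' `"median_split"` mode every trial is labeled, the smaller-distance half
#' of each vowel as `center` and the rest as `peripheral` (for an odd count
#' the extra trial goes to `center`). Ties in distance are broken by trial
#' id order.
#'
#' @param summaries Data.frame with distance columns (see
#'   [trial_distances()]).
#' @param n Total subset size per speaker (e.g. 125) in `"n_subset"` mode.
#' @param mode `"n_subset"` or `"median_split"`.
#' @param window Which window's distance defines typicality: `"initial"`
#'   (default) or `"mid"` (used by the time-reversed control).
#' @return `summaries` with a `subset_label` column in
#'   `{center, peripheral, neither}`.
#' @export
partition_trials <- function(summaries, n = NULL,
                             mode = c("n_subset", "median_split"),
                             window = c("initial", "mid")) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  if (mode == "n_subset" && (is.null(n) || n < 2))
    stop("`n` (total subset size) required in n_subset mode")
  dcol <- if (window == "initial") "init_dist" else "mid_dist"
  if (is.null(summaries[[dcol]])) stop("distances missing; run trial_distances() first")
  summaries$subset_label <- "neither"
  for (sp in unique(summaries$speaker_id)) {
    sel <- which(summaries$speaker_id == sp & summaries$usable &
                 is.finite(summaries[[dcol]]))
    d <- summaries[sel, , drop = FALSE]
    if (mode == "n_subset") {
      quotas <- vowel_quotas(d$vowel, n)
      for (v in names(quotas)) {
        q <- quotas[[v]]
        iv <- sel[d$vowel == v]
        if (length(iv) < 2 * q)
          stop(sprintf("speaker %s vowel %s: %d usable trials < 2 x quota %d",
                       sp, v, length(iv), q))
        ord <- iv[order(summaries[[dcol]][iv], summaries$trial_id[iv])]
        summaries$subset_label[utils::head(ord, q)] <- "center"
        summaries$subset_label[utils::tail(ord, q)] <- "peripheral"
      }
    } else {
      for (v in unique(d$vowel)) {
        iv <- sel[d$vowel == v]
        ord <- iv[order(summaries[[dcol]][iv], summaries$trial_id[iv])]
        n_center <- ceiling(length(iv) / 2)
        summaries$subset_label[utils::head(ord, n_center)] <- "center"
        summaries$subset_label[utils::tail(ord, length(iv) - n_center)] <- "peripheral"
      }
    }
  }
  summaries
}

#' Mean mel distance (variability) of a trial set in one window
#'
#' Variability is the average Euclidean distance, in mels, to the per-vowel
#' median in the given time window, pooled across vowels within speaker.
#'
#' @param summaries Trial summaries with distance columns.
#' @param window `"initial"` or `"mid"`.
#' @return Named numeric: one mean distance per speaker.
#' @export
variability <- function(summaries, window = c("initial", "mid")) {
  window <- match.arg(window)
  dcol <- if (window == "initial") "init_dist" else "mid_dist"
  s <- summaries[summaries$usable & is.finite(summaries[[dcol]]), , drop = FALSE]
  if (nrow(s) == 0) stop("no usable trials")
  tapply(s[[dcol]], s$speaker_id, mean)
}

#' Vowel centering of peripheral trials (with time-reversed control)
#'
#' Forward centering selects each speaker's peripheral trials by their
#' initial-window distance and subtracts their mid-utterance variability
#' from their initial variability: positive values mean formants moved
#' toward the vowel median over the syllable. The `"reversed"` control
#' re-selects peripheral trials by their *mid*-window distance and measures
#' their apparent movement backwards in time (mid minus initial
#' variability); if forward centering merely reflected regression to the
#' mean, the two directions would be statistically equivalent.
#'
#' @param summaries Trial summaries with distance columns (speak trials of
#'   one or more speakers).
#' @param direction `"forward"` or `"reversed"`.
#' @param n Subset size for `"n_subset"` mode, or `NULL` with
#'   `mode = "median_split"`.
#' @param mode Partition mode passed to [partition_trials()].
#' @return Data.frame, one row per speaker: `speaker_id`, `direction`,
#'   `subset`, `n_trials`, `var_init`, `var_mid`, `centering`,
#'   `pct_reduction` (see [percent_reduction()]).
#' @export
centering <- function(summaries, direction = c("forward", "reversed"),
                      n = NULL, mode = c("n_subset", "median_split")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  window <- if (direction == "forward") "initial" else "mid"
  lab <- partition_trials(summaries, n = n, mode = mode, window = window)
  per <- lab[lab$subset_label == "peripheral", , drop = FALSE]
  if (nrow(per) == 0) stop("empty peripheral subset")
  res <- lapply(split(per, per$speaker_id), function(d) {
    vi <- mean(d$init_dist)
    vm <- mean(d$mid_dist)
    cen <- if (direction == "forward") vi - vm else vm - vi
    data.frame(speaker_id = d$speaker_id[1], direction = direction,
               subset = "peripheral", n_trials = nrow(d),
               var_init = vi, var_mid = vm, centering = cen,
               pct_reduction = if (vi > 0) 100 * cen / vi else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percent reduction of initial dispersion by centering
#'
#' `100 * centering / var_init`: the share of the initial distance to the
#' vowel median that is removed by mid-utterance.
#'
#' @param result A row (or data.frame of rows) from [centering()], or a list
#'   with `centering` and `var_init`.
#' @return Numeric percent(s).
#' @export
percent_reduction <- function(result) {
  if (any(!is.finite(result$var_init)) || any(result$var_init <= 0))
    stop("percent reduction undefined when var_init <= 0")
  100 * result$centering / result$var_init
}

#' Reject errorful trials and enforce speak/listen pairing
#'
#' Applies the trial-rejection rule: a speak trial marked with any speech
#' error (omission, misselection, severe distortion, production of another
#' word) or a listen trial marked with an artifact removes *both* members of
#' that speak/listen pair, so the two conditions remain fully matched in
#' acoustics.
#'
#' @param annotations Data.frame with columns `pair_id`, `condition`
#'   (`"speak"`/`"listen"`), and `error_flag` (`"clean"` or a category).
#' @return List with `pairs` (kept pair ids), `speak` and `listen` (kept
#'   annotation rows), and `error_counts` (named counts per category,
#'   including `total` rejected pairs).
#' @export
reject_error_trials <- function(annotations) {
  need <- c("pair_id", "condition", "error_flag")
  if (!all(need %in% names(annotations)))
    stop("annotations must have pair_id, condition, error_flag")
  sp <- annotations[annotations$condition == "speak", ]
  li <- annotations[annotations$condition == "listen", ]
  if (!setequal(sp$pair_id, li$pair_id) ||
      anyDuplicated(sp$pair_id) || anyDuplicated(li$pair_id))
    stop("speak and listen trials must pair one-to-one by pair_id")
  bad_speak <- sp$pair_id[sp$error_flag != "clean"]
  bad_listen <- li$pair_id[li$error_flag != "clean"]
  bad <- union(bad_speak, bad_listen)
  keep <- setdiff(sp$pair_id, bad)
  cat_counts <- c(table(sp$error_flag[sp$error_flag != "clean"]),
                  table(li$error_flag[li$error_flag != "clean"]))
  counts <- if (length(cat_counts)) tapply(as.integer(cat_counts),
                                           names(cat_counts), sum) else integer(0)
  list(pairs = keep,
       speak = sp[sp$pair_id %in% keep, , drop = FALSE],
       listen = li[li$pair_id %in% keep, , drop = FALSE],
       error_counts = c(as.list(counts), list(total = length(bad))))
}
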