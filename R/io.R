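#' Write / read trial summary tables as TSV
#'
#' Plain UTF-8 tab-separated tables with a header row; floats at full
#' precision. Round-trips with [read_trials()] by value.
#'
#' @param summaries Trial summary data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Write / read an epoch set as a raw array with a JSON sidecar
#'
#' The numeric array is stored as little-endian float64 in `<stem>.dat`;
#' `<stem>.json` records dimensions, sampling rate, epoch/baseline bounds,
#' condition, hemisphere, and trial ids. [read_epochs()] restores an
#' identical [epoch_set()].
#'
#' @param epochs An [epoch_set()].
#' @param stem Path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  meta <- list(dim = dim(epochs$data), sfreq = epochs$sfreq,
               condition = epochs$condition, hemisphere = epochs$hemisphere,
               epoch_bounds = epochs$epoch_bounds,
               baseline_bounds = epochs$baseline_bounds,
               trial_ids = epochs$trial_ids)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(meta$dim), size = 8,
                  endian = "little")
  epoch_set(array(vals, dim = meta$dim), meta$sfreq, meta$condition,
            meta$hemisphere, meta$epoch_bounds, meta$baseline_bounds,
            meta$trial_ids)
}

#' Subset an epoch set by trial id
#'
#' @param epochs An [epoch_set()].
#' @param trial_ids Ids to keep (order preserved as given).
#' @return A smaller [epoch_set()].
#' @export
subset_epochs <- function(epochs, trial_ids) {
  idx <- match(trial_ids, epochs$trial_ids)
  if (anyNA(idx)) stop("unknown trial id(s) in subset")
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$sfreq, epochs$condition,
            epochs$hemisphere, epochs$epoch_bounds, epochs$baseline_bounds,
            epochs$trial_ids[idx])
}

#' Write / read a vertex adjacency edge list
#'
#' @param edges 2-column integer matrix.
#' @param path Text file path (two whitespace-separated columns).
#' @return `path` invisibly / the edge matrix.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("from", "to"))
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE))
}

#' Load a participant characteristics table
#'
#' Reads a tab-separated participant table (one row per participant:
#' demographics, lesion profile, aphasia subtype and severity, repetition
#' scores, speech-error counts). `"n/a"` entries become `NA`; numeric and
#' integer columns are typed; duplicate ids or malformed numerics are
#' errors naming the offending row. The bundled synthetic-free fixture
#' (`system.file("extdata", "participants.tsv", package = "censis")`)
#' transcribes the aphasia group's published characteristics table.
#'
#' @param path TSV file path.
#' @return Typed data.frame with one row per participant.
#' @export
load_participants <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                         stringsAsFactors = FALSE, colClasses = "character",
                         quote = "", comment.char = "")
  if (anyDuplicated(d$id))
    stop(sprintf("duplicate participant id: %s", d$id[duplicated(d$id)][1]))
  num_cols <- c("age", "months_post_stroke", "lesion_volume_mm3",
                "ifo_spared_pct", "stg_spared_pct", "heschl_spared_pct",
                "wab_aq", "palpa7_pct", "palpa8_pct", "pal7_pct")
  int_cols <- c("err_omissions", "err_misselections", "err_distortions",
                "err_other_words", "err_total")
  for (cc in intersect(c(num_cols, int_cols), names(d))) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(!is.na(d[[cc]]) & is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric in column '%s', row %d: '%s'",
                   cc, bad[1], d[[cc]][bad[1]]))
    d[[cc]] <- if (cc %in% int_cols) as.integer(v) else v
  }
  d
}
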