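#' Weak seizure annotations
#'
#' Seizure annotations are weak: they mark time only, never the EEG channels
#' expressing the discharge. An `annotation_track` carries both views of the
#' same information — a per-second binary mask and a list of seizure events —
#' and keeps them consistent. Intervals are half-open `[onset, offset)` in
#' seconds from record start; second `t` of the mask is 1 iff `[t, t+1)`
#' overlaps any event.
#'
#' @param events data.frame with numeric columns `onset_s`, `offset_s`
#'   (half-open, seconds); may be `NULL` if `mask` is given.
#' @param duration_s record duration in seconds (non-negative).
#' @param mask optional integer 0/1 vector of length `ceiling(duration_s)`;
#'   used instead of `events` when `events` is `NULL`.
#' @param patient_id identifier string.
#' @return An object of class `annotation_track` with fields `mask`,
#'   `events`, `duration_s`, `patient_id`. Events are merged and sorted.
#' @export
annotation_track <- function(events = NULL, duration_s, mask = NULL,
                             patient_id = "anon") {
  if (duration_s < 0) stop("negative duration")
  if (is.null(events)) {
    if (is.null(mask)) mask <- integer(ceiling(duration_s))
    events <- mask_to_events(mask)
  } else {
    events <- merge_events(events)
    if (nrow(events) && (min(events$onset_s) < 0 ||
                         max(events$offset_s) > duration_s))
      stop("events must lie within [0, duration_s]")
    mask <- events_to_mask(events, duration_s)
  }
  structure(list(mask = as.integer(mask), events = events,
                 duration_s = duration_s,
                 patient_id = as.character(patient_id)),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %s: %d event(s), %d/%d seizure seconds\n",
              x$patient_id, nrow(x$events), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Merge overlapping or touching seizure events
#'
#' @param events data.frame with `onset_s` < `offset_s` per row.
#' @return Sorted data.frame of disjoint events.
#' @export
merge_events <- function(events) {
  events <- as.data.frame(events)
  if (!nrow(events))
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  if (any(events$onset_s >= events$offset_s))
    stop("each event needs onset_s < offset_s")
  o <- order(events$onset_s, events$offset_s)
  on <- events$onset_s[o]; off <- events$offset_s[o]
  res_on <- on[1L]; res_off <- off[1L]
  for (i in seq_along(on)[-1L]) {
    if (on[i] <= res_off[length(res_off)]) {
      res_off[length(res_off)] <- max(res_off[length(res_off)], off[i])
    } else {
      res_on <- c(res_on, on[i]); res_off <- c(res_off, off[i])
    }
  }
  data.frame(onset_s = res_on, offset_s = res_off)
}

#' Convert between event intervals and a per-second mask
#'
#' `events_to_mask()` sets second `t` (0-based) iff `[t, t+1)` overlaps an
#' event; `mask_to_events()` returns the maximal runs of ones. For disjoint
#' integer-second events the two are exact inverses.
#'
#' @param events data.frame with `onset_s`, `offset_s`, non-overlapping.
#' @param duration_s record duration in seconds.
#' @return `events_to_mask()`: integer vector of length
#'   `ceiling(duration_s)`; `mask_to_events()`: event data.frame.
#' @export
events_to_mask <- function(events, duration_s) {
  if (duration_s < 0) stop("negative duration")
  n <- ceiling(duration_s)
  mask <- integer(n)
  events <- as.data.frame(events)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    if (on < 0 || off > duration_s || on >= off)
      stop("event outside [0, duration_s] or empty")
    # seconds t with t < off and t+1 > on
    lo <- max(0L, ceiling(on - 1 + 1e-9))
    hi <- min(n - 1L, ceiling(off - 1e-9) - 1L)
    if (hi >= lo) mask[(lo:hi) + 1L] <- 1L
  }
  mask
}

#' @rdname events_to_mask
#' @param mask integer 0/1 vector, one entry per second.
#' @export
mask_to_events <- function(mask) {
  mask <- as.integer(mask != 0)
  if (!length(mask) || !any(mask == 1L))
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  d <- diff(c(0L, mask, 0L))
  data.frame(onset_s = as.numeric(which(d == 1L) - 1L),
             offset_s = as.numeric(which(d == -1L) - 1L))
}

#' Read and write annotation files
#'
#' Events travel as CSV with header `patient_id,onset_s,offset_s`; masks as
#' a plain text file with a two-line header (`patient_id`, `duration_s`)
#' followed by one 0/1 integer per line.
#'
#' @param ann an [annotation_track()].
#' @param path file path.
#' @return Readers return an [annotation_track()] (for event CSVs holding
#'   several patients, a named list of tracks keyed by patient, with
#'   `duration_s` taken from `duration_s` argument); writers return `path`.
#' @param duration_s record duration(s) in seconds for [read_annotations()],
#'   a single value or named vector keyed by patient id.
#' @export
write_annotations <- function(ann, path) {
  df <- ann$events
  df <- cbind(patient_id = rep(ann$patient_id, nrow(df)), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, duration_s) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "onset_s", "offset_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  ids <- unique(df$patient_id)
  if (length(ids) == 0L)
    stop("annotation CSV contains no events; build an empty track directly")
  get_dur <- function(id) {
    if (length(duration_s) == 1L && is.null(names(duration_s)))
      return(duration_s)
    if (!id %in% names(duration_s)) stop("no duration for patient ", id)
    duration_s[[id]]
  }
  out <- lapply(ids, function(id) {
    sub <- df[df$patient_id == id, c("onset_s", "offset_s")]
    annotation_track(events = sub, duration_s = get_dur(id),
                     patient_id = id)
  })
  names(out) <- ids
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname write_annotations
#' @export
write_mask <- function(ann, path) {
  writeLines(c(ann$patient_id, format(ann$duration_s),
               as.character(ann$mask)), path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  annotation_track(mask = as.integer(lines[-(1:2)]),
                   duration_s = as.numeric(lines[2L]),
                   patient_id = lines[1L])
}
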