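#' Postprocessing configuration
#'
#' Three stages turn raw per-second probabilities into events, in this
#' order: a central non-causal moving-average filter of 60 s smooths the
#' sequence; a per-patient adaptive background adjustment contrasts the
#' current probability with the mean of the previous 10 minutes; detected
#' events are extended on both sides by a 30 s collar to compensate for
#' the smoothing delay.
#'
#' @param maf_s moving-average duration in seconds (discretized to a
#'   centered odd tap count, 61 taps for the default 60).
#' @param background_s trailing background window in seconds (default 600).
#' @param collar_s symmetric collar in seconds (default 30).
#' @param threshold detection threshold in `(0, 1)`.
#' @return A validated `postprocess_config`.
#' @export
postprocess_config <- function(maf_s = 60, background_s = 600,
                               collar_s = 30, threshold = 0.5) {
  if (background_s <= maf_s) stop("background_s must exceed maf_s")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(maf_s = maf_s, background_s = background_s,
                 collar_s = collar_s, threshold = threshold),
            class = "postprocess_config")
}

#' Per-second probability sequence
#'
#' @param p probabilities in `[0, 1]`, one per second.
#' @param t0_s time of the first entry in seconds from record start.
#' @param patient_id identifier.
#' @return A `probability_sequence`.
#' @export
probability_sequence <- function(p, t0_s = 0, patient_id = "anon") {
  p <- as.numeric(p)
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("probabilities outside [0,1]")
  structure(list(p = pmin(pmax(p, 0), 1), t0_s = t0_s,
                 patient_id = as.character(patient_id)),
            class = "probability_sequence")
}

#' Assign window probabilities to seconds
#'
#' The probability of the window `[t, t+16)` is assigned to its center
#' second `t + 8`; the sequence covers the centers of all windows, so a
#' 60 s record (45 window positions) yields 45 entries starting at
#' `t0 = 8` s.
#'
#' @param per_window_probs per-window probabilities (after channel fusion).
#' @param window_start_s window start times on the 1 s grid.
#' @param window_s window length in seconds (default 16).
#' @param patient_id identifier.
#' @return A [probability_sequence()].
#' @export
windows_to_sequence <- function(per_window_probs, window_start_s,
                                window_s = 16, patient_id = "anon") {
  if (length(per_window_probs) != length(window_start_s))
    stop("one start time per window probability is required")
  if (length(window_start_s) > 1L &&
      any(diff(window_start_s) != 1))
    stop("gaps in the window grid")
  probability_sequence(per_window_probs,
                       t0_s = window_start_s[1L] + window_s / 2,
                       patient_id = patient_id)
}

#' Central moving-average filter
#'
#' Centered mean over `maf_s + 1` taps (61 for the nominal 60 s duration);
#' at the edges the window is truncated and renormalized over the
#' available seconds, avoiding boundary bias. Output length equals input
#' length; a constant sequence is unchanged.
#'
#' @param seq a [probability_sequence()].
#' @param maf_s nominal filter duration in seconds.
#' @return A smoothed [probability_sequence()].
#' @export
moving_average <- function(seq, maf_s = 60) {
  p <- seq$p
  n <- length(p)
  if (!n) stop("empty sequence")
  half <- floor(maf_s / 2)
  cs <- cumsum(c(0, p))
  i <- seq_len(n)
  lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  probability_sequence(out, seq$t0_s, seq$patient_id)
}

#' Adaptive background adjustment
#'
#' Contrasts each probability with the mean over the preceding
#' `background_s` seconds (exclusive of the current one; for early samples
#' the available history is used, and the first sample contrasts with
#' itself, mapping to 0). The result is clipped to `[0, 1]`. Subtraction
#' keeps low simmering background probability from accumulating into false
#' detections.
#'
#' @param seq a [probability_sequence()].
#' @param background_s trailing window in seconds.
#' @return An adjusted [probability_sequence()].
#' @export
adapt_background <- function(seq, background_s = 600) {
  p <- seq$p
  n <- length(p)
  if (!n) stop("empty sequence")
  cs <- cumsum(c(0, p))
  i <- seq_len(n)
  lo <- pmax(1L, i - background_s)
  bg <- ifelse(i == 1L, p[1L], (cs[i] - cs[lo]) / (i - lo))
  probability_sequence(pmin(pmax(p - bg, 0), 1), seq$t0_s, seq$patient_id)
}

#' Threshold a sequence and collar the detections
#'
#' Maximal runs with `p >= threshold` become events; each is extended by
#' `collar_s` seconds on both sides, clipped to the record bounds, and
#' overlapping or touching extended events are merged.
#'
#' @param seq a [probability_sequence()].
#' @param threshold detection threshold in `(0, 1)`.
#' @param collar_s symmetric collar in seconds.
#' @param duration_s record duration used for clipping (defaults to the
#'   sequence extent plus the symmetric window margins).
#' @return Event data.frame with `onset_s`, `offset_s` (may be empty).
#' @export
threshold_and_collar <- function(seq, threshold, collar_s = 30,
                                 duration_s = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (is.null(duration_s))
    duration_s <- seq$t0_s + length(seq$p) + seq$t0_s - 1
  hits <- as.integer(seq$p >= threshold)
  ev <- mask_to_events(hits)
  if (!nrow(ev))
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  ev$onset_s <- pmax(0, ev$onset_s + seq$t0_s - collar_s)
  ev$offset_s <- pmin(duration_s, ev$offset_s + seq$t0_s + collar_s)
  merge_events(ev)
}

#' Full postprocessing pipeline
#'
#' Moving average, then background adaptation, then threshold + collar —
#' the fixed stage order of the detection system. Returns both the
#' adjusted sequence (on which epoch metrics are computed) and the
#' detected events.
#'
#' @param seq a raw [probability_sequence()].
#' @param cfg a [postprocess_config()].
#' @param duration_s record duration for collar clipping.
#' @return List `(sequence, events)`.
#' @export
postprocess_sequence <- function(seq, cfg = postprocess_config(),
                                 duration_s = NULL) {
  sm <- moving_average(seq, cfg$maf_s)
  ad <- adapt_background(sm, cfg$background_s)
  ev <- threshold_and_collar(ad, cfg$threshold, cfg$collar_s, duration_s)
  list(sequence = ad, events = ev)
}

#' Read or write a probability sequence as CSV
#'
#' Columns `t_s,probability`, one row per second.
#'
#' @param seq a [probability_sequence()].
#' @param path file path.
#' @return The reader returns a [probability_sequence()]; the writer
#'   `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  df <- data.frame(t_s = seq$t0_s + seq_along(seq$p) - 1L,
                   probability = seq$p)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequence
#' @param patient_id identifier for the read sequence.
#' @export
read_sequence <- function(path, patient_id = "anon") {
  df <- read.csv(path)
  probability_sequence(df$probability, t0_s = df$t_s[1L],
                       patient_id = patient_id)
}
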