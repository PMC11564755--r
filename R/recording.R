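#' EEG recording container
#'
#' A `recording` holds a multichannel EEG signal in microvolts together with
#' its sampling rate and channel labels. All channels share one sampling rate
#' and length; times are seconds from record start.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel (row).
#' @param patient_id identifier string carried through the pipeline.
#'
#' @return An object of class `recording` with fields `signal`, `fs`,
#'   `channel_labels`, `patient_id` and `duration_s` (= samples / fs).
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(512), 2, 256), fs = 256,
#'                  channel_labels = c("F4", "C4"))
#' rec$duration_s
recording <- function(signal, fs, channel_labels = NULL, patient_id = "anon") {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("one channel label per signal row is required")
  storage.mode(signal) <- "double"
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs,
         channel_labels = as.character(channel_labels),
         patient_id = as.character(patient_id),
         duration_s = ncol(signal) / fs),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, nrow(x$signal), ncol(x$signal), x$fs,
              x$duration_s))
  invisible(x)
}

#' The standard eight-pair neonatal bipolar montage
#'
#' Anode/cathode electrode pairs F4-C4, C4-O2, F3-C3, C3-O1, T4-C4, C4-Cz,
#' Cz-C3, C3-T3, the montage routinely used for neonatal seizure review.
#'
#' @return A two-column character matrix (anode, cathode), eight rows.
#' @export
neonatal_bipolar_pairs <- function() {
  m <- rbind(c("F4", "C4"), c("C4", "O2"), c("F3", "C3"), c("C3", "O1"),
             c("T4", "C4"), c("C4", "Cz"), c("Cz", "C3"), c("C3", "T3"))
  colnames(m) <- c("anode", "cathode")
  m
}

#' Derive a bipolar montage from referential channels
#'
#' Forms each output channel as the samplewise difference anode - cathode.
#' Output labels are `"anode-cathode"` strings. The derivation is linear in
#' the input signal.
#'
#' @param rec a [recording()] whose `channel_labels` contain every electrode
#'   referenced by `pairs`.
#' @param pairs two-column character matrix (anode, cathode); defaults to the
#'   eight neonatal pairs of [neonatal_bipolar_pairs()].
#' @return A [recording()] with `nrow(pairs)` channels.
#' @export
derive_bipolar_montage <- function(rec, pairs = neonatal_bipolar_pairs()) {
  stopifnot(inherits(rec, "recording"))
  pairs <- as.matrix(pairs)
  missing <- setdiff(unique(c(pairs)), rec$channel_labels)
  if (length(missing))
    stop("electrode label(s) not present in recording: ",
         paste(missing, collapse = ", "))
  idx_a <- match(pairs[, 1L], rec$channel_labels)
  idx_c <- match(pairs[, 2L], rec$channel_labels)
  out <- rec$signal[idx_a, , drop = FALSE] - rec$signal[idx_c, , drop = FALSE]
  recording(out, rec$fs,
            channel_labels = paste0(pairs[, 1L], "-", pairs[, 2L]),
            patient_id = rec$patient_id)
}
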