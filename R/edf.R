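# Minimal EDF (European Data Format) reader/writer: fixed 256-byte ASCII
# header, 256 bytes per signal, then 16-bit little-endian data records.
# One-second data records are used, so recordings must have an integer
# number of seconds and an integer sampling rate.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)                 # left-justified, space padded
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over a symmetric physical range; samples
#' outside the range are clipped. The quantization step is
#' `(2 * physical_max) / (32767 - (-32767))` microvolts.
#'
#' @param rec a [recording()] with integer `fs` and integer duration.
#' @param path output file path.
#' @param physical_max symmetric physical range bound in microvolts; the
#'   default 2000 covers typical neonatal head-box output.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_max = 2000) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- ncol(rec$signal) / fs
  if (n_rec != round(n_rec))
    stop("EDF writer requires an integer number of seconds")
  n_rec <- as.integer(n_rec)
  ns <- nrow(rec$signal)
  dmax <- 32767L; dmin <- -32767L
  phys_hi <- physical_max; phys_lo <- -physical_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(rec$patient_id, 80L),
    edf_pad("neoseiz", 80L),
    edf_pad("01.01.00", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad("1", 8L),
    edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16L)
  field(rep("", ns), 80L)                    # transducer
  field(rep("uV", ns), 8L)
  field(rep(format(phys_lo), ns), 8L)
  field(rep(format(phys_hi), ns), 8L)
  field(rep(format(dmin), ns), 8L)
  field(rep(format(dmax), ns), 8L)
  field(rep("", ns), 80L)                    # prefiltering
  field(rep(format(as.integer(fs)), ns), 8L)
  field(rep("", ns), 32L)

  scale <- (phys_hi - phys_lo) / (dmax - dmin)
  dig <- round((pmin(pmax(rec$signal, phys_lo), phys_hi) - phys_lo) / scale) +
    dmin
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the plain 16-bit EDF layout written by [write_edf()] (and any
#' EDF whose signals share one sampling rate). Digital values are mapped
#' back to physical units using the per-signal calibration fields.
#'
#' @param path EDF file path.
#' @return A [recording()] in microvolts.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  hd(8L)                                      # version
  patient_id <- hd(80L)
  hd(80L); hd(8L); hd(8L); hd(8L); hd(44L)
  n_rec <- as.integer(hd(8L))
  rec_dur <- as.numeric(hd(8L))
  ns <- as.integer(hd(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  fields <- function(width) vapply(seq_len(ns), function(i) hd(width), "")
  labels <- fields(16L)
  fields(80L); fields(8L)
  pmin <- as.numeric(fields(8L)); pmax <- as.numeric(fields(8L))
  dmin <- as.numeric(fields(8L)); dmax <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L))               # samples per record
  fields(32L)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  if (is.na(fs) || fs <= 0) stop("missing or invalid sampling rate")

  raw <- readBin(con, "integer", n = n_rec * ns * spr[1L], size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != n_rec * ns * spr[1L]) stop("truncated EDF data")
  sig <- matrix(0, ns, n_rec * spr[1L])
  arr <- array(raw, dim = c(spr[1L], ns, n_rec))
  for (ch in seq_len(ns)) sig[ch, ] <- as.vector(arr[, ch, ])
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- sig * scale + (pmin - dmin * scale)
  recording(sig, fs, channel_labels = labels, patient_id = patient_id)
}

#' EDF quantization step
#'
#' Size of one digital step in microvolts for the writer's 16-bit range;
#' write-then-read round-trips are accurate to half this step plus clipping.
#'
#' @param physical_max symmetric physical bound in microvolts.
#' @return Scalar step in microvolts.
#' @export
edf_quantization_step <- function(physical_max = 2000) {
  (2 * physical_max) / (32767 - (-32767))
}

#' Read or write a recording in a standard format
#'
#' `format = "edf"` uses the 16-bit EDF codec; `format = "rds"` stores the
#' recording losslessly in R's serialization format (fast path for
#' intermediate artifacts). `"auto"` dispatches on the file extension.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"edf"`, `"rds"`.
#' @return [read_recording()] returns a [recording()];
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("auto", "edf", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds"
  if (format == "edf") return(read_edf(path))
  obj <- readRDS(path)
  rec <- recording(obj$signal, obj$fs, obj$channel_labels, obj$patient_id)
  rec
}

#' @rdname read_recording
#' @param rec a [recording()].
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "rds"
  if (format == "edf") return(write_edf(rec, path))
  saveRDS(rec[c("signal", "fs", "channel_labels", "patient_id")], path)
  invisible(path)
}
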