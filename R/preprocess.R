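#' Preprocessing configuration
#'
#' Seizure information in neonatal EEG is concentrated between 0.5 and
#' 12 Hz, so the signal is band-limited to 0.5–12.8 Hz and down-sampled to
#' 32 Hz before entering the network. Windows of 16 s slide with a 1 s
#' shift, giving one probability per second downstream.
#'
#' @param hp_hz high-pass cut-off in Hz (default 0.5).
#' @param lp_hz low-pass cut-off in Hz (default 12.8).
#' @param fs_target sampling rate after resampling (default 32 Hz).
#' @param window_s window length in seconds (default 16).
#' @param shift_s window shift in seconds (default 1).
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(hp_hz = 0.5, lp_hz = 12.8, fs_target = 32,
                              window_s = 16, shift_s = 1) {
  if (!(hp_hz < lp_hz && lp_hz < fs_target / 2))
    stop("need hp_hz < lp_hz < fs_target/2")
  if ((window_s * fs_target) %% 1 != 0)
    stop("window_s * fs_target must be an integer")
  structure(list(hp_hz = hp_hz, lp_hz = lp_hz, fs_target = fs_target,
                 window_s = window_s, shift_s = shift_s),
            class = "preprocess_config")
}

#' Band-limit and resample a recording
#'
#' Applies zero-phase (forward–backward) order-4 Butterworth high- and
#' low-pass filters at the configured cut-offs, then resamples to
#' `fs_target`. When the ratio `fs / fs_target` is an integer the
#' (already low-passed) signal is decimated by sample picking; otherwise a
#' polyphase rational resampler is used (e.g. 200 to 32 Hz = 4/25).
#' Zero-phase filtering avoids any timing skew between signal and labels.
#'
#' @param rec a [recording()] with `fs >= 2 * lp_hz`.
#' @param cfg a [preprocess_config()].
#' @return A [recording()] at `fs_target` Hz, same duration within one
#'   sample.
#' @export
bandlimit_resample <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs < 2 * cfg$lp_hz)
    stop("sampling rate below Nyquist requirement for the low-pass")
  hp <- signal::butter(4, cfg$hp_hz / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, cfg$lp_hz / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$signal, 1L, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  ratio <- rec$fs / cfg$fs_target
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, ncol(filt), by = round(ratio))
    out <- filt[, idx, drop = FALSE]
  } else {
    g <- gcd_int(round(cfg$fs_target), round(rec$fs))
    p <- round(cfg$fs_target) / g
    q <- round(rec$fs) / g
    out <- t(apply(filt, 1L, resample_poly, p = p, q = q))
  }
  recording(out, cfg$fs_target, channel_labels = rec$channel_labels,
            patient_id = rec$patient_id)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Rational p/q resampling by zero-stuffed upsampling, a zero-phase
# windowed-sinc FIR anti-aliasing low-pass at the tighter of the two
# Nyquist rates, and decimation. Unity passband gain.
resample_poly <- function(x, p, q) {
  if (p == q) return(x)
  up <- numeric(length(x) * p)
  up[seq(1L, length(up), by = p)] <- x
  ntaps <- 2L * 10L * max(p, q) + 1L
  b <- as.numeric(signal::fir1(ntaps - 1L, 1 / max(p, q)))
  y <- signal::filtfilt(b, 1, up) * p
  y[seq(1L, length(up), by = q)]
}

#' Weak label for one window
#'
#' A 16 s window is labelled seizure iff at least half of the seconds it
#' covers are seizure seconds (majority rule; exactly half counts as
#' seizure). Boundary-straddling windows thus inherit the dominant class.
#'
#' @param mask per-second 0/1 annotation mask.
#' @param start_s window start in whole seconds from record start (0-based).
#' @param cfg a [preprocess_config()].
#' @return 0 or 1.
#' @export
label_window <- function(mask, start_s, cfg = preprocess_config()) {
  sec <- mask[(start_s + 1L):(start_s + cfg$window_s)]
  as.integer(sum(sec) >= cfg$window_s / 2)
}

#' Cut a preprocessed recording into labelled windows
#'
#' One window starts at every whole second `t = 0, 1, ...,
#' floor(duration) - window_s`, so a record of `D` whole seconds yields
#' `D - 15` window positions (16 s windows, 1 s shift). Every channel of a
#' window is an independent training example carrying the window's weak
#' label; channel identity is retained only for bookkeeping.
#'
#' @param rec32 a [recording()] at `cfg$fs_target` Hz.
#' @param ann matching [annotation_track()] (or `NULL` for unlabelled data,
#'   in which case labels are all zero).
#' @param cfg a [preprocess_config()].
#' @return A `windowed_dataset`: list with `x` (array `samples x channels x
#'   n_windows`), `labels` (per window), `window_start_s`, `patient_id`,
#'   `n_channels`, `cfg`.
#' @export
make_windows <- function(rec32, ann = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(rec32, "recording"))
  if (abs(rec32$fs - cfg$fs_target) > 1e-9)
    stop("make_windows expects a recording at fs_target; run ",
         "bandlimit_resample first")
  D <- floor(ncol(rec32$signal) / cfg$fs_target)
  if (D < cfg$window_s) stop("record shorter than one window")
  starts <- seq(0L, D - cfg$window_s, by = cfg$shift_s)
  wlen <- as.integer(cfg$window_s * cfg$fs_target)
  n_ch <- nrow(rec32$signal)
  x <- array(0, dim = c(wlen, n_ch, length(starts)))
  for (i in seq_along(starts)) {
    i0 <- starts[i] * cfg$fs_target
    x[, , i] <- t(rec32$signal[, (i0 + 1L):(i0 + wlen), drop = FALSE])
  }
  mask <- if (is.null(ann)) integer(D) else ann$mask
  labels <- vapply(starts, function(s) label_window(mask, s, cfg), 0L)
  structure(list(x = x, labels = labels, window_start_s = starts,
                 patient_id = rec32$patient_id, n_channels = n_ch,
                 cfg = cfg),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %s: %d windows x %d ch x %d samples, %d seizure\n",
    paste(unique(x$patient_id), collapse = ","), dim(x$x)[3L],
    x$n_channels, dim(x$x)[1L], sum(x$labels)))
  invisible(x)
}

#' Concatenate windowed datasets from several records
#'
#' @param ds_list list of `windowed_dataset` objects with identical window
#'   geometry.
#' @return A single `windowed_dataset`; `patient_id` becomes a per-window
#'   vector.
#' @export
combine_windows <- function(ds_list) {
  stopifnot(length(ds_list) >= 1L)
  wlen <- dim(ds_list[[1L]]$x)[1L]
  n_ch <- ds_list[[1L]]$n_channels
  for (d in ds_list)
    if (dim(d$x)[1L] != wlen || d$n_channels != n_ch)
      stop("window geometry differs between datasets")
  n_tot <- sum(vapply(ds_list, function(d) dim(d$x)[3L], 0))
  x <- array(0, dim = c(wlen, n_ch, n_tot))
  labels <- integer(n_tot); starts <- numeric(n_tot)
  pid <- character(n_tot)
  at <- 0L
  for (d in ds_list) {
    n <- dim(d$x)[3L]
    x[, , at + seq_len(n)] <- d$x
    labels[at + seq_len(n)] <- d$labels
    starts[at + seq_len(n)] <- d$window_start_s
    pid[at + seq_len(n)] <- rep(d$patient_id, length.out = n)
    at <- at + n
  }
  structure(list(x = x, labels = labels, window_start_s = starts,
                 patient_id = pid, n_channels = n_ch,
                 cfg = ds_list[[1L]]$cfg),
            class = "windowed_dataset")
}

#' Flatten a windowed dataset into per-channel training examples
#'
#' Each (window, channel) pair becomes one single-channel example sharing
#' the window's weak label — the network sees channels independently.
#' Optionally subsamples window positions with a stride to thin the heavy
#' overlap of 1 s-shifted windows for training.
#'
#' @param ds a `windowed_dataset`.
#' @param window_stride keep every `window_stride`-th window (default 1).
#' @param channels_per_window draw this many channels at random (without
#'   replacement, from the current RNG stream) per kept window instead of
#'   using all channels; `NULL` keeps all. Thinning is useful for training
#'   because adjacent windows share 15 of their 16 seconds.
#' @return List with `x` (matrix `samples x n_examples`), `y` labels,
#'   `window_index`, `channel_index`.
#' @export
flatten_examples <- function(ds, window_stride = 1L,
                             channels_per_window = NULL) {
  keep <- seq(1L, dim(ds$x)[3L], by = window_stride)
  wlen <- dim(ds$x)[1L]; n_ch <- ds$n_channels
  if (is.null(channels_per_window) || channels_per_window >= n_ch) {
    x <- matrix(ds$x[, , keep], nrow = wlen)  # channel fastest, then window
    y <- rep(ds$labels[keep], each = n_ch)
    return(list(x = x, y = y,
                window_index = rep(keep, each = n_ch),
                channel_index = rep(seq_len(n_ch), times = length(keep))))
  }
  cpw <- as.integer(channels_per_window)
  chan <- as.vector(vapply(keep, function(i) sample.int(n_ch, cpw),
                           integer(cpw)))
  win <- rep(keep, each = cpw)
  x <- matrix(0, wlen, length(win))
  for (j in seq_along(win)) x[, j] <- ds$x[, chan[j], win[j]]
  list(x = x, y = rep(ds$labels[keep], each = cpw),
       window_index = win, channel_index = chan)
}
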