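#' Score one recording end to end
#'
#' Preprocesses a raw recording (band-limit, resample, window), scores it
#' with a model or ensemble, fuses channels, maps window probabilities to
#' their center seconds and runs the probabilistic postprocessing.
#'
#' @param rec a raw [recording()].
#' @param models a `seizure_model`, `seizure_ensemble` or list of models.
#' @param pcfg a [preprocess_config()].
#' @param ppcfg a [postprocess_config()].
#' @param fusion channel-fusion rule, `"mean"` or `"max"`.
#' @param dense use whole-record dense scoring
#'   ([predict_windows_dense()]) instead of per-window evaluation.
#' @return List with `raw_sequence` (pre-smoothing), `sequence` (smoothed
#'   and background-adapted) and `events` (detections).
#' @export
detect_record <- function(rec, models, pcfg = preprocess_config(),
                          ppcfg = postprocess_config(), fusion = "mean",
                          dense = TRUE) {
  rec32 <- bandlimit_resample(rec, pcfg)
  if (dense) {
    mods <- as_model_list(models)
    ps <- lapply(mods, predict_windows_dense, rec32 = rec32, cfg = pcfg)
    pw <- Reduce(`+`, ps) / length(ps)
    starts <- seq(0L, floor(ncol(rec32$signal) / pcfg$fs_target) -
                    pcfg$window_s, by = pcfg$shift_s)
  } else {
    ds <- make_windows(rec32, NULL, pcfg)
    pw <- ensemble_predict(models, ds)
    starts <- ds$window_start_s
  }
  raw <- windows_to_sequence(aggregate_channels(pw, fusion),
                             starts, pcfg$window_s, rec$patient_id)
  post <- postprocess_sequence(raw, ppcfg, duration_s = rec$duration_s)
  list(raw_sequence = raw, sequence = post$sequence,
       events = post$events)
}

#' Preprocess and window a list of raw records
#'
#' @param records list of `list(recording, annotations)` pairs (the shape
#'   produced by [synthesize_corpus()]); `annotations` may be `NULL`.
#' @param pcfg a [preprocess_config()].
#' @return A combined `windowed_dataset` over all records.
#' @export
windows_from_records <- function(records, pcfg = preprocess_config()) {
  ds <- lapply(records, function(r) {
    rec32 <- bandlimit_resample(r$recording, pcfg)
    make_windows(rec32, r$annotations, pcfg)
  })
  combine_windows(ds)
}
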