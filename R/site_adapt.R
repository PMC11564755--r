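#' Pseudo-labelling adaptation configuration
#'
#' A model trained at one recording site degrades at another (distribution
#' shift from hardware, electrode practice and procedures). Adaptation
#' uses an unlabelled sample of the target site: the trained ensemble
#' scores it, confidently non-seizure windows are pseudo-labelled as
#' background, the most seizure-like fraction is discarded as uncertain,
#' and the model is completely retrained on the merged corpus. Only the
#' non-seizure class is ever pseudo-labelled, and target-site ground truth
#' is never used.
#'
#' @param discard_fraction fraction of the unlabelled windows discarded as
#'   uncertain (default 0.015, i.e. 1.5%), so that potential seizure
#'   activity is not marked as background.
#' @param fusion channel-fusion rule for teacher scoring (`"mean"` or
#'   `"max"`).
#' @return A validated `adapt_config`.
#' @export
adapt_config <- function(discard_fraction = 0.015, fusion = "mean") {
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  structure(list(discard_fraction = discard_fraction, fusion = fusion),
            class = "adapt_config")
}

#' Score an unlabelled corpus with a teacher ensemble
#'
#' Produces soft labels (seizure probabilities) for every per-channel
#' training example of the unlabelled windows, preprocessed identically to
#' the training data. Window and channel provenance are retained.
#'
#' @param teacher a `seizure_ensemble` (or list of models).
#' @param ds a `windowed_dataset` of the unlabelled recordings.
#' @return List `(probs, window_index, channel_index)` with one entry per
#'   example.
#' @export
score_unlabelled <- function(teacher, ds) {
  if (!dim(ds$x)[3L]) stop("empty unlabelled corpus")
  models <- as_model_list(teacher)
  ex <- flatten_examples(ds)
  ps <- lapply(models, predict_examples, x = ex$x)
  list(probs = Reduce(`+`, ps) / length(ps),
       window_index = ex$window_index, channel_index = ex$channel_index)
}

#' Pseudo-labelling threshold from a discard fraction
#'
#' Returns the probability threshold that pseudo-labels the lowest
#' `1 - discard_fraction` of the scores as non-seizure and discards the
#' rest as uncertain: with `n` scores, the `floor(n * (1 -
#' discard_fraction))` smallest are kept, and ties at the threshold are
#' discarded (conservative — a tied window is never labelled background).
#'
#' @param probs teacher probabilities of the unlabelled examples.
#' @param discard_fraction fraction to discard.
#' @return The threshold; examples with `probs <` threshold are
#'   pseudo-labelled 0.
#' @export
select_threshold <- function(probs, discard_fraction = 0.015) {
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  n <- length(probs)
  if (!n) stop("no probabilities supplied")
  m <- floor(n * (1 - discard_fraction))     # nominal number kept
  if (m >= n) return(Inf)
  sort(probs, partial = m + 1L)[m + 1L]
}

#' Adapt a model to a new site by pseudo-labelling
#'
#' Implements the full adaptation loop: the teacher scores the unlabelled
#' target-site windows, [select_threshold()] fixes the confidence cut,
#' windows below it join the labelled corpus as background (class 0)
#' examples, class weights are recomputed on the merged corpus (its
#' prevalence changed), and the ensemble is retrained from random
#' initialization. A complete retrain — not fine-tuning — is used because
#' only one class is pseudo-labelled.
#'
#' @param labelled_ds `windowed_dataset` of the labelled source site (both
#'   classes present).
#' @param unlabelled_ds `windowed_dataset` of the unlabelled target site.
#' @param teacher the trained `seizure_ensemble` (same architecture).
#' @param cfg an [adapt_config()].
#' @param train_cfg a [train_config()] for the retrain.
#' @param arch architecture name for the retrain (default `"enhanced"`).
#' @param verbose print epoch lines.
#' @return List with `ensemble` (the adapted `seizure_ensemble`),
#'   `threshold`, `n_pseudo`, `n_discarded`.
#' @export
adapt_model <- function(labelled_ds, unlabelled_ds, teacher,
                        cfg = adapt_config(), train_cfg = train_config(),
                        arch = "enhanced", verbose = FALSE) {
  models <- as_model_list(teacher)
  # thin both corpora with the training stride before scoring, so the
  # pseudo-label unit matches the unit entering training
  lab_ex <- with_seed(train_cfg$seeds[1L],
    flatten_examples(labelled_ds, train_cfg$window_stride,
                     train_cfg$channels_per_window))
  un_ex <- with_seed(train_cfg$seeds[1L] + 1L,
    flatten_examples(unlabelled_ds, train_cfg$window_stride,
                     train_cfg$channels_per_window))
  ps <- lapply(models, predict_examples, x = un_ex$x)
  probs <- Reduce(`+`, ps) / length(ps)
  theta <- select_threshold(probs, cfg$discard_fraction)
  keep <- probs < theta
  x <- cbind(lab_ex$x, un_ex$x[, keep, drop = FALSE])
  y <- c(lab_ex$y, rep(0L, sum(keep)))
  cfg2 <- train_cfg
  cfg2$class_weights <- NULL                 # recompute on the merged set
  fits <- lapply(cfg2$seeds, function(s)
    train_examples(arch, x, y, cfg2, seed = s, verbose = verbose))
  list(ensemble = structure(fits, class = "seizure_ensemble"),
       threshold = theta, n_pseudo = sum(keep),
       n_discarded = sum(!keep))
}
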