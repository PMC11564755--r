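# Epoch metrics (per-second "datapoints"), event metrics, and the
# AUC-difference significance test.

#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney U statistic normalized by
#' `n_pos * n_neg`, with ties counted one half — identical to trapezoidal
#' integration of the ROC.
#'
#' @param labels binary per-datapoint labels (1 = seizure).
#' @param scores classifier scores, higher = more seizure-like.
#' @return AUC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  n1 <- sum(labels); n0 <- length(labels) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                          # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC vertices ordered from the (0,0) corner: cumulative TPR/FPR at each
# distinct score threshold.
roc_points <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  if (sum(labels) == 0L || sum(labels) == length(labels))
    stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  keep <- c(diff(sc) != 0, TRUE)             # last index of each tie group
  tp <- cumsum(lab)[keep]; fp <- cumsum(1 - lab)[keep]
  n1 <- sum(labels); n0 <- length(labels) - n1
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Partial AUC above 90% specificity (AUC90)
#'
#' Trapezoidal area under the ROC restricted to specificity in
#' `[0.9, 1.0]` (false-positive rate 0 to 0.1), with the boundary
#' sensitivity obtained by linear interpolation, normalized by the 0.1
#' band width and expressed as a percent: a perfect classifier scores
#' 100, chance scores 5.
#'
#' @inheritParams roc_auc
#' @return AUC90 in percent.
#' @export
auc90 <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  fpr_max <- 0.1
  x <- pts$fpr; y <- pts$tpr
  # interpolate the curve at fpr_max, then integrate over [0, fpr_max]
  if (max(x) < fpr_max) {
    x <- c(x, fpr_max); y <- c(y, max(y))
  } else if (!any(x == fpr_max)) {
    i <- which(x > fpr_max)[1L]
    yb <- y[i - 1L] + (y[i] - y[i - 1L]) *
      (fpr_max - x[i - 1L]) / (x[i] - x[i - 1L])
    x <- c(x[seq_len(i - 1L)], fpr_max)
    y <- c(y[seq_len(i - 1L)], yb)
  } else {
    keep <- x <= fpr_max
    x <- x[keep]; y <- y[keep]
  }
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  100 * area / fpr_max
}

#' Area under the precision–recall curve
#'
#' Average-precision form: precision steps are summed at each distinct
#' recall increment (trapezoidal interpolation of PR curves is biased and
#' is therefore not the default). The positive class is seizure. With
#' scores carrying no information (all identical) the result equals the
#' prevalence.
#'
#' @inheritParams roc_auc
#' @param method `"average_precision"` (default) or `"trapezoid"`.
#' @return AUC-PR in percent.
#' @export
auc_pr <- function(labels, scores, method = c("average_precision",
                                              "trapezoid")) {
  method <- match.arg(method)
  labels <- as.integer(labels != 0)
  n1 <- sum(labels)
  if (n1 == 0L) stop("at least one positive datapoint is required")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  np <- which(keep)                          # datapoints at/above threshold
  prec <- tp / np
  rec <- tp / n1
  if (method == "average_precision") {
    100 * sum(diff(c(0, rec)) * prec)
  } else {
    100 * sum(diff(c(0, rec)) * (c(prec[1L], head(prec, -1)) + prec) / 2)
  }
}

#' Precision–recall curve points
#'
#' @inheritParams roc_auc
#' @return data.frame `recall`, `precision` at each distinct threshold.
#' @export
pr_points <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  data.frame(recall = tp / sum(labels), precision = tp / which(keep))
}

events_overlap <- function(a_on, a_off, b_on, b_off)
  a_on < b_off & b_on < a_off

#' Event-based detection metrics
#'
#' Good detection rate (GDR) is the percentage of true seizure events
#' overlapped by at least one detection (any overlap counts); false
#' detections per hour (FD/h) is the number of detected events that
#' overlap no true event, divided by the record duration in hours.
#'
#' @param true_events,detected_events event data.frames (`onset_s`,
#'   `offset_s`), each sorted and non-overlapping.
#' @param record_hours record duration in hours.
#' @return List `(gdr_percent, fd_per_hour, n_true, n_detected)`;
#'   `gdr_percent` is `NA` when there are no true events (flagged, so it
#'   can be excluded from averages).
#' @export
event_metrics <- function(true_events, detected_events, record_hours) {
  te <- as.data.frame(true_events); de <- as.data.frame(detected_events)
  detected_true <- vapply(seq_len(nrow(te)), function(i)
    any(events_overlap(te$onset_s[i], te$offset_s[i],
                       de$onset_s, de$offset_s)), TRUE)
  false_det <- vapply(seq_len(nrow(de)), function(j)
    !any(events_overlap(de$onset_s[j], de$offset_s[j],
                        te$onset_s, te$offset_s)), TRUE)
  list(gdr_percent = if (nrow(te)) 100 * mean(detected_true) else NA_real_,
       fd_per_hour = sum(false_det) / record_hours,
       n_true = nrow(te), n_detected = nrow(de))
}

#' GDR versus FD/h operating curve
#'
#' For each threshold, postprocessing is run per patient on the smoothed,
#' background-adapted sequences and the per-patient event metrics are
#' averaged (unweighted) across patients that have at least one true
#' seizure event; set `include_all_patients = TRUE` to average FD/h over
#' every patient instead.
#'
#' @param sequences named list of adapted [probability_sequence()]s, one
#'   per patient.
#' @param truths named list of matching [annotation_track()]s.
#' @param thresholds threshold grid in `(0, 1)`.
#' @param cfg a [postprocess_config()] supplying the collar.
#' @param include_all_patients average FD/h over all patients, not only
#'   seizure patients.
#' @return data.frame `threshold`, `fd_per_hour`, `gdr_percent`.
#' @export
gdr_fd_curve <- function(sequences, truths, thresholds,
                         cfg = postprocess_config(),
                         include_all_patients = FALSE) {
  if (!length(thresholds)) stop("empty threshold grid")
  stopifnot(length(sequences) == length(truths))
  if (!any(vapply(truths, function(tr) nrow(tr$events) > 0L, TRUE)))
    stop("at least one patient with seizure events is required")
  rows <- lapply(thresholds, function(th) {
    gdr <- c(); fd <- c()
    for (i in seq_along(sequences)) {
      s <- sequences[[i]]; tr <- truths[[i]]
      det <- threshold_and_collar(s, th, cfg$collar_s, tr$duration_s)
      em <- event_metrics(tr$events, det, tr$duration_s / 3600)
      has_sz <- nrow(tr$events) > 0L
      if (has_sz) gdr <- c(gdr, em$gdr_percent)
      if (has_sz || include_all_patients) fd <- c(fd, em$fd_per_hour)
    }
    data.frame(threshold = th, fd_per_hour = mean(fd),
               gdr_percent = mean(gdr))
  })
  do.call(rbind, rows)
}

#' Relative error-rate reduction
#'
#' Fraction of the remaining error `1 - AUC` removed by an improvement:
#' `100 * (auc_new - auc_old) / (1 - auc_old)`. An improvement from 0.96
#' to 0.98 is a 50% relative error-rate reduction.
#'
#' @param auc_old,auc_new AUC values as fractions, `auc_old < 1`.
#' @return Reduction in percent.
#' @export
relative_error_reduction <- function(auc_old, auc_new) {
  if (any(auc_old >= 1)) stop("auc_old must be < 1")
  100 * (auc_new - auc_old) / (1 - auc_old)
}

# Hanley-McNeil standard error of an AUC estimate
auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Significance test for an AUC difference
#'
#' Uses the Wilcoxon/Mann–Whitney interpretation of the AUC with the
#' Hanley–McNeil standard error, which shrinks roughly with the inverse
#' square root of `n_pos * n_neg`. The two models' standard errors are
#' treated as independent: `z = (AUC_A - AUC_B) / sqrt(SE_A^2 + SE_B^2)`,
#' two-sided.
#'
#' @param labels shared binary labels.
#' @param scores_a,scores_b the two models' scores on the same datapoints.
#' @return List `(auc_a, auc_b, se_a, se_b, z, p_value)`.
#' @export
auc_difference_test <- function(labels, scores_a, scores_b) {
  labels <- as.integer(labels != 0)
  n1 <- sum(labels); n0 <- length(labels) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  a <- roc_auc(labels, scores_a)
  b <- roc_auc(labels, scores_b)
  se_a <- auc_se(a, n1, n0); se_b <- auc_se(b, n1, n0)
  denom <- sqrt(se_a^2 + se_b^2)
  z <- if (denom == 0) 0 else (a - b) / denom
  list(auc_a = a, auc_b = b, se_a = se_a, se_b = se_b, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Full evaluation report for a set of patients
#'
#' Pools per-second datapoints across patients for the epoch metrics
#' (AUC, AUC90, AUC-PR with their curves) and averages the event metrics
#' across seizure patients at the configured threshold.
#'
#' @param sequences named list of adapted [probability_sequence()]s.
#' @param truths named list of matching [annotation_track()]s.
#' @param cfg a [postprocess_config()].
#' @return An `evaluation_report` list: `auc`, `auc90`, `auc_pr` (all in
#'   percent), `roc_points`, `pr_points`, `gdr_percent`, `fd_per_hour`,
#'   `per_patient`, `n_pos`, `n_neg`.
#' @export
evaluate_detection <- function(sequences, truths,
                               cfg = postprocess_config()) {
  stopifnot(length(sequences) == length(truths))
  labels <- c(); scores <- c()
  per <- list()
  gdr <- c(); fd <- c()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]; tr <- truths[[i]]
    sec <- s$t0_s + seq_along(s$p) - 1L      # second index of each entry
    lab <- tr$mask[sec + 1L]
    labels <- c(labels, lab); scores <- c(scores, s$p)
    det <- threshold_and_collar(s, cfg$threshold, cfg$collar_s,
                                tr$duration_s)
    em <- event_metrics(tr$events, det, tr$duration_s / 3600)
    per[[i]] <- data.frame(patient_id = s$patient_id,
                           auc = if (length(unique(lab)) > 1L)
                             roc_auc(lab, s$p) else NA_real_,
                           gdr_percent = em$gdr_percent,
                           fd_per_hour = em$fd_per_hour)
    if (nrow(tr$events)) { gdr <- c(gdr, em$gdr_percent)
                           fd <- c(fd, em$fd_per_hour) }
  }
  structure(list(
    auc = 100 * roc_auc(labels, scores),
    auc90 = auc90(labels, scores),
    auc_pr = auc_pr(labels, scores),
    roc_points = roc_points(labels, scores),
    pr_points = pr_points(labels, scores),
    gdr_percent = if (length(gdr)) mean(gdr) else NA_real_,
    fd_per_hour = if (length(fd)) mean(fd) else NA_real_,
    per_patient = do.call(rbind, per),
    n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation_report> AUC %.1f%%  AUC90 %.1f%%  AUC-PR %.1f%%\n",
    "  GDR %.1f%%  FD/h %.2f  (%d seizure / %d background seconds)\n"),
    x$auc, x$auc90, x$auc_pr, x$gdr_percent, x$fd_per_hour,
    x$n_pos, x$n_neg))
  invisible(x)
}
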