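test_that("roc_auc is the normalized Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # enumerate the 4 pos-neg pairs: 3 wins, 1 loss -> 0.75
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  # ties count one half
  expect_equal(roc_auc(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(1)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)              # force some ties
    expect_lt(abs(roc_auc(labels, scores) -
                  auc_pair_oracle(labels, scores)), 1e-12)
  }
})

test_that("auc90 normalizes the high-specificity partial area", {
  expect_equal(auc90(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 100)
  # scoreless classifier: the chance diagonal leaves a 5% triangle
  expect_equal(auc90(rep(c(0, 1), 50), rep(0.5, 100)), 5)

  # pair-counting oracle on a random fixture: the partial area over
  # FPR in [0, 0.1] is the mean win rate against the 10% highest-scoring
  # negatives (one vertical ROC strip per negative, ties counted half)
  set.seed(2)
  labels <- sample(rep(c(0, 1), c(300, 120)))
  scores <- rnorm(420) + labels
  pos <- scores[labels == 1]
  top_neg <- sort(scores[labels == 0], decreasing = TRUE)[1:30]
  strip <- vapply(top_neg, function(nv)
    (sum(pos > nv) + 0.5 * sum(pos == nv)) / length(pos), numeric(1))
  oracle <- 100 * sum(strip) / 300 / 0.1
  expect_lt(abs(auc90(labels, scores) - oracle), 1e-9)
  expect_lte(auc90(labels, scores), 100)
})

test_that("auc_pr follows the average-precision construction", {
  expect_equal(auc_pr(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 100)
  # uninformative scores: precision equals prevalence everywhere
  expect_equal(auc_pr(c(rep(0, 8), rep(1, 2)), rep(0.4, 10)), 20)
  expect_error(auc_pr(c(0, 0), c(0.1, 0.2)), "positive")

  set.seed(3)
  labels <- rbinom(60, 1, 0.3); labels[1] <- 1
  scores <- round(rnorm(60), 1)
  # exhaustive threshold sweep oracle
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- vapply(thr, function(t) mean(scores[labels == 1] >= t),
                numeric(1))
  prec <- vapply(thr, function(t) sum(labels == 1 & scores >= t) /
                   sum(scores >= t), numeric(1))
  oracle <- 100 * sum(diff(c(0, rec)) * prec)
  expect_equal(auc_pr(labels, scores), oracle)
})

test_that("event metrics count overlaps and false alarms", {
  truth <- data.frame(onset_s = 100, offset_s = 200)
  em <- event_metrics(truth, truth, 1)
  expect_equal(em$gdr_percent, 100); expect_equal(em$fd_per_hour, 0)

  det <- data.frame(onset_s = c(150, 400), offset_s = c(160, 410))
  em2 <- event_metrics(truth, det, 1)
  expect_equal(em2$gdr_percent, 100)
  expect_equal(em2$fd_per_hour, 1)

  # one detection spanning two true events: both detected, no false alarm
  truth2 <- data.frame(onset_s = c(10, 30), offset_s = c(20, 40))
  em3 <- event_metrics(truth2, data.frame(onset_s = 15, offset_s = 35), 2)
  expect_equal(em3$gdr_percent, 100)
  expect_equal(em3$fd_per_hour, 0)

  # order invariance
  em4 <- event_metrics(truth2[2:1, ], det[2:1, ], 1)
  expect_equal(em4$gdr_percent, event_metrics(truth2, det, 1)$gdr_percent)

  expect_true(is.na(event_metrics(truth[0, ], det, 1)$gdr_percent))
})

test_that("the GDR/FD curve hits its threshold limits", {
  set.seed(4)
  r <- tiny_record(duration_s = 300, seed = 31)
  p <- pmin(pmax(r$annotations$mask * 0.6 + runif(300, 0, 0.3), 0), 1)
  seqs <- list(p1 = probability_sequence(p, 0, "p1"))
  truths <- list(p1 = r$annotations)
  curve <- gdr_fd_curve(seqs, truths, c(0.001, 0.5, 0.999),
                        postprocess_config(collar_s = 5))
  expect_equal(curve$gdr_percent[1], 100)     # theta -> 0 detects all
  expect_equal(curve$fd_per_hour[3], 0)       # theta -> 1 detects nothing
  expect_true(all(diff(curve$fd_per_hour) <= 1e-9))
  expect_error(gdr_fd_curve(seqs, truths, numeric(0)), "grid")
})

test_that("relative error-rate reduction matches its definition", {
  expect_equal(relative_error_reduction(0.96, 0.98), 50)
  expect_equal(relative_error_reduction(0.7, 0.7), 0)
  expect_equal(relative_error_reduction(0.9, 0.8), -100)
  expect_error(relative_error_reduction(1, 0.99), "< 1")
})

test_that("the AUC difference test behaves like a Wilcoxon-based z-test", {
  set.seed(5)
  labels <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + labels
  same <- auc_difference_test(labels, s, s)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)

  # the standard error shrinks with the class-count product: replicating
  # the same datapoints 4x keeps the AUC fixed, and the Hanley-McNeil SE
  # falls by ~sqrt(4) = 2 (its numerator grows with the class counts)
  lab <- rep(c(0, 1), times = c(40, 10))
  sc <- c(rnorm(40), rnorm(10) + 1)
  se1 <- auc_difference_test(lab, sc, rev(sc))$se_a
  se4 <- auc_difference_test(rep(lab, 4), rep(sc, 4),
                             rep(rev(sc), 4))$se_a
  expect_lt(abs(se1 / se4 - 2), 0.4)

  # a genuinely better model is flagged significant on a large fixture
  lab <- rbinom(4000, 1, 0.2)
  good <- rnorm(4000) + 2 * lab
  bad <- rnorm(4000) + 0.2 * lab
  res <- auc_difference_test(lab, good, bad)
  expect_gt(res$z, 2)
  expect_lt(res$p_value, 0.05)
})

test_that("evaluation reports pool per-second datapoints across patients", {
  set.seed(6)
  mk <- function(seed, id) {
    r <- tiny_record(duration_s = 240, seed = seed)
    p <- pmin(pmax(r$annotations$mask * 0.5 + runif(240, 0, 0.3), 0), 1)
    list(seq = probability_sequence(p, 0, id), truth = r$annotations)
  }
  a <- mk(41, "a"); b <- mk(43, "b")
  rep <- evaluate_detection(list(a = a$seq, b = b$seq),
                            list(a = a$truth, b = b$truth),
                            postprocess_config(threshold = 0.4))
  expect_equal(rep$n_pos + rep$n_neg, 480L)
  expect_equal(rep$n_pos, sum(a$truth$mask) + sum(b$truth$mask))
  expect_true(rep$auc > 50 && rep$auc <= 100)
  expect_equal(nrow(rep$per_patient), 2L)
  pooled <- roc_auc(c(a$truth$mask, b$truth$mask), c(a$seq$p, b$seq$p))
  expect_equal(rep$auc, 100 * pooled)
})
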