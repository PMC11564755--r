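# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the full suite stays fast.

# a short synthetic record with one injected seizure
tiny_record <- function(duration_s = 120, seed = 5, ...) {
  synthesize_record(synth_config(duration_s = duration_s, seed = seed, ...))
}

# amplitude-separable single-channel training examples: class 1 carries an
# added rhythmic discharge, class 0 is plain noise
separable_examples <- function(n_per_class = 100, len = 512, seed = 7,
                               strength = 3) {
  set.seed(seed)
  mk <- function(k, seiz) vapply(seq_len(k), function(i) {
    bg <- rnorm(len)
    if (seiz) bg + strength * sin(2 * pi * 2 * seq_len(len) / 32 +
                                  runif(1, 0, 2 * pi))
    else bg
  }, numeric(len))
  list(x = cbind(mk(n_per_class, FALSE), mk(n_per_class, TRUE)),
       y = rep(0:1, each = n_per_class))
}

# brute-force centered moving average (independent oracle)
maf_oracle <- function(p, half) {
  n <- length(p)
  vapply(seq_len(n), function(i)
    mean(p[max(1, i - half):min(n, i + half)]), numeric(1))
}

# brute-force collar oracle: mark every second of every suprathreshold run
# plus a symmetric collar on a discrete timeline, then read off the runs
collar_oracle <- function(p, theta, collar, duration) {
  covered <- logical(duration)
  for (t in which(p >= theta) - 1L) {
    lo <- max(0L, t - collar); hi <- min(duration - 1L, t + collar)
    covered[(lo:hi) + 1L] <- TRUE
  }
  mask_to_events(as.integer(covered))
}

# O(n_pos * n_neg) pair-counting AUC (independent oracle)
auc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
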