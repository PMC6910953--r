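# Shared fixtures and independent oracles, built in code at test time.

# small effect corpus + matching null background corpus, feature mode
tiny_corpus <- function(seed = 7, n_spk = 4, n_utt = 2, effect = NULL,
                        grammar = ddk_grammar(3), dim = 6) {
  generate_corpus(sim_spec(
    n_speakers_per_class = n_spk, utterances_per_speaker = n_utt,
    segment_grammar = grammar, class_effect = effect %||% list(),
    dim = dim, seed = seed))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_scoreset <- function(seed, n_max = 50) {
  set.seed(seed)
  n1 <- sample(2:n_max, 1)
  n0 <- sample(2:n_max, 1)
  sep <- runif(1, 0, 2)
  data.frame(
    llr = c(rnorm(n1, mean = sep), rnorm(n0)),
    true_class = rep(c("PD", "Ctrl"), c(n1, n0)),
    stringsAsFactors = FALSE)
}

# --- brute-force oracles -------------------------------------------------

# EER by exhaustive threshold sweep over every constant piece of the
# step functions (representative thresholds: below all scores, then each
# sorted score value), decision rule "score > lambda => PD"
oracle_eer <- function(llr, true_class) {
  pd <- llr[true_class == "PD"]
  ctrl <- llr[true_class == "Ctrl"]
  cands <- c(min(llr) - 1, sort(unique(llr)))
  best_gap <- Inf; best_eer <- Inf
  for (l in cands) {
    fpr <- mean(ctrl > l)
    fnr <- mean(pd <= l)
    gap <- abs(fpr - fnr)
    if (gap < best_gap - 1e-12 ||
        (gap < best_gap + 1e-12 && (fpr + fnr) / 2 < best_eer)) {
      best_gap <- gap
      best_eer <- (fpr + fnr) / 2
    }
  }
  best_eer
}

# AUC by O(n^2) pair counting, ties worth one half
oracle_auc <- function(score, truth) {
  pos <- score[truth == "PD"]
  neg <- score[truth == "Ctrl"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# delta filter by explicit convolution loop with edge replication
oracle_deltas <- function(static) {
  n <- nrow(static)
  taps <- (-2:2) / 10
  one_pass <- function(m) {
    out <- matrix(0, n, ncol(m))
    for (t in seq_len(n)) {
      for (k in -2:2) {
        idx <- min(max(t + k, 1), n)
        out[t, ] <- out[t, ] + taps[k + 3] * m[idx, ]
      }
    }
    out
  }
  d1 <- one_pass(static)
  cbind(static, d1, one_pass(d1))
}
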