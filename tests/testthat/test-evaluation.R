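test_that("fold assignment is stratified, seeded and a partition", {
  speakers <- data.frame(
    speaker_id = sprintf("s%02d", 1:22),
    class = rep(c("PD", "Ctrl"), each = 11), stringsAsFactors = FALSE)
  f1 <- make_folds(speakers, 11, seed = 4)
  # 22 speakers over 11 folds: two per fold, one of each class
  tab <- table(f1$fold, f1$class)
  expect_true(all(tab == 1))
  expect_setequal(f1$speaker_id, speakers$speaker_id)
  expect_identical(f1, make_folds(speakers, 11, seed = 4))
  expect_false(identical(f1$fold, make_folds(speakers, 11, seed = 5)$fold))
  expect_error(make_folds(speakers[1:8, ], 11), "fewer speakers")
})

test_that("approach semantics: phon_raw scores every test frame, raw_phon only grouped frames", {
  co <- tiny_corpus(seed = 41, n_spk = 6, n_utt = 2, dim = 5,
                    effect = list(plosive = list(mean_shift = 0.5)))
  ubm_co <- tiny_corpus(seed = 43, n_spk = 6, n_utt = 2, dim = 5)
  total_frames <- sum(co$manifest$n_frames)
  plosive_frames <- sum(vapply(group_corpus(co, "plosive"),
                               function(r) sum(r$mask), 1L))
  expect_lt(plosive_frames, total_frames)

  raw_phon <- run_approach(co, ubm_co, "raw_phon", grouping = "plosive",
                           G = 2, n_folds = 3, fold_seed = 1)
  phon_raw <- run_approach(co, ubm_co, "phon_raw", grouping = "plosive",
                           G = 2, n_folds = 3, fold_seed = 1)
  # pooled over the fold partition, every utterance is tested exactly once
  expect_equal(sum(raw_phon$utterance_records$n_frames_scored),
               plosive_frames)
  expect_equal(sum(phon_raw$utterance_records$n_frames_scored),
               total_frames)
})

test_that("approach/grouping combinations are validated before any training", {
  co <- tiny_corpus(seed = 47, n_spk = 4, n_utt = 1, dim = 4)
  expect_error(run_approach(co, co, "baseline", grouping = "plosive",
                            G = 2, n_folds = 2), "no grouping")
  expect_error(run_approach(co, co, "raw_phon", G = 2, n_folds = 2),
               "requires a grouping")
})

test_that("the full cross-validation pipeline is deterministic", {
  co <- tiny_corpus(seed = 51, n_spk = 5, n_utt = 2, dim = 4,
                    effect = list(plosive = list(mean_shift = 1)))
  ubm_co <- tiny_corpus(seed = 53, n_spk = 5, n_utt = 2, dim = 4)
  r1 <- run_approach(co, ubm_co, "raw_phon", grouping = "plosive",
                     G = 2, n_folds = 5, fold_seed = 2)
  r2 <- run_approach(co, ubm_co, "raw_phon", grouping = "plosive",
                     G = 2, n_folds = 5, fold_seed = 2)
  expect_identical(r1$speaker_records, r2$speaker_records)
  expect_identical(r1$speaker_metrics, r2$speaker_metrics)
})

test_that("cross-corpora rounds hold out each corpus exactly once", {
  mk <- function(seed) generate_corpus(sim_spec(
    n_speakers_per_class = 4, utterances_per_speaker = 2,
    segment_grammar = ddk_grammar(3), dim = 4,
    class_effect = list(plosive = list(mean_shift = 1.5)), seed = seed))
  corpora <- list(A = mk(61), B = mk(62), C = mk(63))
  # distinct speaker ids across corpora
  for (nm in names(corpora)) {
    for (u in names(corpora[[nm]]$utterances)) {
      corpora[[nm]]$utterances[[u]]$speaker_id <-
        paste0(nm, "_", corpora[[nm]]$utterances[[u]]$speaker_id)
    }
  }
  ubm_co <- mk(64)
  res <- run_cross_corpora(corpora, ubm_co, "phon_raw",
                           grouping = "plosive", G = 2)
  expect_equal(nrow(res), 3)
  expect_setequal(res$test_corpus, c("A", "B", "C"))
  expect_true(all(res$n_test == 8))
  expect_error(run_cross_corpora(corpora[1:2], ubm_co, "baseline"),
               ">= 3 corpora")
})

test_that("select_best prefers accuracy, then AUC, then smaller G and F", {
  res <- data.frame(accuracy = c(90, 90, 90, 90, 85),
                    auc = c(0.90, 0.85, 0.90, 0.90, 0.99),
                    G = c(64, 8, 8, 8, 4), F = c(10, 10, 12, 14, 10))
  best <- select_best(res)
  expect_equal(best$auc, 0.90)                 # AUC beats the 0.85 row
  expect_equal(best$G, 8)                      # smaller G beats G = 64
  expect_equal(best$F, 12)                     # smaller F breaks the last tie
  one <- res[5, , drop = FALSE]
  expect_equal(select_best(one)$accuracy, 85)
})

test_that("gmm_ubm exposes calibrated thresholds and predicts at both levels", {
  co <- tiny_corpus(seed = 71, n_spk = 4, n_utt = 2, dim = 4,
                    effect = list(plosive = list(mean_shift = 2)))
  records <- unname(co$utterances)
  ubm <- fit_gmm(do.call(rbind, lapply(records, function(u) u$frames$values)),
                 2, map_config(init_seed = 1))
  fit <- gmm_ubm(records, ubm)
  expect_s3_class(fit, "gmm_ubm")
  expect_true(is.finite(fit$threshold_utterance$lambda))
  pu <- predict(fit, records, level = "utterance")
  ps <- predict(fit, records, level = "speaker")
  expect_equal(nrow(pu), length(records))
  expect_equal(nrow(ps), 8)
  expect_true(all(ps$decision %in% c("PD", "Ctrl")))
})
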