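test_that("the generator is fully determined by its seed", {
  sp <- sim_spec(n_speakers_per_class = 3, utterances_per_speaker = 2,
                 class_effect = list(plosive = list(mean_shift = 1)),
                 seed = 123)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(c1$manifest, c2$manifest)
  for (id in names(c1$utterances)) {
    expect_identical(c1$utterances[[id]]$frames$values,
                     c2$utterances[[id]]$frames$values)
    expect_identical(c1$utterances[[id]]$segments,
                     c2$utterances[[id]]$segments)
  }
  # a different seed changes the draw
  c3 <- generate_corpus(sim_spec(n_speakers_per_class = 3,
                                 utterances_per_speaker = 2,
                                 class_effect = list(plosive = list(mean_shift = 1)),
                                 seed = 124))
  expect_false(identical(c1$utterances[[1]]$frames$values,
                         c3$utterances[[1]]$frames$values))
})

test_that("invalid specifications are rejected", {
  expect_error(sim_spec(segment_grammar = ddk_grammar(0)), "empty")
  expect_error(sim_spec(mode = "waveform", sample_rate = 8000), "16000")
  expect_error(sim_spec(class_effect = list(plosive = list(var_scale = -1))),
               "positive")
  expect_error(sim_spec(class_effect = list(sibilant = list(mean_shift = 1))),
               "manner classes")
})

test_that("segments exactly tile each utterance in feature mode", {
  co <- tiny_corpus(seed = 17, n_spk = 2, n_utt = 3, grammar = tdu_grammar(2))
  for (u in co$utterances) {
    seg <- u$segments
    expect_equal(seg$start[1], 0)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    # sum of per-segment frame counts equals N
    n_by_seg <- round((seg$end - seg$start) / 0.0075)
    expect_equal(sum(n_by_seg), nrow(u$frames$values))
    expect_true(all(u$frames$frame_times < seg$end[nrow(seg)]))
  }
})

test_that("the class effect lands on the targeted manner class only", {
  # speaker variability off isolates the generator's effect parameter
  sp <- sim_spec(n_speakers_per_class = 20, utterances_per_speaker = 12,
                 segment_grammar = tdu_grammar(8),
                 class_effect = list(plosive = list(mean_shift = 1.0)),
                 dim = 6, speaker_sd = 0, seed = 55)
  co <- generate_corpus(sp)
  frames_of <- function(target, cls) {
    st <- group_corpus(co, target)
    keep <- vapply(st, function(r) r$class == cls, TRUE)
    do.call(rbind, lapply(st[keep], function(r) r$frames$values))
  }
  pl_pd <- frames_of("plosive", "PD"); pl_ct <- frames_of("plosive", "Ctrl")
  expect_gt(nrow(pl_pd), 1e4)
  diff_pl <- mean(pl_pd[, 1]) - mean(pl_ct[, 1])
  expect_equal(diff_pl, 1.0, tolerance = 0.05)
  # untouched dimensions and untouched classes stay at zero
  expect_lt(max(abs(colMeans(pl_pd)[-1] - colMeans(pl_ct)[-1])), 0.05)
  vw_pd <- frames_of("vowel", "PD"); vw_ct <- frames_of("vowel", "Ctrl")
  expect_lt(max(abs(colMeans(vw_pd) - colMeans(vw_ct))), 0.05)
})

test_that("a null corpus has identically distributed classes", {
  sp <- sim_spec(n_speakers_per_class = 8, utterances_per_speaker = 4,
                 dim = 4, speaker_sd = 0, seed = 90)
  co <- generate_corpus(sp)
  pool <- function(cls) do.call(rbind, lapply(
    Filter(function(u) u$class == cls, co$utterances),
    function(u) u$frames$values))
  d <- abs(colMeans(pool("PD")) - colMeans(pool("Ctrl")))
  expect_lt(max(d), 0.1)
})

test_that("waveform mode synthesizes audio the front-end can consume", {
  sp <- sim_spec(n_speakers_per_class = 1, utterances_per_speaker = 1,
                 segment_grammar = ddk_grammar(3), seed = 19,
                 mode = "waveform")
  co <- generate_corpus(sp)
  u <- co$utterances[[1]]
  expect_equal(length(u$wave) / 16000, u$segments$end[nrow(u$segments)],
               tolerance = 1e-9)
  expect_true(all(is.finite(u$frames$values)))
  expect_equal(ncol(u$frames$values), 30)      # 3 x F at F = 10
  # alignment round-trips against the front-end frame clock
  sel <- select_frames(u$frames, u$segments, "vowel")
  expect_gt(nrow(sel$frames$values), 0)
})

test_that("the TextGrid writer emits one labelled interval per segment", {
  co <- tiny_corpus(seed = 23, n_spk = 1, n_utt = 1, grammar = ddk_grammar(1))
  u <- co$utterances[[1]]
  dir <- withr::local_tempdir()
  p <- write_alignments(co, "TextGrid", dir)
  txt <- readLines(p[1])
  expect_equal(sum(grepl("intervals \\[", txt)), nrow(u$segments))
  expect_equal(sum(grepl("text =", txt)), nrow(u$segments))
})
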