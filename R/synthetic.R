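#' Segment grammars for synthetic utterances
#'
#' \code{ddk_grammar} mimics a diadochokinetic "pa-ta-ka" repetition task:
#' alternating plosive (30-60 ms) and vowel (80-150 ms) segments.
#' \code{tdu_grammar} mimics read-sentence material by inserting
#' fricative, nasal and liquid segments into the cycle.
#'
#' @param n_cycles Number of repetitions of the basic cycle.
#' @return Data frame with columns \code{manner}, \code{min_dur},
#'   \code{max_dur} (seconds), one row per segment of an utterance.
#' @export
ddk_grammar <- function(n_cycles = 6L) {
  cyc <- data.frame(manner = c("plosive", "vowel"),
                    min_dur = c(0.030, 0.080),
                    max_dur = c(0.060, 0.150), stringsAsFactors = FALSE)
  out <- cyc[rep(seq_len(nrow(cyc)), n_cycles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname ddk_grammar
#' @export
tdu_grammar <- function(n_cycles = 3L) {
  cyc <- data.frame(
    manner = c("plosive", "vowel", "fricative", "vowel", "nasal",
               "vowel", "liquid", "vowel"),
    min_dur = c(0.030, 0.080, 0.060, 0.080, 0.050, 0.080, 0.050, 0.080),
    max_dur = c(0.060, 0.150, 0.120, 0.150, 0.100, 0.150, 0.100, 0.150),
    stringsAsFactors = FALSE)
  out <- cyc[rep(seq_len(nrow(cyc)), n_cycles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Specification of a synthetic two-class corpus
#'
#' Describes a seeded corpus of PD and control speakers whose utterances
#' are concatenations of manner-labelled segments. In \code{feature} mode
#' each segment emits diagonal-Gaussian feature frames directly (one
#' frame per 7.5 ms hop), bypassing the DSP front-end; in
#' \code{waveform} mode each segment is synthesized as 16 kHz audio
#' (formant-like pulse trains for vowels and sonorants, shaped noise for
#' fricatives, closure-plus-burst for plosives) to exercise the front-end
#' end to end.
#'
#' The patient effect is confined to the manner classes named in
#' \code{class_effect}: in feature mode the class mean of PD speakers is
#' shifted by \code{mean_shift} feature standard deviations along the
#' first feature dimension and the emission variance is multiplied by
#' \code{var_scale}; in waveform mode \code{mean_shift} controls the
#' amplitude of frication noise injected into the segment (a
#' spirantization-like degradation).
#'
#' @param n_speakers_per_class Speakers per class.
#' @param utterances_per_speaker Utterances per speaker.
#' @param segment_grammar Ordered segment template, e.g. [ddk_grammar()].
#' @param class_effect Named list, manner class ->
#'   \code{list(mean_shift =, var_scale =)}; empty list for a null
#'   corpus.
#' @param dim Feature dimension in feature mode.
#' @param emission_means Optional named list, manner class -> base mean
#'   vector of length \code{dim}. By default a fixed, seed-independent
#'   set of class means is used, so corpora generated with different
#'   seeds are draws from the same population (as required for
#'   cross-corpora experiments); the seed only drives sampling.
#' @param speaker_sd Standard deviation of the per-speaker random offset
#'   (inter-speaker variability), in feature std units.
#' @param seed Integer seed; fully determines the corpus.
#' @param mode \code{"feature"} or \code{"waveform"}.
#' @param sample_rate Sample rate in waveform mode; must be 16000.
#' @return An object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_speakers_per_class = 20L, utterances_per_speaker = 5L,
                     segment_grammar = ddk_grammar(),
                     class_effect = list(), dim = 10L,
                     emission_means = NULL, speaker_sd = 0.2,
                     seed = 1L, mode = c("feature", "waveform"),
                     sample_rate = 16000L) {
  mode <- match.arg(mode)
  if (nrow(segment_grammar) == 0L) stop("empty segment grammar")
  if (any(segment_grammar$min_dur <= 0) ||
      any(segment_grammar$max_dur < segment_grammar$min_dur))
    stop("segment durations must be positive with min_dur <= max_dur")
  if (mode == "waveform" && sample_rate != 16000L)
    stop("waveform mode requires sample_rate = 16000")
  for (eff in class_effect) {
    if (!is.null(eff$var_scale) && eff$var_scale <= 0)
      stop("variance scale must be positive")
  }
  if (!all(names(class_effect) %in% manner_classes()))
    stop("class_effect names must be manner classes")
  if (is.null(emission_means)) {
    emission_means <- default_emission_means(as.integer(dim))
  } else {
    if (!all(vapply(emission_means, length, 1L) == dim))
      stop("emission_means vectors must have length dim")
  }
  structure(list(n_speakers_per_class = as.integer(n_speakers_per_class),
                 utterances_per_speaker = as.integer(utterances_per_speaker),
                 segment_grammar = segment_grammar,
                 class_effect = class_effect, dim = as.integer(dim),
                 emission_means = emission_means,
                 speaker_sd = speaker_sd, seed = as.integer(seed),
                 mode = mode, sample_rate = as.integer(sample_rate)),
            class = "sim_spec")
}

# fixed, seed-independent class means: distinct deterministic directions
# with ~1.5 sigma spread, one per manner class
default_emission_means <- function(dim) {
  out <- list()
  cls <- manner_classes()
  for (c_idx in seq_along(cls))
    out[[cls[c_idx]]] <- 1.5 * cos(c_idx * seq_len(dim) + c_idx)
  out
}

# example phone labels per manner class, drawn per segment
.sim_labels <- list(
  plosive = c("p", "t", "k"), vowel = c("a", "e", "o"),
  fricative = c("f", "s", "x"), nasal = c("m", "n"),
  liquid = c("l", "r"), affricate = "t\u0283", other = "sil")

#' Generate a synthetic corpus
#'
#' Draws the corpus described by a [sim_spec()]: one RNG stream, seeded
#' by \code{spec$seed} and consumed in a fixed order (speakers, then
#' utterances, then segments), so an identical spec always yields an
#' identical corpus. Segment durations are drawn uniformly within their
#' grammar range and snapped to the 7.5 ms frame grid, so the alignment
#' intervals exactly tile each utterance.
#'
#' @param spec A [sim_spec()].
#' @return An object of class \code{sim_corpus}: \code{utterances} (list
#'   of records with \code{speaker_id}, \code{class}, \code{utterance_id},
#'   \code{frames} or \code{wave}, \code{segments}), \code{manifest}
#'   (data frame), \code{truth} (ground-truth emission parameters) and
#'   \code{spec}.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  hop <- 0.0075

  with_local_seed(spec$seed, {
    base_means <- spec$emission_means
    utterances <- list()
    manifest <- NULL
    for (cls in c("PD", "Ctrl")) {
      for (s in seq_len(spec$n_speakers_per_class)) {
        spk <- sprintf("%s_%02d", cls, s)
        offset <- stats::rnorm(spec$dim, sd = spec$speaker_sd)
        for (u in seq_len(spec$utterances_per_speaker)) {
          utt_id <- sprintf("%s_u%02d", spk, u)
          rec <- sim_utterance(spec, cls, offset, base_means, hop)
          rec$speaker_id <- spk
          rec$class <- cls
          rec$utterance_id <- utt_id
          rec$frames$utterance_id <- utt_id
          utterances[[utt_id]] <- rec
          manifest <- rbind(manifest, data.frame(
            speaker_id = spk, class = cls, utterance_id = utt_id,
            n_frames = nrow(rec$frames$values),
            duration = rec$segments$end[nrow(rec$segments)],
            stringsAsFactors = FALSE))
        }
      }
    }
    structure(list(utterances = utterances, manifest = manifest,
                   truth = list(base_means = base_means,
                                class_effect = spec$class_effect,
                                speaker_sd = spec$speaker_sd),
                   spec = spec),
              class = "sim_corpus")
  })
}

# one utterance: draw durations, then emissions segment by segment
sim_utterance <- function(spec, cls, offset, base_means, hop) {
  gr <- spec$segment_grammar
  durs <- stats::runif(nrow(gr), gr$min_dur, gr$max_dur)
  n_frames_seg <- pmax(1L, as.integer(round(durs / hop)))
  ends <- cumsum(n_frames_seg) * hop
  starts <- c(0, ends[-length(ends)])
  labels <- vapply(gr$manner, function(m) {
    lab <- .sim_labels[[m]]
    if (length(lab) == 1L) lab else sample(lab, 1L)
  }, "")
  segments <- data.frame(label = labels, start = starts, end = ends,
                         manner = gr$manner, stringsAsFactors = FALSE)

  if (spec$mode == "feature") {
    vals <- vector("list", nrow(gr))
    for (i in seq_len(nrow(gr))) {
      m <- gr$manner[i]
      mu <- base_means[[m]] + offset
      sdv <- rep(1, spec$dim)
      eff <- spec$class_effect[[m]]
      if (cls == "PD" && !is.null(eff)) {
        mu[1L] <- mu[1L] + (eff$mean_shift %||% 0)
        sdv <- sdv * sqrt(eff$var_scale %||% 1)
      }
      k <- n_frames_seg[i]
      vals[[i]] <- matrix(stats::rnorm(k * spec$dim), k) *
        rep(sdv, each = k) + rep(mu, each = k)
    }
    vals <- do.call(rbind, vals)
    times <- (seq_len(nrow(vals)) - 0.5) * hop
    list(frames = frame_matrix(vals, times), segments = segments)
  } else {
    sr <- spec$sample_rate
    waves <- vector("list", nrow(gr))
    for (i in seq_len(nrow(gr))) {
      m <- gr$manner[i]
      n <- n_frames_seg[i] * as.integer(hop * sr)
      eff <- if (cls == "PD") spec$class_effect[[m]] else NULL
      waves[[i]] <- sim_segment_wave(m, n, sr,
                                     frication = eff$mean_shift %||% 0,
                                     jitter_scale = eff$var_scale %||% 1)
    }
    wave <- unlist(waves, use.names = FALSE)
    fr <- extract_rasta_plp(load_and_normalize(wave, sample_rate = sr),
                            frontend_config(F = 10L))
    list(frames = fr, segments = segments, wave = wave, sample_rate = sr)
  }
}

# crude source-filter segment templates; enough spectral contrast for the
# front-end, no attempt at natural speech
sim_segment_wave <- function(manner, n, sr, frication = 0, jitter_scale = 1) {
  t <- seq_len(n) / sr
  jit <- jitter_scale
  base <- switch(manner,
    vowel = 0.6 * sin(2 * pi * 120 * t) + 0.3 * sin(2 * pi * 700 * t) +
      0.15 * sin(2 * pi * 1200 * t),
    nasal = 0.4 * sin(2 * pi * 120 * t) + 0.2 * sin(2 * pi * 250 * t),
    liquid = 0.4 * sin(2 * pi * 120 * t) + 0.25 * sin(2 * pi * 400 * t) +
      0.1 * sin(2 * pi * 800 * t),
    fricative = c(0, diff(stats::rnorm(n))) * 0.3,       # high-pass noise
    affricate = {
      nc <- floor(n / 3)
      c(numeric(nc), c(0, diff(stats::rnorm(n - nc))) * 0.3)
    },
    plosive = {
      nc <- floor(0.7 * n)                                # closure
      burst <- stats::rnorm(n - nc) * exp(-8 * seq_len(n - nc) / (n - nc))
      c(numeric(nc), 0.5 * burst)
    },
    numeric(n))                                           # silence/other
  base <- base * (1 + 0.02 * (jit - 1) * stats::rnorm(1))
  if (frication > 0)
    base <- base + 0.05 * frication * c(0, diff(stats::rnorm(n)))
  base
}

#' @export
print.sim_corpus <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<sim_corpus> %d utterances, %d speakers (%d PD / %d Ctrl), mode = %s\n",
              nrow(m), length(unique(m$speaker_id)),
              length(unique(m$speaker_id[m$class == "PD"])),
              length(unique(m$speaker_id[m$class == "Ctrl"])),
              x$spec$mode))
  invisible(x)
}

#' Write alignment files for a synthetic corpus
#'
#' Writes one alignment file per utterance: a Praat TextGrid with a
#' single interval tier \code{phones}, or a CTM file with one
#' \code{utt channel start dur label} line per segment. Times are printed
#' to nanosecond precision so the files round-trip through
#' [read_alignment()] losslessly.
#'
#' @param corpus A \code{sim_corpus}.
#' @param format \code{"TextGrid"} or \code{"CTM"}.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_alignments <- function(corpus, format = c("TextGrid", "CTM"), out_dir) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (u in corpus$utterances) {
    seg <- u$segments
    if (format == "TextGrid") {
      path <- file.path(out_dir, paste0(u$utterance_id, ".TextGrid"))
      xmax <- seg$end[nrow(seg)]
      lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
                 "xmin = 0", sprintf("xmax = %.9f", xmax),
                 "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
                 '        class = "IntervalTier"', '        name = "phones"',
                 "        xmin = 0", sprintf("        xmax = %.9f", xmax),
                 sprintf("        intervals: size = %d", nrow(seg)))
      for (i in seq_len(nrow(seg))) {
        lines <- c(lines,
                   sprintf("        intervals [%d]:", i),
                   sprintf("            xmin = %.9f", seg$start[i]),
                   sprintf("            xmax = %.9f", seg$end[i]),
                   sprintf('            text = "%s"', seg$label[i]))
      }
    } else {
      path <- file.path(out_dir, paste0(u$utterance_id, ".ctm"))
      lines <- sprintf("%s 1 %.9f %.9f %s", u$utterance_id, seg$start,
                       seg$end - seg$start, seg$label)
    }
    writeLines(lines, path, useBytes = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the speaker manifest of a corpus as CSV
#'
#' @param corpus A \code{sim_corpus}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_corpus_manifest <- function(corpus, path) {
  utils::write.csv(corpus$manifest, path, row.names = FALSE)
  invisible(path)
}
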