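#' Speaker-disjoint, class-stratified fold assignment
#'
#' Partitions speakers into k folds for cross-validation: speakers are
#' shuffled within each class (seeded) and dealt round-robin, so fold
#' sizes are balanced and every speaker appears in exactly one test fold.
#'
#' @param speakers Data frame with \code{speaker_id} and \code{class}
#'   columns (one row per speaker).
#' @param n_folds Number of folds (default 11).
#' @param seed Shuffle seed.
#' @return The input data frame with a \code{fold} column (1..n_folds).
#' @export
make_folds <- function(speakers, n_folds = 11L, seed = 1L) {
  speakers <- unique(speakers[, c("speaker_id", "class")])
  if (nrow(speakers) < n_folds)
    stop("fewer speakers (", nrow(speakers), ") than folds (", n_folds, ")")
  speakers$fold <- NA_integer_
  with_local_seed(seed, {
    for (cls in unique(speakers$class)) {
      idx <- which(speakers$class == cls)
      idx <- idx[sample.int(length(idx))]
      speakers$fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  rownames(speakers) <- NULL
  speakers
}

grouping_sides <- function(approach) {
  # which side of the experiment the phonemic grouping is applied to
  switch(approach,
         baseline  = c(ubm = FALSE, adapt = FALSE),
         raw_phon  = c(ubm = FALSE, adapt = TRUE),
         phon_phon = c(ubm = TRUE,  adapt = TRUE),
         phon_raw  = c(ubm = TRUE,  adapt = FALSE),
         stop("unknown approach: ", approach))
}

corpus_records <- function(corpus, grouping = NULL) {
  utts <- if (inherits(corpus, "sim_corpus")) corpus$utterances else corpus
  if (is.null(grouping)) return(unname(utts))
  unname(group_corpus(utts, grouping))
}

pool_frames <- function(records) {
  do.call(rbind, lapply(records, function(u) u$frames$values))
}

#' Run one detection experiment under speaker-disjoint cross-validation
#'
#' Orchestrates one cell of the experimental design for a given approach:
#' \describe{
#'   \item{baseline}{no phonemic grouping anywhere;}
#'   \item{raw_phon}{grouping applied to the adaptation/testing corpus
#'     only;}
#'   \item{phon_phon}{grouping applied to both the UBM corpus and the
#'     adaptation/testing corpus;}
#'   \item{phon_raw}{grouping applied to the UBM corpus only — every test
#'     frame is scored, no acoustic segment of the adaptation-testing
#'     corpus is discarded.}
#' }
#' The UBM is trained once on the (optionally grouped) background corpus;
#' in each of the k folds the PD and control models are MAP-adapted on
#' the training speakers, the decision threshold is calibrated at the
#' equal-error-rate point of the training-fold scores, and the held-out
#' speakers are scored. Decisions are pooled over folds into a single
#' confusion matrix. No speaker contributes to both adaptation and test
#' of the same fold.
#'
#' @param adapt_corpus The adaptation/testing corpus (a
#'   \code{sim_corpus} or list of utterance records with alignments).
#' @param ubm_corpus The background corpus used to train the UBM.
#' @param approach One of \code{"baseline"}, \code{"raw_phon"},
#'   \code{"phon_phon"}, \code{"phon_raw"}.
#' @param grouping Manner class for the phonemic grouping (required
#'   except for the baseline).
#' @param G Number of UBM components.
#' @param config A [map_config()].
#' @param n_folds,fold_seed Cross-validation folds and shuffle seed.
#' @param F Static-coefficient count carried as metadata (feature-mode
#'   corpora fix the dimension directly).
#' @param task Task label carried as metadata.
#' @return Object of class \code{pd_eval}: \code{speaker_metrics} and
#'   \code{utterance_metrics} (one-row [compute_metrics()] frames),
#'   \code{speaker_records}, \code{utterance_records}, \code{folds},
#'   \code{n_unscorable}.
#' @export
run_approach <- function(adapt_corpus, ubm_corpus,
                         approach = c("baseline", "raw_phon", "phon_phon",
                                      "phon_raw"),
                         grouping = NULL, G = 8L, config = map_config(),
                         n_folds = 11L, fold_seed = 1L, F = NA_integer_,
                         task = NA_character_) {
  approach <- match.arg(approach)
  sides <- grouping_sides(approach)
  if (approach == "baseline") {
    if (!is.null(grouping)) stop("baseline uses no grouping")
  } else if (is.null(grouping)) {
    stop(approach, " requires a grouping class")
  }

  ubm_records <- corpus_records(ubm_corpus,
                                if (sides[["ubm"]]) grouping else NULL)
  ubm <- fit_gmm(pool_frames(ubm_records), G, config,
                 meta = list(grouping = if (sides[["ubm"]]) grouping,
                             approach = approach))

  adapt_grouping <- if (sides[["adapt"]]) grouping else NULL
  records <- corpus_records(adapt_corpus, adapt_grouping)
  speakers <- unique(data.frame(
    speaker_id = vapply(records, `[[`, "", "speaker_id"),
    class = vapply(records, `[[`, "", "class"), stringsAsFactors = FALSE))
  folds <- make_folds(speakers, n_folds, fold_seed)

  meta <- list(approach = approach,
               grouping = grouping %||% "none", F = F, G = as.integer(G),
               task = task)
  utt_rec <- NULL
  spk_rec <- NULL
  for (k in seq_len(n_folds)) {
    test_spk <- folds$speaker_id[folds$fold == k]
    spk_of <- vapply(records, `[[`, "", "speaker_id")
    train <- records[!(spk_of %in% test_spk)]
    test <- records[spk_of %in% test_spk]
    stopifnot(length(intersect(
      vapply(train, `[[`, "", "speaker_id"),
      vapply(test, `[[`, "", "speaker_id"))) == 0L)   # speaker disjointness

    fit <- gmm_ubm(train, ubm, config, meta = meta)
    u <- predict(fit, test, level = "utterance")
    s <- predict(fit, test, level = "speaker")
    u$fold <- k
    s$fold <- k
    utt_rec <- rbind(utt_rec, u)
    spk_rec <- rbind(spk_rec, s)
  }

  u_ok <- utt_rec[utt_rec$scorable, , drop = FALSE]
  structure(list(
    speaker_metrics = compute_metrics(spk_rec$true_class, spk_rec$decision,
                                      spk_rec$score, meta),
    utterance_metrics = compute_metrics(u_ok$true_class, u_ok$decision,
                                        u_ok$llr, meta),
    speaker_records = spk_rec, utterance_records = utt_rec,
    folds = folds, n_unscorable = sum(!utt_rec$scorable), meta = meta),
    class = "pd_eval")
}

#' @export
print.pd_eval <- function(x, ...) {
  m <- x$speaker_metrics
  cat(sprintf("<pd_eval> %s / %s (G = %d): accuracy %.1f%% +/- %.1f, AUC %.3f, sens %.2f, spec %.2f (%d speakers)\n",
              x$meta$approach, x$meta$grouping, x$meta$G, m$accuracy,
              m$ci_halfwidth, m$auc, m$sensitivity, m$specificity, m$n_test))
  invisible(x)
}

#' Cross-corpora validation: adapt on two corpora, test on the third
#'
#' For each round, two corpora are pooled to MAP-adapt the class models
#' (and to calibrate the threshold); the held-out corpus is used
#' exclusively for testing. Only the baseline and the phon_raw approach
#' apply, since the test side is never grouped.
#'
#' @param corpora Named list of at least three corpora with compatible
#'   feature dimensions.
#' @param ubm_corpus Background corpus for the UBM.
#' @param approach \code{"baseline"} or \code{"phon_raw"}.
#' @param grouping Manner class for the UBM grouping (phon_raw).
#' @param G,config,F,task As in [run_approach()].
#' @return Data frame with one [compute_metrics()] row per round
#'   (column \code{test_corpus} identifies the round), speaker level.
#' @export
run_cross_corpora <- function(corpora, ubm_corpus,
                              approach = c("baseline", "phon_raw"),
                              grouping = NULL, G = 8L,
                              config = map_config(), F = NA_integer_,
                              task = NA_character_) {
  approach <- match.arg(approach)
  if (length(corpora) < 3L) stop("cross-corpora validation needs >= 3 corpora")
  if (is.null(names(corpora)))
    names(corpora) <- paste0("corpus", seq_along(corpora))
  sides <- grouping_sides(approach)
  if (approach == "phon_raw" && is.null(grouping))
    stop("phon_raw requires a grouping class")

  ubm_records <- corpus_records(ubm_corpus,
                                if (sides[["ubm"]]) grouping else NULL)
  ubm <- fit_gmm(pool_frames(ubm_records), G, config)

  out <- NULL
  for (test_name in names(corpora)) {
    train <- unlist(lapply(corpora[setdiff(names(corpora), test_name)],
                           corpus_records), recursive = FALSE)
    test <- corpus_records(corpora[[test_name]])
    stopifnot(length(intersect(
      vapply(train, `[[`, "", "speaker_id"),
      vapply(test, `[[`, "", "speaker_id"))) == 0L)

    meta <- list(approach = approach, grouping = grouping %||% "none",
                 F = F, G = as.integer(G), task = task,
                 test_corpus = test_name)
    fit <- gmm_ubm(unname(train), ubm, config, meta = meta)
    s <- predict(fit, test, level = "speaker")
    out <- rbind(out, compute_metrics(s$true_class, s$decision, s$score,
                                      meta))
  }
  rownames(out) <- NULL
  out
}

#' Run one approach over a grid of model sizes
#'
#' @param adapt_corpus,ubm_corpus,approach,grouping,config,n_folds,fold_seed,F,task
#'   As in [run_approach()].
#' @param G_grid Numbers of Gaussians to evaluate (the standard grid is
#'   the powers of two from 4 to 256).
#' @return Data frame of speaker-level metric rows, one per G.
#' @export
run_grid <- function(adapt_corpus, ubm_corpus, approach, grouping = NULL,
                     G_grid = 2^(2:8), config = map_config(),
                     n_folds = 11L, fold_seed = 1L, F = NA_integer_,
                     task = NA_character_) {
  rows <- lapply(G_grid, function(G) {
    run_approach(adapt_corpus, ubm_corpus, approach, grouping, G, config,
                 n_folds, fold_seed, F, task)$speaker_metrics
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best grid cell
#'
#' Picks the best-performing cell of a results table by accuracy, with
#' ties broken by higher AUC, then smaller G, then smaller F (parsimony).
#'
#' @param results Data frame of metric rows with columns \code{accuracy},
#'   \code{auc}, \code{G} and optionally \code{F}.
#' @return The selected row.
#' @export
select_best <- function(results) {
  if (nrow(results) == 0L) stop("empty results")
  Fcol <- if ("F" %in% names(results)) results$F else rep(0, nrow(results))
  Fcol[is.na(Fcol)] <- 0
  ord <- order(-results$accuracy, -results$auc, results$G, Fcol)
  results[ord[1L], , drop = FALSE]
}
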