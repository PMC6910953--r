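#' Score one utterance against the PD and control models
#'
#' Computes the average per-frame log-likelihood of the utterance under
#' each class model,
#' \deqn{\Lambda_u^c = \frac{1}{N} \sum_{n=1}^{N} \log p(x_n \mid \Gamma^c),}
#' and the log-likelihood ratio \eqn{\Lambda_u = \Lambda_u^{PD} -
#' \Lambda_u^{Ctrl}}. An utterance left with zero frames (possible after
#' phonemic grouping) is flagged unscorable rather than scored; the
#' evaluation stage excludes and counts such utterances.
#'
#' @param frames Utterance frames (matrix or [frame_matrix()]).
#' @param model_pd,model_ctrl MAP-adapted \code{diag_gmm} class models.
#' @param utterance_id,speaker_id,true_class,grouping,F,G Provenance
#'   carried into the record.
#' @return A one-row data frame (\code{score_record}) with columns
#'   \code{utterance_id}, \code{speaker_id}, \code{true_class},
#'   \code{lambda_pd}, \code{lambda_ctrl}, \code{llr}, \code{grouping},
#'   \code{F}, \code{G}, \code{n_frames_scored}, \code{scorable}.
#' @export
score_utterance <- function(frames, model_pd, model_ctrl,
                            utterance_id = NA_character_,
                            speaker_id = NA_character_,
                            true_class = NA_character_,
                            grouping = NA_character_,
                            F = NA_integer_, G = NA_integer_) {
  x <- frames_as_matrix(frames)
  n <- nrow(x)
  if (n == 0L) {
    return(data.frame(utterance_id = utterance_id, speaker_id = speaker_id,
                      true_class = true_class, lambda_pd = NA_real_,
                      lambda_ctrl = NA_real_, llr = NA_real_,
                      grouping = grouping, F = F, G = G,
                      n_frames_scored = 0L, scorable = FALSE,
                      stringsAsFactors = FALSE))
  }
  l_pd <- mean(gmm_log_density(model_pd, x))
  l_ctrl <- mean(gmm_log_density(model_ctrl, x))
  data.frame(utterance_id = utterance_id, speaker_id = speaker_id,
             true_class = true_class, lambda_pd = l_pd,
             lambda_ctrl = l_ctrl, llr = l_pd - l_ctrl,
             grouping = grouping, F = F, G = G,
             n_frames_scored = n, scorable = TRUE, stringsAsFactors = FALSE)
}

#' Calibrate the decision threshold at the equal-error-rate point
#'
#' Sweeps the decision threshold over the calibration scores and returns
#' the \eqn{\lambda} at which the false-positive rate (controls accepted
#' as PD) equals the false-negative rate (PD rejected). The decision rule
#' is strict: a score counts as PD only when it is higher than
#' \eqn{\lambda}. When no exact crossing exists, \eqn{\lambda} is the
#' midpoint of the score interval minimizing \eqn{|FPR - FNR|} and the
#' EER is \eqn{(FPR + FNR) / 2} there; ties between intervals are broken
#' toward the smaller EER, then the lower threshold.
#'
#' @param scores Numeric scores (\eqn{\Lambda_u}), or a data frame with
#'   columns \code{llr} and \code{true_class}.
#' @param true_class Class labels (\code{"PD"} / \code{"Ctrl"}) when
#'   \code{scores} is numeric.
#' @return A list of class \code{decision_threshold}: \code{lambda},
#'   \code{eer}, \code{fpr}, \code{fnr}, \code{source}.
#' @export
eer_threshold <- function(scores, true_class = NULL) {
  if (is.data.frame(scores)) {
    true_class <- scores$true_class
    scores <- scores$llr
  }
  keep <- is.finite(scores)
  scores <- scores[keep]; true_class <- true_class[keep]
  if (!all(c("PD", "Ctrl") %in% true_class))
    stop("calibration scores must contain both classes")
  pd <- scores[true_class == "PD"]
  ctrl <- scores[true_class == "Ctrl"]

  s <- sort(unique(scores))
  # candidate thresholds: one per constant piece of the step functions,
  # [s_i, s_{i+1}), plus a piece below the smallest score
  cand_rep <- c(s[1L] - 1, s)
  cand_mid <- c(s[1L] - 1, (c(s[-1L], s[length(s)] + 2) + s) / 2)
  fpr <- vapply(cand_rep, function(l) mean(ctrl > l), 1)
  fnr <- vapply(cand_rep, function(l) mean(pd <= l), 1)
  gap <- abs(fpr - fnr)
  eer <- (fpr + fnr) / 2
  best <- which(gap <= min(gap) + 1e-12)
  best <- best[order(eer[best], cand_mid[best])][1L]
  structure(list(lambda = cand_mid[best], eer = eer[best],
                 fpr = fpr[best], fnr = fnr[best],
                 source = sprintf("%d PD / %d Ctrl calibration scores",
                                  length(pd), length(ctrl))),
            class = "decision_threshold")
}

#' @export
print.decision_threshold <- function(x, ...) {
  cat(sprintf("<decision_threshold> lambda = %.6g, EER = %.3f (%s)\n",
              x$lambda, x$eer, x$source))
  invisible(x)
}

#' Accept or reject the PD hypothesis for a score
#'
#' A score strictly higher than the threshold accepts the PD hypothesis;
#' a score at or below it is classed as control (ties go to control, per
#' the strict inequality of the decision rule).
#'
#' @param score Numeric score(s) \eqn{\Lambda_u}, or a
#'   \code{score_record} data frame with an \code{llr} column.
#' @param threshold A [eer_threshold()] result or a numeric \eqn{\lambda}.
#' @return Character vector of \code{"PD"} / \code{"Ctrl"}.
#' @export
decide <- function(score, threshold) {
  if (is.data.frame(score)) score <- score$llr
  lambda <- if (inherits(threshold, "decision_threshold"))
    threshold$lambda else threshold
  ifelse(score > lambda, "PD", "Ctrl")
}

#' Aggregate utterance scores into a speaker score
#'
#' The speaker score of one (speaker, grouping, F, G) cell is the mean of
#' that speaker's scorable per-utterance log-likelihood ratios; speakers
#' with no scorable utterance are dropped (and reported via the
#' \code{n_dropped} attribute).
#'
#' @param records A \code{score_record} data frame (multiple speakers
#'   allowed).
#' @return Data frame with one row per speaker: \code{speaker_id},
#'   \code{true_class}, \code{score}, \code{n_utterances}.
#' @export
speaker_score <- function(records) {
  rec <- records[records$scorable, , drop = FALSE]
  dropped <- setdiff(unique(records$speaker_id), unique(rec$speaker_id))
  sp <- split(rec, rec$speaker_id)
  out <- do.call(rbind, lapply(sp, function(r) {
    data.frame(speaker_id = r$speaker_id[1L], true_class = r$true_class[1L],
               score = mean(r$llr), n_utterances = nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}
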