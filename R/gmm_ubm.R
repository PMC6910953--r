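#' Fit a GMM-UBM detector for parkinsonian speech
#'
#' The core estimator of the package: from a universal background model
#' and a set of labelled training utterances it MAP-adapts one mixture
#' per class (PD and control), scores the training utterances with the
#' log-likelihood ratio of average per-frame log-likelihoods, and
#' calibrates the decision threshold at the equal-error-rate point of
#' those calibration scores — at the utterance level and, after averaging
#' each speaker's utterance scores, at the speaker level.
#'
#' @param utterances List of training records, each with \code{frames}
#'   (a [frame_matrix()]), \code{class} (\code{"PD"} / \code{"Ctrl"}),
#'   \code{speaker_id} and \code{utterance_id}.
#' @param ubm A \code{diag_gmm} background model (see [fit_gmm()]).
#' @param config A [map_config()].
#' @param meta Metadata (grouping, F, G, ...) stamped on score records.
#' @return An object of class \code{gmm_ubm} with components
#'   \code{model_pd}, \code{model_ctrl}, \code{threshold_utterance},
#'   \code{threshold_speaker}, \code{calibration} (the training score
#'   records) and \code{meta}.
#' @seealso [predict.gmm_ubm()], [map_adapt()], [eer_threshold()]
#' @export
gmm_ubm <- function(utterances, ubm, config = map_config(), meta = list()) {
  classes <- vapply(utterances, `[[`, "", "class")
  if (!all(c("PD", "Ctrl") %in% classes))
    stop("training utterances must contain both classes")
  pool <- function(cls) {
    do.call(rbind, lapply(utterances[classes == cls],
                          function(u) u$frames$values))
  }
  model_pd <- map_adapt(ubm, pool("PD"), config)
  model_ctrl <- map_adapt(ubm, pool("Ctrl"), config)

  fit <- structure(list(model_pd = model_pd, model_ctrl = model_ctrl,
                        ubm = ubm, config = config, meta = meta),
                   class = "gmm_ubm")
  cal <- score_records(fit, utterances)
  fit$calibration <- cal
  scorable <- cal[cal$scorable, , drop = FALSE]
  fit$threshold_utterance <- eer_threshold(scorable)
  spk <- speaker_score(cal)
  fit$threshold_speaker <- eer_threshold(spk$score, spk$true_class)
  fit
}

score_records <- function(fit, utterances) {
  do.call(rbind, lapply(utterances, function(u) {
    score_utterance(u$frames, fit$model_pd, fit$model_ctrl,
                    utterance_id = u$utterance_id,
                    speaker_id = u$speaker_id, true_class = u$class,
                    grouping = fit$meta$grouping %||% NA_character_,
                    F = fit$meta$F %||% NA_integer_,
                    G = length(fit$model_pd$weights))
  }))
}

#' Score and classify utterances with a fitted detector
#'
#' @param object A [gmm_ubm()] fit.
#' @param newdata List of utterance records (as in [gmm_ubm()]).
#' @param level \code{"speaker"} (default: utterance log-likelihood
#'   ratios averaged per speaker, thresholded with the speaker-level
#'   lambda) or \code{"utterance"}.
#' @param ... Unused.
#' @return Data frame of scores with a \code{decision} column; at
#'   utterance level, unscorable (zero-frame) utterances carry
#'   \code{NA} decisions and are flagged by \code{scorable = FALSE}.
#' @export
predict.gmm_ubm <- function(object, newdata,
                            level = c("speaker", "utterance"), ...) {
  level <- match.arg(level)
  rec <- score_records(object, newdata)
  if (level == "utterance") {
    rec$decision <- ifelse(rec$scorable,
                           decide(rec$llr, object$threshold_utterance),
                           NA_character_)
    return(rec)
  }
  spk <- speaker_score(rec)
  spk$decision <- decide(spk$score, object$threshold_speaker)
  spk
}

#' @export
print.gmm_ubm <- function(x, ...) {
  cat(sprintf("<gmm_ubm> G = %d, D = %d; lambda(utt) = %.4g (EER %.3f), lambda(spk) = %.4g (EER %.3f)\n",
              length(x$model_pd$weights), ncol(x$model_pd$means),
              x$threshold_utterance$lambda, x$threshold_utterance$eer,
              x$threshold_speaker$lambda, x$threshold_speaker$eer))
  invisible(x)
}

#' @export
summary.gmm_ubm <- function(object, ...) {
  print(object)
  cal <- object$calibration
  cat(sprintf("calibration: %d utterances (%d unscorable), %d speakers\n",
              nrow(cal), sum(!cal$scorable),
              length(unique(cal$speaker_id))))
  invisible(object)
}
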