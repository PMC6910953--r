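#' Fuse manner-grouping scores with logistic regression
#'
#' Combines k per-speaker scores (one per manner grouping in the tuple,
#' all produced with the same F and G) into a single score: a binary
#' logistic regression with a small fixed L2 (ridge) penalty is fit on
#' the training speakers by iteratively reweighted least squares, and the
#' fused score of a test speaker is the linear predictor (log-odds). The
#' ridge term (default 1e-4) only guards against separation and collinear
#' or constant components; it is not a tuning knob.
#'
#' @param train_scores Numeric matrix (speakers x k) of training score
#'   vectors.
#' @param train_class Training labels, \code{"PD"} / \code{"Ctrl"} (PD is
#'   the positive class).
#' @param test_scores Matrix of test score vectors with the same columns.
#' @param lambda_ridge Fixed L2 penalty strength.
#' @return List with \code{fused} (numeric, one log-odds score per test
#'   speaker), \code{coef} (intercept and weights) and
#'   \code{train_fused}.
#' @export
fuse_scores <- function(train_scores, train_class, test_scores,
                        lambda_ridge = 1e-4) {
  train_scores <- as.matrix(train_scores)
  test_scores <- as.matrix(test_scores)
  if (ncol(test_scores) != ncol(train_scores)) stop("tuple structure mismatch")
  y <- as.numeric(train_class == "PD")
  if (all(y == 1) || all(y == 0)) stop("training scores contain one class only")

  X <- cbind(1, train_scores)
  beta <- ridge_logistic(X, y, lambda_ridge)
  list(fused = as.numeric(cbind(1, test_scores) %*% beta),
       coef = as.numeric(beta),
       train_fused = as.numeric(X %*% beta))
}

# Ridge-penalized logistic regression by damped Newton / IRLS.
# The intercept is penalized too, which keeps the fit exactly
# antisymmetric under a label flip.
ridge_logistic <- function(X, y, lambda, max_iter = 200L, tol = 1e-12) {
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, y - mu) - lambda * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(lambda, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Evaluation metrics for one experiment cell
#'
#' Computes the reporting metrics for a set of per-speaker decisions and
#' scores, with PD as the positive class: accuracy in percent with a
#' 95 % Wald binomial confidence-interval halfwidth
#' \eqn{1.96 \sqrt{\hat p (1-\hat p)/n} \times 100}, the AUC as the
#' Mann-Whitney statistic of the scores (ties counted one half),
#' sensitivity \code{TP/(TP+FN)} and specificity \code{TN/(TN+FP)}.
#'
#' @param truth True classes (\code{"PD"} / \code{"Ctrl"}).
#' @param decision Decided classes, same coding.
#' @param score Numeric scores used for the AUC (higher = more PD-like).
#' @param meta Optional named list of cell metadata (approach, grouping,
#'   task, F, G) bound into the result row.
#' @return One-row data frame (\code{eval_result}): \code{accuracy},
#'   \code{ci_halfwidth} (both in percent), \code{auc},
#'   \code{sensitivity}, \code{specificity}, \code{n_test},
#'   \code{tp}, \code{fn}, \code{tn}, \code{fp}, plus any metadata.
#' @export
compute_metrics <- function(truth, decision, score, meta = list()) {
  stopifnot(length(truth) == length(decision),
            length(truth) == length(score))
  if (!all(c("PD", "Ctrl") %in% truth)) stop("both classes required")
  n <- length(truth)
  tp <- sum(truth == "PD" & decision == "PD")
  fn <- sum(truth == "PD" & decision == "Ctrl")
  tn <- sum(truth == "Ctrl" & decision == "Ctrl")
  fp <- sum(truth == "Ctrl" & decision == "PD")
  p_hat <- (tp + tn) / n
  out <- data.frame(
    accuracy = 100 * p_hat,
    ci_halfwidth = 100 * 1.96 * sqrt(p_hat * (1 - p_hat) / n),
    auc = auc_mann_whitney(score, truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    n_test = n, tp = tp, fn = fn, tn = tn, fp = fp,
    stringsAsFactors = FALSE)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  class(out) <- c("eval_result", "data.frame")
  out
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' @param score Numeric scores, higher indicating the positive class.
#' @param truth Labels; \code{positive} marks the positive class.
#' @param positive Positive label (default \code{"PD"}).
#' @return AUC in \code{[0, 1]}; tied score pairs count one half.
#' @export
auc_mann_whitney <- function(score, truth, positive = "PD") {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
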