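#' MAP / EM configuration
#'
#' Settings for UBM training and Reynolds-style MAP adaptation.
#'
#' @param relevance_factor Relevance factor r of the MAP interpolation
#'   (default 16, the standard speaker-verification value).
#' @param adapt Which parameter sets to adapt; any of \code{"means"},
#'   \code{"weights"}, \code{"variances"}. Means-only by default.
#' @param n_em_iters Maximum EM iterations for UBM training (default 25).
#' @param em_tol Relative log-likelihood change below which EM stops
#'   (default 1e-6).
#' @param init_seed Seed for the k-means++ initialization.
#' @param variance_floor_factor Per-dimension variance floor, as a
#'   fraction of the global variance of the training data (default 1e-3).
#' @return An object of class \code{map_config}.
#' @export
map_config <- function(relevance_factor = 16, adapt = "means",
                       n_em_iters = 25L, em_tol = 1e-6, init_seed = 1L,
                       variance_floor_factor = 1e-3) {
  stopifnot(relevance_factor > 0,
            all(adapt %in% c("means", "weights", "variances")))
  structure(list(relevance_factor = relevance_factor, adapt = adapt,
                 n_em_iters = as.integer(n_em_iters), em_tol = em_tol,
                 init_seed = as.integer(init_seed),
                 variance_floor_factor = variance_floor_factor),
            class = "map_config")
}

new_diag_gmm <- function(weights, means, variances, meta = list(),
                         loglik_trace = numeric(0)) {
  stopifnot(abs(sum(weights) - 1) < 1e-12,
            nrow(means) == length(weights),
            all(dim(means) == dim(variances)), all(variances > 0))
  structure(list(weights = weights, means = means, variances = variances,
                 meta = meta, loglik_trace = loglik_trace),
            class = "diag_gmm")
}

#' Fit a diagonal-covariance Gaussian mixture (UBM training)
#'
#' Maximum-likelihood EM for a G-component mixture of diagonal Gaussians,
#' used to train the universal background model on pooled background
#' frames. Initialization is seeded k-means++, so the fit is fully
#' deterministic given \code{config$init_seed}. Variances are floored at
#' \code{variance_floor_factor} times the global per-dimension variance;
#' the per-iteration total log-likelihood is stored in the returned
#' object's \code{loglik_trace} and is non-decreasing.
#'
#' @param x Numeric matrix of frames (rows) by feature dimensions, or a
#'   [frame_matrix()].
#' @param G Number of mixture components.
#' @param config A [map_config()].
#' @param meta Optional metadata list carried in the model (corpus,
#'   grouping, F, ...).
#' @return An object of class \code{diag_gmm}.
#' @export
fit_gmm <- function(x, G, config = map_config(), meta = list()) {
  x <- frames_as_matrix(x)
  n <- nrow(x); d <- ncol(x)
  G <- as.integer(G)
  if (n < G) stop("fewer rows (", n, ") than components (", G, ")")
  if (n < G * d) warning("fewer rows than G*D; estimates may be unstable")

  gvar <- apply(x, 2L, stats::var)
  if (n == 1L) gvar <- rep(1, d)
  floor_v <- pmax(config$variance_floor_factor * gvar, 1e-12)

  if (G == 1L) {
    v <- apply(x, 2L, function(col) mean((col - mean(col))^2))  # biased ML
    v <- pmax(v, floor_v)
    mdl <- new_diag_gmm(1, matrix(colMeans(x), 1L), matrix(v, 1L), meta)
    mdl$loglik_trace <- sum(gmm_log_density(mdl, x))
    return(mdl)
  }

  mu <- with_local_seed(config$init_seed, kmeanspp_centers(x, G))
  w <- rep(1 / G, G)
  sg <- matrix(rep(pmax(gvar, floor_v), each = G), G, d)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(config$n_em_iters)) {
    lp <- comp_log_dens(x, mu, sg) +
      matrix(log(w), n, G, byrow = TRUE)                 # n x G
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    gamma <- exp(lp - lse)                               # responsibilities
    ng <- colSums(gamma)
    ng <- pmax(ng, 1e-10)
    w <- ng / n
    mu <- (t(gamma) %*% x) / ng
    ex2 <- (t(gamma) %*% (x^2)) / ng
    sg <- pmax(ex2 - mu^2, rep(floor_v, each = G))
    if (is.finite(ll_old) && abs(ll - ll_old) <= config$em_tol * abs(ll_old))
      break
    ll_old <- ll
  }
  new_diag_gmm(w / sum(w), mu, sg, meta, ll_trace)
}

# k-means++ center seeding followed by a short Lloyd refinement.
kmeanspp_centers <- function(x, G) {
  n <- nrow(x)
  centers <- matrix(0, G, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (g in 2L:G) {
    if (sum(d2) <= 0) {
      # all remaining rows coincide with a chosen center: spread centers
      # deterministically so EM still has G distinct starting points
      centers[g, ] <- centers[1L, ] + 1e-6 * g
      next
    }
    idx <- sample.int(n, 1L, prob = d2 / sum(d2))
    centers[g, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[g, ])^2))
  }
  km <- tryCatch(suppressWarnings(stats::kmeans(x, centers, iter.max = 10L)),
                 error = function(e) NULL)
  if (is.null(km)) centers else km$centers
}

# n x G matrix of per-component diagonal Gaussian log densities.
comp_log_dens <- function(x, mu, sg) {
  n <- nrow(x); G <- nrow(mu)
  const <- -0.5 * (ncol(x) * log(2 * pi) + rowSums(log(sg)))  # length G
  quad <- x^2 %*% t(1 / sg) - 2 * (x %*% t(mu / sg)) +
    matrix(rowSums(mu^2 / sg), n, G, byrow = TRUE)
  -0.5 * quad + matrix(const, n, G, byrow = TRUE)
}

#' Mixture log-density of feature vectors
#'
#' Evaluates \code{log sum_g w_g N(x; mu_g, diag(sigma^2_g))} by
#' log-sum-exp, which stays finite for any finite input.
#'
#' @param model A \code{diag_gmm}.
#' @param x A D-vector, an N x D matrix, or a [frame_matrix()].
#' @return Numeric vector of per-row log densities.
#' @export
gmm_log_density <- function(model, x) {
  x <- frames_as_matrix(x)
  if (ncol(x) != ncol(model$means)) stop("dimension mismatch")
  lp <- comp_log_dens(x, model$means, model$variances) +
    matrix(log(model$weights), nrow(x), length(model$weights), byrow = TRUE)
  logsumexp_rows(lp)
}

#' MAP-adapt a UBM to class data
#'
#' Reynolds-style maximum-a-posteriori adaptation: component posteriors
#' \code{gamma_g(x_n)} are computed under the UBM, occupancies
#' \code{n_g = sum_n gamma_g(x_n)} give the data-dependent interpolation
#' weight \code{alpha_g = n_g / (n_g + r)}, and each adapted mean is
#' \code{alpha_g * E_g[x] + (1 - alpha_g) * mu_g}. Parameters not listed
#' in \code{config$adapt} are copied from the UBM; an empty frame set
#' returns the UBM unchanged.
#'
#' @param ubm A \code{diag_gmm} universal background model.
#' @param x Adaptation frames (matrix or [frame_matrix()]).
#' @param config A [map_config()]; \code{relevance_factor} controls the
#'   prior strength.
#' @return The adapted \code{diag_gmm}.
#' @export
map_adapt <- function(ubm, x, config = map_config()) {
  x <- frames_as_matrix(x)
  if (nrow(x) == 0L) return(ubm)
  if (ncol(x) != ncol(ubm$means)) stop("dimension mismatch")
  n <- nrow(x); G <- length(ubm$weights)
  r <- config$relevance_factor

  lp <- comp_log_dens(x, ubm$means, ubm$variances) +
    matrix(log(ubm$weights), n, G, byrow = TRUE)
  gamma <- exp(lp - logsumexp_rows(lp))
  ng <- colSums(gamma)
  alpha <- ng / (ng + r)
  safe_ng <- pmax(ng, 1e-300)

  out <- ubm
  ex <- (t(gamma) %*% x) / safe_ng
  if ("means" %in% config$adapt)
    out$means <- alpha * ex + (1 - alpha) * ubm$means
  if ("variances" %in% config$adapt) {
    ex2 <- (t(gamma) %*% (x^2)) / safe_ng
    v <- alpha * ex2 + (1 - alpha) * (ubm$variances + ubm$means^2) -
      out$means^2
    out$variances <- pmax(v, 1e-12)
  }
  if ("weights" %in% config$adapt) {
    w <- alpha * ng / n + (1 - alpha) * ubm$weights
    out$weights <- w / sum(w)
  }
  out$meta$adapted <- TRUE
  out
}

frames_as_matrix <- function(x) {
  if (inherits(x, "frame_matrix")) x$values
  else if (is.null(dim(x))) matrix(as.numeric(x), 1L)
  else as.matrix(x)
}

#' @export
print.diag_gmm <- function(x, ...) {
  cat(sprintf("<diag_gmm> G = %d components, D = %d dims%s\n",
              length(x$weights), ncol(x$means),
              if (isTRUE(x$meta$adapted)) " (MAP-adapted)" else ""))
  invisible(x)
}

#' @export
summary.diag_gmm <- function(object, ...) {
  cat(sprintf("Diagonal-covariance GMM: %d components, %d dimensions\n",
              length(object$weights), ncol(object$means)))
  cat("weights:", format(object$weights, digits = 3), "\n")
  if (length(object$loglik_trace))
    cat(sprintf("EM iterations: %d, final log-likelihood: %.4f\n",
                length(object$loglik_trace),
                object$loglik_trace[length(object$loglik_trace)]))
  invisible(object)
}

#' @export
logLik.diag_gmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (!length(object$loglik_trace)) stop("no stored training log-likelihood")
    return(object$loglik_trace[length(object$loglik_trace)])
  }
  sum(gmm_log_density(object, newdata))
}

#' @export
predict.diag_gmm <- function(object, newdata,
                             type = c("log_density", "responsibility"), ...) {
  type <- match.arg(type)
  x <- frames_as_matrix(newdata)
  if (type == "log_density") return(gmm_log_density(object, x))
  lp <- comp_log_dens(x, object$means, object$variances) +
    matrix(log(object$weights), nrow(x), length(object$weights), byrow = TRUE)
  exp(lp - logsumexp_rows(lp))
}

#' Simulate draws from a fitted mixture
#'
#' @param object A \code{diag_gmm}.
#' @param nsim Number of frames to draw.
#' @param seed Seed for the draw (RNG state is restored afterwards).
#' @param ... Unused.
#' @return An \code{nsim} x D matrix.
#' @export
simulate.diag_gmm <- function(object, nsim = 1L, seed = NULL, ...) {
  draw <- function() {
    comp <- sample.int(length(object$weights), nsim, replace = TRUE,
                       prob = object$weights)
    mu <- object$means[comp, , drop = FALSE]
    sd <- sqrt(object$variances[comp, , drop = FALSE])
    mu + matrix(stats::rnorm(nsim * ncol(mu)), nsim) * sd
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Serialize / restore a GMM as JSON-compatible text
#'
#' \code{write_gmm} writes the model parameters and metadata to a plain
#' text file at full double precision; \code{read_gmm} restores a
#' bit-exact copy.
#'
#' @param model A \code{diag_gmm}.
#' @param path Output path.
#' @return \code{write_gmm}: the path, invisibly; \code{read_gmm}: the
#'   model.
#' @export
write_gmm <- function(model, path) {
  enc <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    sprintf("G %d", length(model$weights)),
    sprintf("D %d", ncol(model$means)),
    paste("weights", enc(model$weights)),
    vapply(seq_len(nrow(model$means)),
           function(g) paste("mean", enc(model$means[g, ])), ""),
    vapply(seq_len(nrow(model$variances)),
           function(g) paste("var", enc(model$variances[g, ])), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  lines <- readLines(path)
  val <- function(prefix) {
    l <- lines[startsWith(lines, paste0(prefix, " "))]
    lapply(strsplit(sub(paste0("^", prefix, " "), "", l), " "), as.numeric)
  }
  w <- val("weights")[[1L]]
  mu <- do.call(rbind, val("mean"))
  sg <- do.call(rbind, val("var"))
  new_diag_gmm(w, mu, sg, meta = list(restored = TRUE))
}
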