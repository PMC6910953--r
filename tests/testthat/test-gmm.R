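test_that("single-Gaussian fit is the closed-form ML estimate", {
  set.seed(2)
  x <- matrix(stats::rnorm(500 * 3, mean = 2, sd = 1.5), 500, 3)
  m <- fit_gmm(x, 1)
  expect_equal(m$weights, 1)
  expect_equal(as.numeric(m$means), colMeans(x))
  expect_equal(as.numeric(m$variances),
               apply(x, 2, function(v) mean((v - mean(v))^2)))
})

test_that("EM log-likelihood is non-decreasing and seeded fits are identical", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    x <- matrix(stats::rnorm(600 * 2), 600, 2)
    for (G in c(2, 4)) {
      m <- fit_gmm(x, G, map_config(init_seed = seed))
      expect_true(all(diff(m$loglik_trace) >= -1e-8))
    }
  }
  set.seed(3); x <- matrix(stats::rnorm(400 * 2), 400, 2)
  m1 <- fit_gmm(x, 4, map_config(init_seed = 9))
  m2 <- fit_gmm(x, 4, map_config(init_seed = 9))
  expect_identical(m1$means, m2$means)
  expect_identical(m1$loglik_trace, m2$loglik_trace)
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(42)
  truth <- rbind(c(-2, 0), c(2, 1))
  x <- rbind(
    matrix(stats::rnorm(5000 * 2, sd = 0.7), 5000, 2) +
      rep(truth[1, ], each = 5000),
    matrix(stats::rnorm(5000 * 2, sd = 0.7), 5000, 2) +
      rep(truth[2, ], each = 5000))
  m <- fit_gmm(x, 2, map_config(init_seed = 1))
  perm <- if (sum((m$means[1, ] - truth[1, ])^2) <
              sum((m$means[1, ] - truth[2, ])^2)) 1:2 else 2:1
  expect_lt(max(abs(m$means[perm, ] - truth)), 0.05)
})

test_that("degenerate inputs: identical rows hit the variance floor, n < G errors", {
  x <- matrix(1, 50, 3)
  m <- fit_gmm(x, 1)
  expect_true(all(is.finite(m$variances)))
  expect_true(all(m$variances <= 1e-11))
  m2 <- fit_gmm(x, 2, map_config(init_seed = 2))
  expect_true(all(is.finite(unlist(m2[c("weights", "means", "variances")]))))
  expect_error(fit_gmm(matrix(0, 3, 2), 4), "fewer rows")
})

test_that("MAP adaptation: closed form for G = 1, UBM limit, empty data", {
  ubm <- fit_gmm(matrix(stats::rnorm(200 * 2), 200, 2), 1)
  mu0 <- as.numeric(ubm$means)
  set.seed(8)
  x <- matrix(stats::rnorm(40 * 2, mean = 3), 40, 2)
  r <- 16
  ad <- map_adapt(ubm, x, map_config(relevance_factor = r))
  expect_equal(as.numeric(ad$means),
               (40 * colMeans(x) + r * mu0) / (40 + r), tolerance = 1e-12)
  # r -> Inf leaves the UBM untouched
  ad_inf <- map_adapt(ubm, x, map_config(relevance_factor = 1e12))
  expect_lt(max(abs(as.numeric(ad_inf$means) - mu0)), 1e-9)
  # no frames: model unchanged
  expect_equal(map_adapt(ubm, x[0, , drop = FALSE])$means, ubm$means)
  expect_error(map_adapt(ubm, matrix(0, 5, 3)), "dimension")
})

test_that("adapted means lie between UBM means and the posterior data means", {
  set.seed(77)
  ubm <- fit_gmm(matrix(stats::rnorm(800 * 2), 800, 2), 4,
                 map_config(init_seed = 3))
  x <- matrix(stats::rnorm(100 * 2, mean = 1), 100, 2)
  ad <- map_adapt(ubm, x, map_config(relevance_factor = 16))
  lp <- sapply(seq_along(ubm$weights), function(g)
    log(ubm$weights[g]) + gmm_log_density(
      structure(list(weights = 1, means = ubm$means[g, , drop = FALSE],
                     variances = ubm$variances[g, , drop = FALSE]),
                class = "diag_gmm"), x))
  gamma <- exp(lp - apply(lp, 1, function(r) max(r) + log(sum(exp(r - max(r))))))
  ex <- (t(gamma) %*% x) / pmax(colSums(gamma), 1e-300)
  lo <- pmin(ubm$means, ex); hi <- pmax(ubm$means, ex)
  expect_true(all(ad$means >= lo - 1e-10 & ad$means <= hi + 1e-10))
})

test_that("mixture log-density: closed form, permutation invariance, naive-sum oracle", {
  g1 <- structure(list(weights = 1, means = matrix(0, 1, 1),
                       variances = matrix(1, 1, 1)), class = "diag_gmm")
  expect_equal(gmm_log_density(g1, 0), -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(12)
  w <- c(0.5, 0.3, 0.2)
  mu <- matrix(stats::rnorm(6), 3, 2)
  sg <- matrix(stats::runif(6, 0.5, 2), 3, 2)
  m <- structure(list(weights = w, means = mu, variances = sg),
                 class = "diag_gmm")
  x <- matrix(stats::rnorm(20), 10, 2)
  # brute force in probability space
  naive <- log(sapply(seq_len(10), function(i) {
    sum(sapply(1:3, function(g)
      w[g] * prod(stats::dnorm(x[i, ], mu[g, ], sqrt(sg[g, ])))))
  }))
  expect_equal(gmm_log_density(m, x), naive, tolerance = 1e-10)

  p <- c(3, 1, 2)
  mp <- structure(list(weights = w[p], means = mu[p, ], variances = sg[p, ]),
                  class = "diag_gmm")
  expect_equal(gmm_log_density(mp, x), gmm_log_density(m, x), tolerance = 1e-12)

  # log-sum-exp never overflows for extreme inputs
  expect_true(is.finite(gmm_log_density(m, c(1e6, -1e6))))
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(6)
  m <- fit_gmm(matrix(stats::rnorm(300 * 2), 300, 2), 3,
               map_config(init_seed = 5))
  p <- withr::local_tempfile(fileext = ".gmm")
  write_gmm(m, p)
  m2 <- read_gmm(p)
  expect_identical(m2$weights, as.numeric(m$weights))
  expect_identical(unname(m2$means), unname(m$means))
  expect_identical(unname(m2$variances), unname(m$variances))
})

test_that("simulate() draws from the fitted density", {
  m <- structure(list(weights = c(0.5, 0.5), means = rbind(-5, 5),
                      variances = rbind(0.1, 0.1)), class = "diag_gmm")
  s <- simulate(m, 4000, seed = 3)
  expect_equal(mean(abs(s)), 5, tolerance = 0.1)
  expect_identical(simulate(m, 50, seed = 3), simulate(m, 50, seed = 3))
})
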