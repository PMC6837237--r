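test_that("the tempering exponent solve matches its defining equation", {
  # identical log-likelihoods: weights equal at any increment -> jump to 1
  expect_equal(next_exponent(rep(3.7, 50), q = 0.2), 1)
  # two samples: population CoV of two weights is (x-1)/(x+1) < 1, so the
  # target 1.0 is unattainable and the exponent caps at 1
  expect_equal(next_exponent(c(0, 10), q = 0), 1)
  # large sample: the returned increment reproduces the target CoV
  set.seed(7)
  ll <- rnorm(1000, sd = 5)
  q1 <- next_exponent(ll, q = 0, target = 1.0, tol = 1e-12)
  expect_gt(q1, 0)
  expect_lt(q1, 1)
  w <- exp(q1 * (ll - max(ll)))
  cov_w <- sqrt(mean((w - mean(w))^2)) / mean(w)
  expect_equal(cov_w, 1.0, tolerance = 1e-6)
  expect_error(next_exponent(ll, q = 1), "below 1")
})

test_that("the stage covariance equals the weighted outer-product sum", {
  s <- matrix(c(-1, 1), 2, 1)
  expect_equal(stage_covariance(s, c(0.5, 0.5), b = 1), matrix(1, 1, 1))
  expect_equal(stage_covariance(matrix(2, 5, 1), rep(0.2, 5), b = 1),
               matrix(0, 1, 1))
  set.seed(8)
  s <- matrix(rnorm(60), 20, 3)
  w <- runif(20); w <- w / sum(w)
  S <- stage_covariance(s, w, b = 0.2)
  mu <- colSums(s * w)
  oracle <- matrix(0, 3, 3)
  for (k in 1:20)
    oracle <- oracle + w[k] * tcrossprod(s[k, ] - mu)
  oracle <- 0.04 * oracle
  expect_equal(S, oracle, tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-14))
  expect_error(stage_covariance(s, rep(1, 20), b = 0.2), "normalized")
})

test_that("degenerate resampling reduces to a multinomial bootstrap", {
  set.seed(3)
  cur <- matrix(runif(40, 1, 2), 20, 2)
  pr <- prior_box(c(0, 0), c(3, 3))
  mv <- resample_and_move(cur, rep(0, 20), rep(0.05, 20),
                          Sigma = matrix(0, 2, 2), q_next = 1,
                          loglik_fn = function(th) 0, prior = pr)
  expect_equal(nrow(mv$samples), 20)
  # with a zero proposal every output row is one of the current samples
  key <- apply(cur, 1, paste, collapse = "|")
  expect_true(all(apply(mv$samples, 1, paste, collapse = "|") %in% key))
  expect_error(
    resample_and_move(cur, rep(0, 20), rep(0.05, 20),
                      Sigma = matrix(c(1, 2, 2, 1), 2, 2), q_next = 1,
                      loglik_fn = function(th) 0, prior = pr),
    "positive semidefinite")
})

test_that("gaussian likelihood evaluations match the closed forms", {
  fwd <- function(th) rep(0, 1)
  spec <- likelihood_spec(fwd, data = 0, sigma = 1 / sqrt(2 * pi))
  expect_equal(log_likelihood(numeric(0), spec), 0)

  m <- 7; sig <- 0.3
  spec <- likelihood_spec(function(th) rep(0, m), data = rep(sig, m),
                          sigma = sig)
  expect_equal(log_likelihood(numeric(0), spec),
               -(m / 2) * log(2 * pi * sig^2) - m / 2)

  # free-sigma parametrization: last component is sigma
  spec <- likelihood_spec(function(th) th[1] * (1:4), data = (1:4) * 2)
  expect_equal(log_likelihood(c(2, 0.5), spec), -2 * log(2 * pi * 0.25))
  expect_equal(log_likelihood(c(2, -1), spec), -Inf)

  # failed forward solves are rejected, not fatal
  spec <- likelihood_spec(function(th) stop("boom"), data = 1:3, sigma = 1)
  expect_identical(log_likelihood(1, spec), -Inf)

  # dense-covariance path against a direct multivariate normal density
  set.seed(12)
  m <- 5
  A <- matrix(rnorm(m * m), m)
  S <- crossprod(A) + diag(m) * 0.1
  D <- rnorm(m); g <- rnorm(m)
  spec <- likelihood_spec(function(th) g, data = D, covariance = function(th) S)
  direct <- -m / 2 * log(2 * pi) - 0.5 * determinant(S)$modulus -
    0.5 * drop(t(D - g) %*% solve(S) %*% (D - g))
  expect_equal(log_likelihood(numeric(0), spec), as.numeric(direct),
               tolerance = 1e-10)
})

test_that("a flat likelihood returns the prior and its constant evidence", {
  pr <- prior_box(-2, 5)
  fit <- run_tmcmc(function(th) log(0.37), pr,
                   tmcmc_config(n_samples = 2000), seed = 4)
  expect_equal(fit$log_evidence, log(0.37), tolerance = 1e-9)
  expect_true(all(fit$samples >= -2 & fit$samples <= 5))
  ks <- suppressWarnings(stats::ks.test(fit$samples[, 1], "punif", -2, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("the evidence of a gaussian bump in a uniform box is -log(volume)", {
  pr <- prior_box(-10, 10)
  fit <- run_tmcmc(function(th) stats::dnorm(th, log = TRUE), pr,
                   tmcmc_config(n_samples = 1000), seed = 21)
  expect_equal(fit$log_evidence, -log(20), tolerance = 0.15)
  expect_true(all(diff(c(0, fit$stages$q)) > 0))
  expect_equal(fit$stages$q[nrow(fit$stages)], 1)
  expect_true(all(fit$samples >= -10 & fit$samples <= 10))
  expect_lt(abs(mean(fit$samples)), 0.15)
})

test_that("a linear-gaussian posterior is recovered with its closed form", {
  set.seed(31)
  d <- 2; m <- 8; sig <- 0.1
  H <- matrix(rnorm(m * d), m, d)
  theta_true <- c(0.7, -0.4)
  D <- drop(H %*% theta_true) + rnorm(m, sd = sig)
  post_cov <- solve(crossprod(H)) * sig^2
  post_mean <- drop(solve(crossprod(H), crossprod(H, D)))
  spec <- likelihood_spec(function(th) drop(H %*% th), D, sigma = sig)
  fit <- run_tmcmc(likelihood_function(spec), prior_box(c(-10, -10), c(10, 10)),
                   tmcmc_config(n_samples = 2000), seed = 32)
  sm <- posterior_summary(fit)
  expect_lt(max(abs(sm$mean - post_mean) / sqrt(diag(post_cov))), 0.3)
  expect_lt(max(abs(sm$sd / sqrt(diag(post_cov)) - 1)), 0.3)
})

test_that("posterior summaries use the population CoV convention", {
  fit <- structure(list(samples = matrix(c(0.9, 1, 1.1), 3, 1,
                                         dimnames = list(NULL, "x"))),
                   class = "tmcmc_fit")
  sm <- posterior_summary(fit)
  expect_equal(sm$mean, 1)
  expect_equal(sm$cov_pct, 100 * sqrt(0.02 / 3), tolerance = 1e-10)

  set.seed(5)
  v <- rnorm(200, 2, 0.3)
  fit$samples <- matrix(v, dimnames = list(NULL, "x"))
  sm <- posterior_summary(fit)
  expect_equal(sm$cov_pct, 100 * sqrt(mean((v - mean(v))^2)) / mean(v),
               tolerance = 1e-12)
})

test_that("worker count does not change seeded results", {
  pr <- prior_box(-5, 5)
  ll <- function(th) stats::dnorm(th, log = TRUE)
  f1 <- run_tmcmc(ll, pr, tmcmc_config(n_samples = 200, workers = 1), seed = 6)
  f2 <- run_tmcmc(ll, pr, tmcmc_config(n_samples = 200, workers = 2), seed = 6)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_evidence, f2$log_evidence)
})
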