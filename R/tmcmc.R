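#' Uniform box prior
#'
#' Independent uniform prior over a hyper-rectangle; density is constant
#' inside the box and zero outside.
#'
#' @param lower,upper Numeric vectors of equal length with `lower < upper`.
#' @param names Optional parameter names.
#' @return An object of class `prior_box`.
#' @export
prior_box <- function(lower, upper, names = NULL) {
  if (length(lower) != length(upper)) stop("lower and upper lengths differ")
  if (any(!(lower < upper))) stop("each lower bound must be below its upper bound")
  if (is.null(names)) names <- paste0("theta", seq_along(lower))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 names = names, d = length(lower)),
            class = "prior_box")
}

prior_sample <- function(prior, n) {
  d <- prior$d
  m <- matrix(stats::runif(n * d), n, d)
  m <- sweep(m, 2, prior$upper - prior$lower, `*`)
  m <- sweep(m, 2, prior$lower, `+`)
  colnames(m) <- prior$names
  m
}

prior_contains <- function(prior, theta) {
  all(theta >= prior$lower & theta <= prior$upper)
}

#' TMCMC sampler configuration
#'
#' @param n_samples Population size per stage (constant across stages).
#' @param b Proposal covariance scaling factor (the stage covariance is
#'   `b^2` times the weighted sample covariance); 0.2 is the usual choice.
#' @param cov_target Target coefficient of variation of the plausibility
#'   weights used to choose each tempering exponent (usually 1.0).
#' @param exponent_tol Bisection tolerance for the exponent solve.
#' @param max_stages Hard cap on the number of tempering stages.
#' @param workers Parallel workers for likelihood evaluation (results are
#'   identical to serial execution for a fixed seed).
#' @param jitter Diagonal jitter added to a rank-deficient stage covariance.
#' @return A list of class `tmcmc_config`.
#' @export
tmcmc_config <- function(n_samples = 500, b = 0.2, cov_target = 1.0,
                         exponent_tol = 1e-8, max_stages = 60, workers = 1,
                         jitter = 0) {
  stopifnot(n_samples >= 2, b > 0, cov_target > 0)
  structure(list(n_samples = as.integer(n_samples), b = b,
                 cov_target = cov_target, exponent_tol = exponent_tol,
                 max_stages = as.integer(max_stages),
                 workers = as.integer(workers), jitter = jitter),
            class = "tmcmc_config")
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Next tempering exponent
#'
#' Chooses q_{j+1} so that the coefficient of variation (population SD over
#' mean) of the plausibility weights w = exp((q_{j+1} - q_j) * loglik)
#' equals `target`, by bisection on the increment; weights are computed in
#' log space with max-subtraction. If even the full jump to q = 1 keeps the
#' CoV below target (including the degenerate case of identical
#' log-likelihoods), returns 1.
#'
#' @param loglik Log-likelihood values at the current samples (-Inf allowed).
#' @param q Current exponent (0 <= q < 1).
#' @param target Target CoV (default 1.0).
#' @param tol Bisection tolerance on the increment.
#' @return The next exponent q_{j+1} in (q, 1].
#' @export
next_exponent <- function(loglik, q, target = 1.0, tol = 1e-8) {
  if (q >= 1) stop("current exponent must be below 1")
  if (all(!is.finite(loglik)))
    stop("all log-likelihoods are non-finite; cannot temper")
  shifted <- loglik - max(loglik[is.finite(loglik)])
  cov_at <- function(dq) {
    w <- exp(dq * shifted)
    mw <- mean(w)
    if (mw == 0) return(Inf)
    sqrt(mean((w - mw)^2)) / mw
  }
  hi <- 1 - q
  if (cov_at(hi) <= target) return(1)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cov_at(mid) <= target) lo <- mid else hi <- mid
  }
  q + (lo + hi) / 2
}

#' Scaled weighted sample covariance of a TMCMC stage
#'
#' Computes `b^2 * sum_k wbar_k (theta_k - mu)(theta_k - mu)^T` with `mu`
#' the weight-averaged mean. A rank-deficient result is jittered on the
#' diagonal (with a warning) so the proposal stays usable.
#'
#' @param samples N x d matrix.
#' @param wbar Normalized plausibility weights (sum to 1).
#' @param b Scaling factor.
#' @param jitter Diagonal jitter used when the covariance is degenerate.
#' @return A d x d symmetric positive semidefinite matrix.
#' @export
stage_covariance <- function(samples, wbar, b = 0.2, jitter = 0) {
  samples <- as.matrix(samples)
  if (abs(sum(wbar) - 1) > 1e-8) stop("weights must be normalized")
  mu <- colSums(samples * wbar)
  centered <- sweep(samples, 2, mu)
  S <- b^2 * crossprod(centered, centered * wbar)
  S <- (S + t(S)) / 2
  if (all(diag(S) <= 0)) {
    if (jitter > 0) {
      warning("degenerate stage covariance; adding diagonal jitter")
      S <- S + diag(jitter, ncol(S))
    }
  }
  S
}

# Cholesky factor with escalating jitter fallback.
safe_chol <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  sc <- mean(diag(S))
  if (sc <= 0) sc <- 1e-300
  for (f in 10^(-12:-4)) {
    ch <- tryCatch(chol(S + diag(f * sc, ncol(S))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("stage covariance is not positive semidefinite")
}

#' Resample and move a TMCMC generation
#'
#' Multinomial resampling by normalized plausibility weight followed by
#' Metropolis chains: a sample selected n_k times seeds an independent chain
#' of length n_k targeting the tempered density
#' `f ∝ likelihood^q_next * prior`, with Gaussian proposals of covariance
#' `Sigma`. The chain records its state after every proposal (accepted or
#' not), so the new generation again has N samples. Proposals outside the
#' prior box are rejected outright. Each chain runs on its own RNG
#' substream, so results are independent of the worker count.
#'
#' @param samples N x d matrix of the current generation.
#' @param loglik Their log-likelihood values.
#' @param wbar Normalized plausibility weights.
#' @param Sigma Proposal covariance (from [stage_covariance()]).
#' @param q_next Tempering exponent of the target.
#' @param loglik_fn Log-likelihood function (vector -> scalar).
#' @param prior The [prior_box()].
#' @param workers Parallel workers.
#' @return List with the new `samples`, their `loglik`, and the Metropolis
#'   `accept_rate`.
#' @export
resample_and_move <- function(samples, loglik, wbar, Sigma, q_next,
                              loglik_fn, prior, workers = 1) {
  N <- nrow(samples)
  eig <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(eig) < -1e-10 * max(abs(eig), 1e-300))
    stop("proposal covariance is not positive semidefinite")
  counts <- as.vector(stats::rmultinom(1, N, wbar))
  sel <- which(counts > 0)
  L <- if (all(diag(Sigma) == 0)) NULL else safe_chol(Sigma)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, length(sel))

  run_chain <- function(ci) {
    k <- sel[ci]
    rng <- local_rng(chain_seeds[ci])
    on.exit(rng())
    n <- counts[k]
    d <- ncol(samples)
    th <- samples[k, ]
    ll <- loglik[k]
    out <- matrix(NA_real_, n, d)
    out_ll <- numeric(n)
    acc <- 0L
    for (s in seq_len(n)) {
      prop <- if (is.null(L)) th else th + drop(crossprod(L, stats::rnorm(d)))
      ok <- prior_contains(prior, prop)
      if (ok) {
        pll <- loglik_fn(prop)
        lr <- q_next * (pll - ll)
        if (is.nan(lr)) lr <- -Inf
        if (log(stats::runif(1)) < lr) {
          th <- prop; ll <- pll; acc <- acc + 1L
        }
      } else stats::runif(1)  # keep the substream aligned with the accept draw
      out[s, ] <- th
      out_ll[s] <- ll
    }
    list(samples = out, loglik = out_ll, acc = acc, n = n)
  }

  res <- if (workers > 1) {
    parallel::mclapply(seq_along(sel), run_chain, mc.cores = workers)
  } else lapply(seq_along(sel), run_chain)
  new_samples <- do.call(rbind, lapply(res, `[[`, "samples"))
  new_ll <- unlist(lapply(res, `[[`, "loglik"))
  colnames(new_samples) <- colnames(samples)
  list(samples = new_samples, loglik = new_ll,
       accept_rate = sum(vapply(res, `[[`, 0L, "acc")) /
                     max(sum(counts), 1L))
}

#' Transitional MCMC sampling with evidence estimation
#'
#' Tempers from the prior to the posterior through intermediate densities
#' proportional to `likelihood^q * prior`, with the exponent schedule chosen
#' adaptively from the spread of the plausibility weights. Each stage
#' resamples by weight and moves the population with Metropolis chains; the
#' log-evidence accumulates as the sum over stages of the log mean
#' plausibility weight.
#'
#' @param loglik_fn Function mapping a parameter vector to a log-likelihood
#'   (may return -Inf, e.g. for failed forward solves).
#' @param prior A [prior_box()].
#' @param config A [tmcmc_config()].
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `tmcmc_fit`: final `samples` (N x d, drawn
#'   from the posterior), their `loglik`, `log_evidence`, and a `stages`
#'   data frame (exponent, log mean weight, acceptance rate, effective
#'   sample size).
#' @export
run_tmcmc <- function(loglik_fn, prior, config = tmcmc_config(), seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng())
  N <- config$n_samples
  samples <- prior_sample(prior, N)
  eval_ll <- function(th_mat) {
    if (config$workers > 1) {
      unlist(parallel::mclapply(seq_len(nrow(th_mat)),
                                function(i) loglik_fn(th_mat[i, ]),
                                mc.cores = config$workers))
    } else
      vapply(seq_len(nrow(th_mat)), function(i) loglik_fn(th_mat[i, ]), 0.0)
  }
  loglik <- eval_ll(samples)
  q <- 0
  log_evidence <- 0
  stages <- list()
  j <- 0
  while (q < 1) {
    j <- j + 1
    if (j > config$max_stages)
      stop("TMCMC did not reach q = 1 within ", config$max_stages,
           " stages (last q = ", signif(q, 6), ")")
    q_next <- next_exponent(loglik, q, config$cov_target, config$exponent_tol)
    dq <- q_next - q
    logw <- dq * loglik
    logw[!is.finite(loglik)] <- -Inf
    logS <- logmeanexp(logw)
    log_evidence <- log_evidence + logS
    lse <- logS + log(length(logw))
    wbar <- exp(logw - lse)
    wbar <- wbar / sum(wbar)
    Sigma <- stage_covariance(samples, wbar, config$b, config$jitter)
    mv <- resample_and_move(samples, loglik, wbar, Sigma, q_next,
                            loglik_fn, prior, config$workers)
    stages[[j]] <- data.frame(
      stage = j, q = q_next, log_mean_weight = logS,
      ess = 1 / sum(wbar^2), accept_rate = mv$accept_rate)
    samples <- mv$samples
    loglik <- mv$loglik
    q <- q_next
  }
  structure(list(samples = samples, loglik = loglik,
                 log_evidence = log_evidence,
                 stages = do.call(rbind, stages),
                 prior = prior, config = config, seed = seed),
            class = "tmcmc_fit")
}

#' @export
print.tmcmc_fit <- function(x, ...) {
  cat(sprintf("tmcmc_fit: %d samples, %d parameters, %d stages\n",
              nrow(x$samples), ncol(x$samples), nrow(x$stages)))
  cat(sprintf("  log evidence = %.3f\n", x$log_evidence))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summaries from a TMCMC fit
#'
#' Marginal posterior mean, population standard deviation, and coefficient
#' of variation u = SD/mean (reported in percent) for each parameter.
#'
#' @param fit A `tmcmc_fit`.
#' @param pars Optional character vector of parameter names.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `cov_pct`.
#' @export
posterior_summary <- function(fit, pars = NULL) {
  s <- fit$samples
  if (!is.null(pars)) {
    if (!all(pars %in% colnames(s))) stop("unknown parameter name")
    s <- s[, pars, drop = FALSE]
  }
  mean_ <- colMeans(s)
  sd_ <- sqrt(colMeans(sweep(s, 2, mean_)^2))
  cov_pct <- ifelse(mean_ == 0, NA_real_, 100 * sd_ / mean_)
  if (any(mean_ == 0))
    warning("posterior mean is zero for some parameter; CoV undefined")
  data.frame(parameter = colnames(s), mean = unname(mean_),
             sd = unname(sd_), cov_pct = unname(cov_pct),
             row.names = NULL)
}
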