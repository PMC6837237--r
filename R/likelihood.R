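#' Gaussian-error likelihood specification
#'
#' Links a deterministic forward map g(theta) to observed data D under the
#' prediction-error model D = g(theta) + e with e ~ N(0, Sigma). By default
#' Sigma = sigma^2 I and the noise SD sigma is treated as a free parameter
#' appended as the *last* component of theta; it can instead be fixed to a
#' known value, or a full covariance function can be plugged in.
#'
#' @param forward Function mapping the model-parameter vector (theta without
#'   sigma) to a predicted data vector of the same length as `data`.
#' @param data Observed data vector (e.g. `as.vector(obs$data)`).
#' @param sigma `"free"` (default) to estimate the noise SD as the last
#'   component of theta, or a fixed positive number.
#' @param covariance Optional function theta -> covariance matrix for a
#'   non-iid error model; overrides `sigma`.
#' @return An object of class `likelihood_spec`.
#' @export
likelihood_spec <- function(forward, data, sigma = "free", covariance = NULL) {
  data <- as.numeric(data)
  if (!is.function(forward)) stop("forward must be a function")
  if (!identical(sigma, "free") && !(is.numeric(sigma) && sigma > 0))
    stop("sigma must be \"free\" or a positive number")
  structure(list(forward = forward, data = data, sigma = sigma,
                 covariance = covariance, m = length(data)),
            class = "likelihood_spec")
}

#' Log-likelihood of a parameter vector
#'
#' Evaluates `log p(D | theta, M) = -(m/2) log(2 pi) - (1/2) log|Sigma|
#' - J/2` with the weighted misfit `J = (D - g)' Sigma^{-1} (D - g)`. For
#' the default iid model this reduces to
#' `-(m/2) log(2 pi sigma^2) - ||D - g||^2 / (2 sigma^2)`. A failed forward
#' solve (error or non-finite output) yields `-Inf`, so the sample is
#' rejected rather than aborting the sampler.
#'
#' @param theta Parameter vector; if the spec has `sigma = "free"`, the last
#'   component is sigma.
#' @param spec A [likelihood_spec()].
#' @return Scalar log-likelihood (possibly -Inf).
#' @export
log_likelihood <- function(theta, spec) {
  stopifnot(inherits(spec, "likelihood_spec"))
  free_sigma <- identical(spec$sigma, "free") && is.null(spec$covariance)
  if (free_sigma) {
    sig <- theta[length(theta)]
    th <- theta[-length(theta)]
    if (!(sig > 0)) return(-Inf)
  } else {
    sig <- spec$sigma
    th <- theta
  }
  g <- tryCatch(spec$forward(th), error = function(e) NULL)
  if (is.null(g) || length(g) != spec$m || any(!is.finite(g))) return(-Inf)
  r <- spec$data - g
  if (!is.null(spec$covariance)) {
    S <- spec$covariance(theta)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    z <- backsolve(ch, r, transpose = TRUE)
    return(-(spec$m / 2) * log(2 * pi) - sum(log(diag(ch))) -
             0.5 * sum(z^2))
  }
  -(spec$m / 2) * log(2 * pi * sig^2) - sum(r^2) / (2 * sig^2)
}

# Closure form used by the sampler.
likelihood_function <- function(spec) {
  function(theta) log_likelihood(theta, spec)
}
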