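#' Candidate defect model
#'
#' A defect model M_i frees the scaled stiffness (beta) or scaled relaxed
#' area (alpha) of one artery — or of two arteries for a pair model
#' M_{i:j} — while every other artery is held at its reference value. The
#' observation-noise SD sigma is always an additional free parameter, and
#' optionally a scaled blood viscosity can be estimated too.
#'
#' @param arteries One or two artery ids whose parameter is free.
#' @param kind `"stiffness"` (beta) or `"area"` (alpha).
#' @param id Model label; default `"M<i>"` or `"M<i>:<j>"`.
#' @param bounds Uniform prior bounds for each free defect parameter.
#' @param sigma_bounds Uniform prior bounds for sigma (m/s).
#' @param estimate_viscosity If `TRUE`, prepend a scaled-viscosity parameter
#'   (multiplier on the reference viscosity).
#' @param viscosity_bounds Prior bounds for the viscosity scale.
#' @return An object of class `defect_model`.
#' @export
defect_model <- function(arteries, kind = c("stiffness", "area"), id = NULL,
                         bounds = c(0, 3), sigma_bounds = c(0, 1),
                         estimate_viscosity = FALSE,
                         viscosity_bounds = c(0.5, 1.5)) {
  kind <- match.arg(kind)
  arteries <- as.integer(arteries)
  if (length(arteries) < 1 || length(arteries) > 2)
    stop("a defect model frees one or two arteries")
  if (is.null(id)) id <- paste0("M", paste(arteries, collapse = ":"))
  par_sym <- if (kind == "stiffness") "beta" else "alpha"
  nm <- c(if (estimate_viscosity) "viscosity_scale",
          paste0(par_sym, arteries), "sigma")
  lower <- c(if (estimate_viscosity) viscosity_bounds[1],
             rep(bounds[1], length(arteries)), sigma_bounds[1])
  upper <- c(if (estimate_viscosity) viscosity_bounds[2],
             rep(bounds[2], length(arteries)), sigma_bounds[2])
  structure(list(id = id, arteries = arteries, kind = kind,
                 estimate_viscosity = estimate_viscosity,
                 prior = prior_box(lower, upper, nm)),
            class = "defect_model")
}

#' Forward map of a defect model
#'
#' Builds the deterministic map g(theta | M): substitute the model's free
#' parameters into the reference network, simulate the flow, and return the
#' sensor velocity samples as one vector (column-wise, sensor-major). The
#' discretization is resolved once against the reference network so every
#' candidate theta is solved on the identical grid.
#'
#' @param model A [defect_model()].
#' @param net Reference [artery_network()].
#' @param waveform,config,sensors Simulation setup shared with the data.
#' @return A function theta -> numeric vector (length samples x sensors).
#' @export
make_forward_map <- function(model, net, waveform, config, sensors) {
  rcfg <- if (inherits(config, "solver_config_resolved")) config
          else resolve_solver(config, net, waveform)
  sc <- sensors_to_cpp(sensors, net, rcfg)
  base <- net_to_cpp(net)
  wv <- list(period = waveform$period, cos_coef = waveform$cos_coef,
             sin_coef = waveform$sin_coef)
  idx <- match(model$arteries, net$arteries$id)
  ref_B <- net$arteries$ref_stiffness[idx]
  ref_A <- net$arteries$ref_area[idx]
  mu_ref <- net$fluid$viscosity
  nv <- if (model$estimate_viscosity) 1L else 0L
  kind <- model$kind
  function(theta) {
    fac <- theta[nv + seq_along(idx)]
    if (any(!(fac > 0))) stop("non-positive defect factor")
    nt <- base
    if (kind == "stiffness") nt$stiffness[idx] <- fac * ref_B
    else nt$area[idx] <- fac * ref_A
    if (nv == 1L) nt$Kr <- -22 * (theta[1] * mu_ref) * pi
    as.vector(cpp_run(nt, wv, rcfg, sc, list())$velocity)
  }
}

#' Evaluate one defect model against observed data
#'
#' Runs TMCMC for the model's parameters given the observations, returning
#' the posterior ensemble and the log-evidence used for model selection.
#'
#' @param model A [defect_model()].
#' @param obs An `observation_set`.
#' @param net Reference network (healthy values).
#' @param waveform,config Simulation setup; must match the data generation.
#' @param tmcmc A [tmcmc_config()].
#' @param seed Integer seed.
#' @param sigma `"free"` (default) to estimate the noise SD alongside the
#'   defect parameters, or a fixed positive value (useful for noise-free
#'   self-consistency checks, where a free sigma has a singular posterior).
#' @return List with `model`, `fit` (the `tmcmc_fit`), `log_evidence` and
#'   the posterior `summary` data frame.
#' @export
evaluate_model <- function(model, obs, net, waveform = inflow_waveform(),
                           config = solver_config(), tmcmc = tmcmc_config(),
                           seed = 1, sigma = "free") {
  if (is.null(obs$sensors))
    stop("observation set carries no sensor layout; supply one generated ",
         "by generate_dataset() or attach $sensors")
  fwd <- make_forward_map(model, net, waveform, config, obs$sensors)
  prior <- model$prior
  if (!identical(sigma, "free")) {
    keep <- prior$names != "sigma"
    prior <- prior_box(prior$lower[keep], prior$upper[keep],
                       prior$names[keep])
  }
  spec <- likelihood_spec(fwd, as.vector(obs$data), sigma = sigma)
  fit <- run_tmcmc(likelihood_function(spec), prior, tmcmc, seed)
  list(model = model, fit = fit, log_evidence = fit$log_evidence,
       summary = posterior_summary(fit))
}

#' Posterior probabilities over a model class
#'
#' Normalizes per-model log-evidences into the model-selection posterior
#' `Pr(M_i | D) = rho(D | M_i) Pr(M_i) / sum_j rho(D | M_j) Pr(M_j)`,
#' computed stably with max-subtraction. The default model prior is uniform.
#'
#' @param log_evidence Numeric vector of log-evidences.
#' @param prior Prior model probabilities (default uniform); must sum to 1.
#' @return Probabilities summing to 1, named like `log_evidence`.
#' @export
model_posterior <- function(log_evidence, prior = NULL) {
  k <- length(log_evidence)
  if (k == 0) stop("empty model list")
  if (any(!is.finite(log_evidence))) stop("log-evidences must be finite")
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (length(prior) != k || abs(sum(prior) - 1) > 1e-8)
    stop("model prior must have one probability per model and sum to 1")
  lp <- log_evidence + log(prior)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- names(log_evidence)
  p
}

#' Bayesian defect localization over a class of candidate models
#'
#' Evaluates every candidate defect model on the same data (each with its
#' own seeded TMCMC run), converts the log-evidences into the
#' model-selection posterior, and tabulates per-model parameter estimates.
#' The posterior probability of model M_i measures how likely the structural
#' defect is to sit in artery i.
#'
#' @param models List of [defect_model()] objects (>= 2 for a real
#'   selection; a single model gets probability 1).
#' @param obs,net,waveform,config,tmcmc As in [evaluate_model()].
#' @param seed Master seed; per-model seeds are derived from it and the
#'   model's position so runs are reproducible and independently
#'   parallelizable.
#' @param model_prior Optional prior over models (default uniform).
#' @return An object of class `defect_selection`: `table` (one row per
#'   model: estimates, CoV u\%, sigma estimate, log-evidence, posterior
#'   probability), `evaluations` (full per-model results), `winner` (id of
#'   the maximum-probability model).
#' @export
run_selection <- function(models, obs, net, waveform = inflow_waveform(),
                          config = solver_config(), tmcmc = tmcmc_config(),
                          seed = 1, model_prior = NULL) {
  if (!length(models)) stop("empty model list")
  rcfg <- if (inherits(config, "solver_config_resolved")) config
          else resolve_solver(config, net, waveform)
  evals <- vector("list", length(models))
  failed <- logical(length(models))
  for (i in seq_along(models)) {
    evals[[i]] <- tryCatch(
      evaluate_model(models[[i]], obs, net, waveform, rcfg, tmcmc,
                     seed = seed + 1000L * i),
      error = function(e) {
        warning("model ", models[[i]]$id, " failed: ", conditionMessage(e))
        NULL
      })
    failed[i] <- is.null(evals[[i]])
  }
  ok <- !failed
  if (!any(ok)) stop("every model evaluation failed")
  le <- vapply(evals[ok], `[[`, 0.0, "log_evidence")
  names(le) <- vapply(models[ok], `[[`, "", "id")
  pr <- model_posterior(le, if (is.null(model_prior)) NULL
                            else model_prior[ok] / sum(model_prior[ok]))
  rows <- lapply(which(ok), function(i) {
    sm <- evals[[i]]$summary
    isd <- sm$parameter == "sigma"
    def <- !isd & sm$parameter != "viscosity_scale"
    data.frame(
      model = models[[i]]$id,
      estimate = paste(sprintf("%.4g", sm$mean[def]), collapse = ", "),
      u_pct = paste(sprintf("%.3g", sm$cov_pct[def]), collapse = ", "),
      sigma_hat = sm$mean[isd],
      u_sigma_pct = sm$cov_pct[isd],
      log_evidence = evals[[i]]$log_evidence,
      probability = unname(pr[models[[i]]$id]))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, evaluations = evals,
                 probabilities = pr, log_evidence = le,
                 winner = names(pr)[which.max(pr)],
                 incomplete = any(failed), seed = seed),
            class = "defect_selection")
}

#' @export
print.defect_selection <- function(x, digits = 4, ...) {
  tab <- x$table
  tab$probability <- ifelse(tab$probability < 1e-8, "~0",
                            sprintf("%.5f", tab$probability))
  tab$log_evidence <- sprintf("%.1f", tab$log_evidence)
  cat("defect_selection (winner: ", x$winner, ")\n", sep = "")
  if (x$incomplete) cat("  [incomplete: some model evaluations failed]\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Save a selection result as JSON + CSV
#'
#' Writes `<stem>.json` (probabilities, log-evidences, winner, seed at full
#' precision) and `<stem>_table.csv` (the result table).
#'
#' @param result A `defect_selection`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_selection_result <- function(result, stem) {
  jsonlite::write_json(
    list(winner = result$winner,
         probabilities = as.list(result$probabilities),
         log_evidence = as.list(result$log_evidence),
         seed = result$seed),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$table, paste0(stem, "_table.csv"),
                   row.names = FALSE)
  invisible(stem)
}
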