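#' Pooled velocity scale
#'
#' Population standard deviation (n denominator) of all clean velocity
#' samples pooled across sensors and times. The observation noise SD is
#' specified as a fraction of this scale, so using the population convention
#' makes the injected sigma exactly reproducible.
#'
#' @param velocities Numeric vector or matrix of clean velocities.
#' @return The pooled scale eta, m/s.
#' @export
pooled_scale <- function(velocities) {
  v <- as.numeric(velocities)
  if (length(v) < 2) stop("need at least 2 velocity values")
  sqrt(mean((v - mean(v))^2))
}

#' Add Gaussian observation noise to simulated velocities
#'
#' Corrupts each clean sample v_k as D_k = v_k + sigma * eps_k with
#' independent standard-normal eps_k and sigma = `fraction` times the pooled
#' velocity scale of the experiment (see [pooled_scale()]).
#'
#' @param sim A [simulate_flow()] result, or a samples x sensors matrix.
#' @param fraction Noise fraction (e.g. 0.01 for 1\% noise).
#' @param seed Integer seed; noise is reproducible given the seed.
#' @return An object of class `observation_set` with the noisy `data`
#'   matrix, the `clean` matrix, `sigma`, `eta`, `fraction`, `seed`, and the
#'   sensor/time layout.
#' @export
add_noise <- function(sim, fraction, seed = 1) {
  stopifnot(fraction >= 0)
  clean <- if (inherits(sim, "pw_simulation")) sim$velocity else as.matrix(sim)
  eta <- pooled_scale(clean)
  sigma <- fraction * eta
  rng <- local_rng(seed)
  on.exit(rng())
  noise <- matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean))
  structure(list(
    data = clean + sigma * noise, clean = clean,
    sigma = sigma, eta = eta, fraction = fraction, seed = seed,
    times = if (inherits(sim, "pw_simulation")) sim$times else NULL,
    sensors = if (inherits(sim, "pw_simulation")) sim$sensors else NULL),
    class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf(
    "observation_set: %d samples x %d sensors, sigma = %.3g m/s (%.3g x eta = %.3g)\n",
    nrow(x$data), ncol(x$data), x$sigma, x$fraction, x$eta))
  if (!is.null(x$truth))
    cat("  ground truth attached (synthetic dataset)\n")
  invisible(x)
}

#' Multiplicatively perturb the relaxed areas of a network
#'
#' Models systemic misspecification of the 'known' healthy geometry: each
#' artery's relaxed area is multiplied by an independent (1 + sigma_alpha *
#' eps_k), eps_k standard normal, while the stored reference values are kept
#' unchanged. Data generated from the perturbed network can therefore not be
#' reproduced exactly by any parameter setting of an inference model built on
#' the reference values.
#'
#' @param net An [artery_network()].
#' @param sigma_alpha Parameter noise level (>= 0).
#' @param seed Integer seed.
#' @param on_nonpositive `"error"` or `"resample"`: what to do if a draw
#'   makes an area non-positive.
#' @return The perturbed network.
#' @export
perturb_reference_areas <- function(net, sigma_alpha, seed = 1,
                                    on_nonpositive = c("error", "resample")) {
  on_nonpositive <- match.arg(on_nonpositive)
  stopifnot(sigma_alpha >= 0)
  if (sigma_alpha == 0) return(net)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(net$arteries)
  fac <- 1 + sigma_alpha * stats::rnorm(n)
  if (any(fac <= 0)) {
    if (on_nonpositive == "error")
      stop("area perturbation produced a non-positive area; ",
           "reduce sigma_alpha or use on_nonpositive = 'resample'")
    for (tries in 1:100) {
      bad <- fac <= 0
      if (!any(bad)) break
      fac[bad] <- 1 + sigma_alpha * stats::rnorm(sum(bad))
    }
    if (any(fac <= 0)) stop("could not draw positive area factors")
  }
  net$arteries$area <- net$arteries$area * fac
  net$arteries$alpha <- net$arteries$area / net$arteries$ref_area
  net
}

#' Generate a synthetic noisy dataset with known ground truth
#'
#' End-to-end fixture generator: injects a defect into the reference
#' network, optionally corrupts all relaxed areas (systemic
#' misspecification), simulates the flow, and adds observation noise. The
#' returned observation set carries a ground-truth sidecar (`$truth`) with
#' the defect, injected sigma, eta and all seeds.
#'
#' Observation noise and parameter noise use separate RNG streams derived
#' from the master seed by fixed offsets, so e.g. the same observation noise
#' can be replayed with and without misspecification.
#'
#' @param net Reference [artery_network()].
#' @param defect A [defect_spec()] or `NULL`.
#' @param waveform,config,sensors Simulation setup; `config` is resolved
#'   against the reference network so that inference re-uses the identical
#'   discretization.
#' @param fraction Observation noise fraction.
#' @param sigma_alpha Parameter noise level for relaxed areas (0 = off).
#' @param seed Master seed.
#' @return An `observation_set` with `$truth` attached.
#' @export
generate_dataset <- function(net, defect = NULL, waveform = inflow_waveform(),
                             config = solver_config(), sensors,
                             fraction = 0.01, sigma_alpha = 0, seed = 1) {
  rcfg <- if (inherits(config, "solver_config_resolved")) config
          else resolve_solver(config, net, waveform)
  noise_seed <- seed + 101L
  area_seed <- seed + 211L
  net_true <- apply_defect(net, defect)
  if (sigma_alpha > 0)
    net_true <- perturb_reference_areas(net_true, sigma_alpha, area_seed)
  sim <- simulate_flow(net_true, waveform, rcfg, sensors)
  obs <- add_noise(sim, fraction, noise_seed)
  obs$truth <- list(defect = defect, sigma = obs$sigma, eta = obs$eta,
                    fraction = fraction, sigma_alpha = sigma_alpha,
                    seed = seed, noise_seed = noise_seed,
                    area_seed = area_seed,
                    true_areas = net_true$arteries$area)
  obs
}

#' Write observations to CSV (with a metadata sidecar)
#'
#' The CSV has columns `sensor_id`, `time_s`, `velocity_m_s`; a YAML sidecar
#' (`<path>.meta.yaml`) stores sigma, eta, fraction, seed, the sensor layout
#' and any ground truth. Externally produced files in the same schema can be
#' read back with [read_observations()] (the entry point for real data).
#'
#' @param obs An `observation_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  ns <- ncol(obs$data)
  nt <- nrow(obs$data)
  times <- if (is.null(obs$times)) seq_len(nt) else obs$times
  df <- data.frame(sensor_id = rep(seq_len(ns), each = nt),
                   time_s = rep(times, ns),
                   velocity_m_s = as.vector(obs$data))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sigma = obs$sigma, eta = obs$eta, fraction = obs$fraction,
               seed = obs$seed)
  if (!is.null(obs$sensors))
    meta$sensors <- lapply(seq_len(nrow(obs$sensors)), function(i)
      list(sensor_id = obs$sensors$sensor_id[i],
           artery = obs$sensors$artery[i],
           position = obs$sensors$position[i]))
  if (!is.null(obs$truth)) {
    tr <- obs$truth
    meta$truth <- list(
      fraction = tr$fraction, sigma = tr$sigma, eta = tr$eta,
      sigma_alpha = tr$sigma_alpha, seed = tr$seed,
      defect = if (is.null(tr$defect)) NULL else
        list(artery = tr$defect$artery, parameter = tr$defect$parameter,
             factor = tr$defect$factor))
  }
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' Read observations from CSV
#'
#' @param path CSV path written by [write_observations()] or following the
#'   same schema (`sensor_id`, `time_s`, `velocity_m_s`).
#' @return An `observation_set` (clean signal unknown, `clean = NULL`).
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  req <- c("sensor_id", "time_s", "velocity_m_s")
  if (!all(req %in% names(df)))
    stop("observation file must have columns ", paste(req, collapse = ", "))
  sid <- sort(unique(df$sensor_id))
  times <- sort(unique(df$time_s))
  D <- matrix(NA_real_, length(times), length(sid))
  for (j in seq_along(sid)) {
    sub <- df[df$sensor_id == sid[j], ]
    D[, j] <- sub$velocity_m_s[match(times, sub$time_s)]
  }
  obs <- structure(list(data = D, clean = NULL, sigma = NA_real_,
                        eta = NA_real_, fraction = NA_real_, seed = NA,
                        times = times, sensors = NULL),
                   class = "observation_set")
  mp <- paste0(path, ".meta.yaml")
  if (file.exists(mp)) {
    meta <- yaml::read_yaml(mp)
    obs$sigma <- meta$sigma %||% NA_real_
    obs$eta <- meta$eta %||% NA_real_
    obs$fraction <- meta$fraction %||% NA_real_
    obs$seed <- meta$seed %||% NA
    if (!is.null(meta$truth)) obs$truth <- meta$truth
  }
  obs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
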