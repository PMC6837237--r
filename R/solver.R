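#' Solver configuration for the discontinuous Galerkin scheme
#'
#' Controls the spatial discretization (elements per artery, polynomial
#' degree), time stepping and junction Newton iteration. When `dt` is `NULL`
#' the time step is resolved from a CFL-type bound against the reference
#' network (see [resolve_solver()]): `dt = cfl * h_min / ((2p + 1) * s_max)`
#' with `s_max` a conservative signal-speed estimate including `headroom`
#' times the largest resting wave speed, then rounded down so that the
#' sampling period `sample_period` is an exact integer multiple of `dt`.
#'
#' @param elements Elements per artery (N >= 1).
#' @param degree Legendre polynomial degree p >= 0.
#' @param dt Time step, s, or `NULL` to choose by the CFL bound.
#' @param final_time Total simulated time T, s; `NULL` rounds the waveform's
#'   `n_cycles * period` up to a whole number of sampling periods.
#' @param sample_period Sensor sampling period (s); default 0.064.
#' @param cfl CFL number used when choosing `dt` (<= 0.5).
#' @param headroom Multiplier on resting wave speeds when bounding the signal
#'   speed; covers stiffness perturbations up to `headroom^2` during
#'   inference sweeps.
#' @param newton_tol Convergence tolerance for the junction Newton solve
#'   (scaled residuals).
#' @param newton_maxit Maximum Newton iterations per junction solve.
#' @param check_cfl_every Audit the CFL bound every this many steps.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(elements = 4, degree = 2, dt = NULL,
                          final_time = NULL, sample_period = 0.064,
                          cfl = 0.25, headroom = 2.0,
                          newton_tol = 1e-13, newton_maxit = 25,
                          check_cfl_every = 200) {
  stopifnot(elements >= 1, degree >= 0, cfl > 0, cfl <= 0.5,
            sample_period > 0, newton_tol > 0)
  if (!is.null(dt) && !(dt > 0)) stop("dt must be positive")
  structure(list(elements = as.integer(elements), degree = as.integer(degree),
                 dt = dt, final_time = final_time,
                 sample_period = sample_period, cfl = cfl,
                 headroom = headroom, newton_tol = newton_tol,
                 newton_maxit = as.integer(newton_maxit),
                 check_cfl_every = as.integer(check_cfl_every)),
            class = "solver_config")
}

# Orthonormal Legendre basis values phi_k(x) = sqrt(k + 1/2) P_k(x) and,
# optionally, derivatives, for x in (-1, 1). Returns length(x) x (p+1).
legendre_basis <- function(x, p, deriv = FALSE) {
  n <- length(x)
  P <- matrix(0, n, p + 1)
  P[, 1] <- 1
  if (p >= 1) P[, 2] <- x
  if (p >= 2) for (k in 1:(p - 1))
    P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
  scale <- sqrt(seq(0, p) + 0.5)
  if (!deriv) return(sweep(P, 2, scale, `*`))
  D <- matrix(0, n, p + 1)
  if (p >= 1) for (k in 1:p) {
    at_edge <- abs(abs(x) - 1) < 1e-14
    D[!at_edge, k + 1] <- k * (P[!at_edge, k] - x[!at_edge] * P[!at_edge, k + 1]) /
      (1 - x[!at_edge]^2)
    D[at_edge, k + 1] <- sign(x[at_edge])^(k + 1) * k * (k + 1) / 2
  }
  sweep(D, 2, scale, `*`)
}

# Quadrature + basis tables shared by the C++ stepper.
dg_basis <- function(degree) {
  nq <- max(degree + 1, 2)
  gl <- pracma::gaussLegendre(nq, -1, 1)
  list(qx = gl$x, qw = gl$w,
       V = legendre_basis(gl$x, degree),
       Vd = legendre_basis(gl$x, degree, deriv = TRUE),
       phiL = drop(legendre_basis(-1, degree)),
       phiR = drop(legendre_basis(1, degree)))
}

# Flatten an artery_network into the 0-based arrays the C++ core expects.
net_to_cpp <- function(net) {
  a <- net$arteries
  kid <- matrix(-1L, nrow(a), 2)
  for (i in seq_len(nrow(a))) {
    ch <- sort(a$id[a$parent == a$id[i]])
    if (length(ch) == 2) kid[i, ] <- match(ch, a$id) - 1L
  }
  list(length = a$length, area = a$area, stiffness = a$stiffness,
       parent = ifelse(a$parent == 0, -1L, match(a$parent, a$id) - 1L),
       child1 = kid[, 1], child2 = kid[, 2],
       inlet = match(net$inlet, a$id) - 1L,
       density = net$fluid$density, p_ext = net$fluid$p_ext,
       Kr = net$fluid$Kr)
}

#' Resolve a solver configuration against a network and waveform
#'
#' Fixes the time step, step counts and quadrature tables so that repeated
#' simulations (e.g. the forward sweeps of an inference run) all share one
#' discretization. The time step is chosen against the *reference* geometry
#' with a `headroom` factor so that perturbed stiffness/area values explored
#' during inference remain CFL-stable.
#'
#' @param config A [solver_config()].
#' @param net The reference [artery_network()].
#' @param waveform An [inflow_waveform()].
#' @return A resolved config (class `solver_config_resolved`) with `dt`,
#'   `n_steps`, `sample_stride`, `final_time` and basis tables fixed.
#' @export
resolve_solver <- function(config, net, waveform) {
  a <- net$arteries
  cref <- sqrt(a$ref_stiffness / (2 * net$fluid$density)) * a$ref_area^0.25
  tg <- seq(0, waveform$period, length.out = 512)
  umax <- max(abs(waveform_velocity(waveform, tg)))
  smax <- config$headroom * max(cref) + 2 * umax
  hmin <- min(a$length) / config$elements
  if (is.null(config$dt)) {
    dt_req <- config$cfl * hmin / ((2 * config$degree + 1) * smax)
    stride <- ceiling(config$sample_period / dt_req)
  } else {
    stride <- round(config$sample_period / config$dt)
    if (stride < 1 || abs(stride * config$dt - config$sample_period) >
        1e-9 * config$sample_period)
      stop("sample_period must be an integer multiple of dt")
  }
  dt <- config$sample_period / stride
  final_time <- config$final_time
  if (is.null(final_time))
    final_time <- ceiling(waveform$n_cycles * waveform$period /
                          config$sample_period) * config$sample_period
  n_samples <- floor(final_time / config$sample_period + 1e-9)
  n_steps <- round(final_time / dt)
  out <- config
  out$dt <- dt
  out$sample_stride <- as.integer(stride)
  out$n_steps <- as.integer(n_steps)
  out$n_samples <- as.integer(n_samples)
  out$final_time <- final_time
  out$basis <- dg_basis(config$degree)
  out$cfl_limit <- 0.5
  class(out) <- c("solver_config_resolved", "solver_config")
  out
}

#' Sensor configuration
#'
#' Velocity sensors at fixed positions along arteries. Positions may be the
#' keywords `"start"`/`"end"` (x = 0 / x = artery length) or a numeric
#' coordinate in metres from the upstream end.
#'
#' @param artery Integer vector of artery ids.
#' @param position Character or numeric vector, recycled against `artery`.
#' @return A data frame of class `sensor_config` with columns `sensor_id`,
#'   `artery`, `position`.
#' @export
sensor_config <- function(artery, position = "end") {
  n <- max(length(artery), length(position))
  artery <- rep_len(as.integer(artery), n)
  position <- rep_len(position, n)
  if (n < 1) stop("sensor configuration must be non-empty")
  out <- data.frame(sensor_id = seq_len(n), artery = artery,
                    position = as.character(position),
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_config", "data.frame")
  out
}

# Resolve sensors against network + config: element indices and local basis.
sensors_to_cpp <- function(sensors, net, rcfg) {
  a <- net$arteries
  idx <- match(sensors$artery, a$id)
  if (anyNA(idx))
    stop("sensor references unknown artery ",
         paste(sensors$artery[is.na(idx)], collapse = ", "))
  x <- numeric(nrow(sensors))
  for (i in seq_len(nrow(sensors))) {
    p <- sensors$position[i]
    L <- a$length[idx[i]]
    x[i] <- if (p == "start") 0 else if (p == "end") L else {
      xv <- suppressWarnings(as.numeric(p))
      if (is.na(xv) || xv < 0 || xv > L)
        stop("sensor ", i, ": position must be 'start', 'end' or in [0, ",
             signif(L, 4), "]")
      xv
    }
  }
  Ne <- rcfg$elements
  h <- a$length[idx] / Ne
  elem <- pmin(pmax(floor(x / h), 0), Ne - 1)
  xi <- 2 * (x - elem * h) / h - 1
  phi <- t(legendre_basis(xi, rcfg$degree))  # Np x nsens
  list(artery = as.integer(idx - 1L), element = as.integer(elem),
       phi = phi, x = x)
}

#' Simulate pulse-wave propagation on a network
#'
#' Advances the nonlinear 1D flow equations from rest (u = 0, A = A0) under
#' the given inflow waveform and records velocity at each sensor every
#' `sample_period` seconds, from `t = sample_period` to the final time.
#' Output is deterministic: identical inputs give bit-identical records.
#'
#' @param net An [artery_network()].
#' @param waveform An [inflow_waveform()].
#' @param config A [solver_config()] or the result of [resolve_solver()].
#'   Unresolved configs are resolved against `net` (so perturbed copies of a
#'   reference network should be simulated with a config resolved against the
#'   reference; see [resolve_solver()]).
#' @param sensors A [sensor_config()].
#' @return An object of class `pw_simulation`: `records` (long data frame
#'   with sensor_id, artery_id, position, time_s, velocity_m_s), `velocity`
#'   (samples x sensors matrix), `times`, `state`, `diagnostics`, and the
#'   resolved `config`.
#' @export
simulate_flow <- function(net, waveform, config = solver_config(), sensors) {
  rcfg <- if (inherits(config, "solver_config_resolved")) config
          else resolve_solver(config, net, waveform)
  sc <- sensors_to_cpp(sensors, net, rcfg)
  res <- cpp_run(net_to_cpp(net),
                 list(period = waveform$period,
                      cos_coef = waveform$cos_coef,
                      sin_coef = waveform$sin_coef),
                 rcfg, sc, list())
  nrec <- nrow(res$velocity)
  records <- data.frame(
    sensor_id = rep(sensors$sensor_id, each = nrec),
    artery_id = rep(sensors$artery, each = nrec),
    position = rep(sc$x, each = nrec),
    time_s = rep(res$times, times = nrow(sensors)),
    velocity_m_s = as.vector(res$velocity))
  structure(list(records = records, velocity = res$velocity,
                 times = res$times, state = res$state,
                 diagnostics = res$diagnostics, config = rcfg,
                 sensors = sensors, waveform = waveform),
            class = "pw_simulation")
}

#' @export
print.pw_simulation <- function(x, ...) {
  cat(sprintf(
    "pw_simulation: %d sensors x %d samples (dt = %.3g s, %d steps)\n",
    ncol(x$velocity), nrow(x$velocity), x$config$dt, x$diagnostics$n_steps))
  cat(sprintf("  max junction mass residual %.3g m^3/s\n",
              x$diagnostics$junction_mass_residual))
  invisible(x)
}

#' Advance the solver state by a number of time steps
#'
#' Low-level access to the time stepper, mainly for testing conservation and
#' steady-state properties. Starting from `state = NULL` initializes the rest
#' state. The returned state carries the previous right-hand side so that
#' repeated calls continue the Adams-Bashforth history exactly.
#'
#' @param net,waveform,config As in [simulate_flow()].
#' @param state A state list from a previous call, or `NULL` for rest.
#' @param n_steps Number of time steps to advance.
#' @return A list with the updated modal coefficients (`Ah`, `uh`), time,
#'   step counter, accumulated boundary mass influx, and diagnostics.
#' @export
dg_step <- function(net, waveform, config = solver_config(), state = NULL,
                    n_steps = 1) {
  rcfg <- if (inherits(config, "solver_config_resolved")) config
          else resolve_solver(config, net, waveform)
  rcfg$n_steps <- as.integer(n_steps)
  rcfg$sample_stride <- 0L
  sc <- list(artery = integer(0), element = integer(0),
             phi = matrix(0, rcfg$degree + 1, 0))
  res <- cpp_run(net_to_cpp(net),
                 list(period = waveform$period, cos_coef = waveform$cos_coef,
                      sin_coef = waveform$sin_coef),
                 rcfg, sc, if (is.null(state)) list() else state)
  st <- res$state
  st$diagnostics <- res$diagnostics
  st
}

#' Reconstruct a field from modal coefficients
#'
#' Evaluates the element-local Legendre expansion of area or velocity at
#' arbitrary positions along one artery.
#'
#' @param state A state list from [dg_step()] or `sim$state`.
#' @param net,config The network and (resolved or not) config used to
#'   produce the state.
#' @param artery Artery id.
#' @param x Positions along the artery, m.
#' @param field `"velocity"` or `"area"`.
#' @return Numeric vector of field values at `x`.
#' @export
evaluate_field <- function(state, net, config, artery, x,
                           field = c("velocity", "area")) {
  field <- match.arg(field)
  a <- net$arteries
  i <- match(artery, a$id)
  if (is.na(i)) stop("unknown artery ", artery)
  Ne <- config$elements
  Np <- config$degree + 1
  h <- a$length[i] / Ne
  coef <- if (field == "velocity") state$uh else state$Ah
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    e <- min(max(floor(x[j] / h), 0), Ne - 1)
    xi <- 2 * (x[j] - e * h) / h - 1
    phi <- drop(legendre_basis(xi, config$degree))
    off <- ((i - 1) * Ne + e) * Np
    out[j] <- sum(coef[off + seq_len(Np)] * phi)
  }
  out
}

#' Solve the Y-bifurcation coupling conditions
#'
#' Given the outgoing characteristic of the parent (`W1 = u + 4c`) and of
#' each child (`W2 = u - 4c`), solves for the six coupled boundary values
#' (A, u per artery) enforcing conservation of mass flux and continuity of
#' total pressure `p + rho u^2 / 2` across the bifurcation, by Newton
#' iteration.
#'
#' @param area0 Relaxed areas (parent, child1, child2), m^2.
#' @param stiffness Tube-law stiffnesses, Pa/m.
#' @param W1_parent Outgoing characteristic of the parent, m/s.
#' @param W2_children Outgoing characteristics of the two children, m/s
#'   (length 2).
#' @param density Fluid density, kg/m^3.
#' @param tol,maxit Newton tolerance (scaled residuals) and iteration cap.
#' @return List with `area`, `velocity` (length 3 each), the physical
#'   residuals `residual_mass` (m^3/s) and `residual_pressure` (Pa), and the
#'   iteration count.
#' @export
junction_solve <- function(area0, stiffness, W1_parent, W2_children,
                           density = 1060, tol = 1e-13, maxit = 25) {
  stopifnot(length(W2_children) == 2)
  cpp_junction_solve(area0, stiffness, density, W1_parent,
                     W2_children[1], W2_children[2], tol, as.integer(maxit))
}

#' Total blood volume held in the network state
#'
#' Discrete integral of A over all arteries, from the modal coefficients
#' (only the constant mode contributes).
#'
#' @param state State list from [dg_step()].
#' @param net,config Network and config used to produce the state.
#' @return Volume in m^3.
#' @export
state_volume <- function(state, net, config) {
  a <- net$arteries
  Ne <- config$elements
  Np <- config$degree + 1
  phi0 <- drop(legendre_basis(0, 0))  # 1/sqrt(2)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    h <- a$length[i] / Ne
    for (e in seq_len(Ne) - 1) {
      off <- ((i - 1) * Ne + e) * Np
      tot <- tot + h * state$Ah[off + 1] * phi0
    }
  }
  tot
}
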