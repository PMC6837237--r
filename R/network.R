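#' Fluid properties for blood
#'
#' Bundles the fluid constants used by the flow model: density \eqn{\rho},
#' dynamic viscosity \eqn{\mu}, external pressure \eqn{p_{ext}}, and the
#' derived friction coefficient \eqn{K_r = -22 \mu \pi} (viscous resistance
#' per unit length for the assumed velocity profile).
#'
#' @param density Blood density in kg/m^3 (default 1060, standard for blood).
#' @param viscosity Dynamic viscosity in Pa s (default reference value 0.0045).
#' @param p_ext External pressure in Pa.
#' @return A list of class `blood_fluid` with fields `density`, `viscosity`,
#'   `p_ext` and the derived `Kr`.
#' @export
blood_fluid <- function(density = 1060, viscosity = 0.0045, p_ext = 0) {
  stopifnot(density > 0, viscosity >= 0)
  structure(list(density = density, viscosity = viscosity, p_ext = p_ext,
                 Kr = -22 * viscosity * pi),
            class = "blood_fluid")
}

#' Branching arterial network
#'
#' Builds a rooted binary tree of artery segments. Each non-terminal artery
#' has exactly two children (a Y-bifurcation); the root is the inlet. Every
#' artery carries its current stiffness `B` and relaxed area `A0` together
#' with reference values, so the dimensionless defect parameters
#' \eqn{\beta = B/B^*} and \eqn{\alpha = A_0/A_0^*} are always available
#' (both equal 1 for a healthy artery).
#'
#' @param arteries Data frame with columns `id` (integer), `parent` (integer,
#'   0 for the inlet artery), `length` (m), `area` (relaxed cross-sectional
#'   area, m^2) and `stiffness` (tube-law coefficient B, Pa/m). Optional
#'   columns `ref_area` and `ref_stiffness` give the healthy reference values
#'   (default: the current values).
#' @param fluid A [blood_fluid()] object.
#' @return An object of class `artery_network`.
#' @export
artery_network <- function(arteries, fluid = blood_fluid()) {
  req <- c("id", "parent", "length", "area", "stiffness")
  miss <- setdiff(req, names(arteries))
  if (length(miss))
    stop("arteries is missing columns: ", paste(miss, collapse = ", "))
  arteries <- as.data.frame(arteries)
  if (is.null(arteries$ref_area)) arteries$ref_area <- arteries$area
  if (is.null(arteries$ref_stiffness)) arteries$ref_stiffness <- arteries$stiffness
  for (i in seq_len(nrow(arteries))) {
    a <- arteries[i, ]
    if (!(a$length > 0) || !(a$area > 0) || !(a$stiffness > 0) ||
        !(a$ref_area > 0) || !(a$ref_stiffness > 0))
      stop("artery ", a$id, ": length, area and stiffness must all be positive")
  }
  if (anyDuplicated(arteries$id))
    stop("duplicated artery ids: ",
         paste(unique(arteries$id[duplicated(arteries$id)]), collapse = ", "))
  arteries <- arteries[order(arteries$id), , drop = FALSE]
  rownames(arteries) <- NULL
  arteries$beta <- arteries$stiffness / arteries$ref_stiffness
  arteries$alpha <- arteries$area / arteries$ref_area

  roots <- arteries$id[arteries$parent == 0]
  if (length(roots) != 1)
    stop("network must have exactly one inlet artery (parent = 0); found ",
         length(roots))
  for (i in seq_len(nrow(arteries))) {
    p <- arteries$parent[i]
    if (p != 0 && !(p %in% arteries$id))
      stop("artery ", arteries$id[i], ": parent ", p, " does not exist")
  }
  # children, ordered by ascending id
  kids <- split(arteries$id, factor(arteries$parent, levels = arteries$id))
  nkid <- lengths(kids)
  bad <- names(nkid)[!(nkid %in% c(0L, 2L))]
  if (length(bad))
    stop("artery ", bad[1], " has ", nkid[bad[1]],
         " children; every non-terminal artery must have exactly 2")
  # tree check: every artery must reach the root
  idx <- match(arteries$parent, arteries$id)
  for (i in seq_len(nrow(arteries))) {
    seen <- integer(0); j <- i
    while (!is.na(j)) {
      if (j %in% seen) stop("cycle detected through artery ", arteries$id[i])
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  structure(list(arteries = arteries, fluid = fluid,
                 inlet = roots,
                 terminal = arteries$id[!(arteries$id %in% arteries$parent)]),
            class = "artery_network")
}

#' @export
print.artery_network <- function(x, ...) {
  a <- x$arteries
  cat("artery_network: ", nrow(a), " arteries, inlet ", x$inlet, ", ",
      length(x$terminal), " terminals\n", sep = "")
  cat(sprintf("  lengths %.3f-%.3f m, areas %.2e-%.2e m^2\n",
              min(a$length), max(a$length), min(a$area), max(a$area)))
  ndef <- sum(a$beta != 1 | a$alpha != 1)
  if (ndef > 0)
    cat("  defects on arteries:",
        paste(a$id[a$beta != 1 | a$alpha != 1], collapse = ", "), "\n")
  invisible(x)
}

#' Tube-law transmural pressure
#'
#' Elastic (Laplace) tube law \eqn{p = p_{ext} + B(\sqrt{A} - \sqrt{A_0})}
#' relating cross-sectional area to internal pressure. The stiffness
#' coefficient collects the wall properties,
#' \eqn{B = \sqrt{\pi} E h / ((1-\nu^2) A_0)} with Poisson ratio 1/2.
#'
#' @param A Cross-sectional area(s), m^2. Must be positive.
#' @param geom A list or one-row data frame with fields `stiffness` (B, Pa/m)
#'   and `area` (relaxed area A0, m^2), e.g. a row of `net$arteries`.
#' @param p_ext External pressure, Pa.
#' @return Internal pressure(s) in Pa; equals `p_ext` at `A = A0` and is
#'   strictly increasing in `A`.
#' @export
tube_law_pressure <- function(A, geom, p_ext = 0) {
  if (any(!is.finite(A)) || any(A <= 0))
    stop("cross-sectional area must be positive and finite")
  p_ext + geom$stiffness * (sqrt(A) - sqrt(geom$area))
}

#' Pulse-wave speed
#'
#' Characteristic wave speed of the elastic tube law,
#' \eqn{c = \sqrt{(A/\rho)\,\partial p/\partial A} = \sqrt{B/(2\rho)}\,A^{1/4}}.
#'
#' @inheritParams tube_law_pressure
#' @param density Fluid density, kg/m^3.
#' @return Wave speed(s) in m/s.
#' @export
wave_speed <- function(A, geom, density = 1060) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("area must be positive")
  if (!(density > 0)) stop("density must be positive")
  sqrt(geom$stiffness / (2 * density)) * A^0.25
}

#' Seeded fixture network generator
#'
#' Generates a full Y-bifurcating tree of `n_arteries` segments with
#' randomized geometry: lengths uniform on [0.026, 0.17] m and relaxed areas
#' in [1e-6, 1e-5] m^2 (tapering with depth so daughters are no wider than
#' their parent's range), with stiffness chosen so that the resting pulse-wave
#' speed of each artery lies in `wave_speed_range`. Topology is the
#' breadth-first complete tree: artery `i` has children `2i` and `2i + 1`.
#' Reference values equal the generated values, so beta = alpha = 1
#' everywhere.
#'
#' @param n_arteries Odd integer >= 3 (every bifurcation adds two arteries).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param wave_speed_range Range of resting wave speeds, m/s.
#' @param fluid A [blood_fluid()] object.
#' @return An [artery_network()].
#' @export
build_fixture_network <- function(n_arteries = 19, seed = 1,
                                  wave_speed_range = c(4, 6),
                                  fluid = blood_fluid()) {
  if (n_arteries < 3 || n_arteries %% 2 == 0)
    stop("n_arteries must be odd and >= 3 (full bifurcating tree)")
  rng <- local_rng(seed)
  on.exit(rng())
  ids <- seq_len(n_arteries)
  parent <- ifelse(ids == 1, 0L, ids %/% 2L)
  depth <- floor(log2(ids))
  maxd <- max(depth)
  len <- stats::runif(n_arteries, 0.026, 0.17)
  # areas taper with depth inside the printed range [1e-6, 1e-5]
  lo <- -6; hi <- -5
  frac <- if (maxd > 0) depth / maxd else rep(0, n_arteries)
  lg <- hi - frac * 0.7 + stats::runif(n_arteries, -0.15, 0.15)
  area <- 10^pmin(pmax(lg, lo), hi)
  c0 <- stats::runif(n_arteries, wave_speed_range[1], wave_speed_range[2])
  stiffness <- 2 * fluid$density * c0^2 / sqrt(area)
  artery_network(data.frame(id = ids, parent = parent, length = len,
                            area = area, stiffness = stiffness),
                 fluid = fluid)
}

#' Structural defect specification
#'
#' A defect multiplies one artery's reference stiffness or relaxed area by a
#' factor: an aneurysm is typically modelled as enlarged area (alpha > 1) or
#' reduced stiffness, a stenosis as reduced area (alpha < 1).
#'
#' @param artery Integer artery id.
#' @param parameter `"stiffness"` or `"area"`.
#' @param factor Positive multiplier applied to the reference value.
#' @return A list of class `defect_spec`.
#' @export
defect_spec <- function(artery, parameter = c("stiffness", "area"), factor) {
  parameter <- match.arg(parameter)
  if (!(factor > 0)) stop("defect factor must be positive")
  structure(list(artery = as.integer(artery), parameter = parameter,
                 factor = factor), class = "defect_spec")
}

#' Inject a structural defect into a network
#'
#' Returns a network identical to `net` except that the targeted artery's
#' stiffness or relaxed area is `factor` times its reference value, so its
#' scaled parameter (beta or alpha) equals `factor` exactly.
#'
#' @param net An [artery_network()].
#' @param defect A [defect_spec()], or `NULL` for no change.
#' @return The modified network.
#' @export
apply_defect <- function(net, defect) {
  if (is.null(defect)) return(net)
  stopifnot(inherits(net, "artery_network"), inherits(defect, "defect_spec"))
  i <- match(defect$artery, net$arteries$id)
  if (is.na(i)) stop("artery ", defect$artery, " not present in the network")
  if (defect$parameter == "stiffness") {
    net$arteries$stiffness[i] <- defect$factor * net$arteries$ref_stiffness[i]
    net$arteries$beta[i] <- defect$factor
  } else {
    net$arteries$area[i] <- defect$factor * net$arteries$ref_area[i]
    net$arteries$alpha[i] <- defect$factor
  }
  net
}

# Children of each artery (list indexed by id), ascending id within a pair.
network_children <- function(net) {
  a <- net$arteries
  lapply(a$id, function(id) sort(a$id[a$parent == id]))
}

#' Read a network configuration file
#'
#' Reads the YAML network format written by [write_network_config()]:
#' a `fluid` block and an `arteries` list with per-artery `id`, `parent`,
#' `length`, `area`, `stiffness` and optional reference values. All
#' structural invariants are validated; errors name the offending artery.
#'
#' @param path File path.
#' @return An [artery_network()].
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$arteries)) stop("network config has no 'arteries' block")
  arts <- do.call(rbind, lapply(cfg$arteries, function(a) {
    for (f in c("id", "parent", "length", "area", "stiffness"))
      if (is.null(a[[f]]))
        stop("artery entry ", deparse(a$id), ": missing field '", f, "'")
    data.frame(id = as.integer(a$id), parent = as.integer(a$parent),
               length = a$length, area = a$area, stiffness = a$stiffness,
               ref_area = if (is.null(a$ref_area)) a$area else a$ref_area,
               ref_stiffness = if (is.null(a$ref_stiffness)) a$stiffness
                               else a$ref_stiffness)
  }))
  fl <- cfg$fluid
  fluid <- blood_fluid(
    density = if (is.null(fl$density)) 1060 else fl$density,
    viscosity = if (is.null(fl$viscosity)) 0.0045 else fl$viscosity,
    p_ext = if (is.null(fl$p_ext)) 0 else fl$p_ext)
  artery_network(arts, fluid = fluid)
}

#' Write a network configuration file
#'
#' @param net An [artery_network()].
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_network_config <- function(net, path) {
  a <- net$arteries
  yaml::write_yaml(list(
    fluid = list(density = net$fluid$density, viscosity = net$fluid$viscosity,
                 p_ext = net$fluid$p_ext),
    arteries = lapply(seq_len(nrow(a)), function(i) list(
      id = a$id[i], parent = a$parent[i], length = a$length[i],
      area = a$area[i], stiffness = a$stiffness[i],
      ref_area = a$ref_area[i], ref_stiffness = a$ref_stiffness[i]))
  ), path, precision = 15)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`; returns a restore
# function for use with on.exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
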