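# Shared desk-scale fixtures: small seeded networks, a one-cycle inflow
# waveform, and a coarse (1 element, degree 1) discretization that keeps
# repeated forward solves cheap while exercising every code path
# (junction coupling, characteristic boundaries, AB2 stepping).

desk_wave <- function(cycles = 1) inflow_waveform(n_cycles = cycles)

desk_net <- function(n = 7, seed = 42) build_fixture_network(n, seed = seed)

desk_config <- function(net, wave, elements = 1, degree = 1, cfl = 0.3, ...) {
  resolve_solver(solver_config(elements = elements, degree = degree,
                               cfl = cfl, ...), net, wave)
}

# single straight vessel for solver-only tests
single_artery_net <- function(length = 0.2, area = 5e-6, c0 = 5,
                              fluid = blood_fluid()) {
  artery_network(data.frame(id = 1, parent = 0, length = length, area = area,
                            stiffness = 2 * fluid$density * c0^2 / sqrt(area)),
                 fluid = fluid)
}

zero_wave <- function() inflow_waveform(cos_coef = rep(0, 3),
                                        sin_coef = rep(0, 3), n_cycles = 1)

# one narrow systolic pulse followed by a long quiet window; enough
# harmonics that truncation ripple in the quiet window is negligible
pulse_wave <- function(period = 2, peak = 0.3) {
  inflow_waveform(period = period, n_cycles = 1, peak = peak,
                  systole_fraction = 0.1, n_harmonics = 64)
}
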