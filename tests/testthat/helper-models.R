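# Shared fixtures, all built in code.

# Two-group toy model: A is CD34+ with exponential inhibition, B mature with
# a mild spline response.
toy_model <- function(s = 2e-4, a = 0.4, b = -0.01) {
  culture_model(
    groups = list(
      phenotype_group("A", growth_correlation("exponential", a = a, b = b,
                                              domain = c(0, 600)),
                      w = 1, is_cd34 = TRUE),
      phenotype_group("B", growth_correlation("spline",
                                              knots_conc = c(0, 100, 300, 600),
                                              knots_rate = c(0.1, 0.15, 0.2, 0.2)),
                      w = 2)),
    secretion = secretion_correlation("constant_per_cell", s = s),
    V0 = 1, seed_density = 1e5)
}

# Concentration-independent toy (growth decoupled from the factor).
toy_model_const <- function(r1 = 0.25, r2 = 0.1, s = 2e-4) {
  culture_model(
    groups = list(
      phenotype_group("A", growth_correlation("exponential", a = r1, b = 0),
                      w = 1, is_cd34 = TRUE),
      phenotype_group("B", growth_correlation("exponential", a = r2, b = 0),
                      w = 1)),
    secretion = secretion_correlation("constant_per_cell", s = s),
    V0 = 1, seed_density = 1e5)
}

# Sampler over the toy groups; sigma = 0 gives deterministic draws.
toy_sampler <- function(sigma = 0, total = 1e5) {
  population_sampler(
    cd34_mu = stats::qlogis(0.5), cd34_sigma = sigma,
    cd38_mu = stats::qlogis(0.5), cd38_sigma = sigma,
    mapping = list(cd34pos_cd38neg = c(A = 1),
                   cd34pos_cd38pos = c(A = 1),
                   cd34neg = c(B = 1)),
    total_cells = total)
}

# Minimal simulation_result stand-in for metric tests built from an explicit
# piecewise-linear concentration trajectory.
fake_result <- function(time, C, N0 = c(A = 1e5, B = 1e5),
                        N1 = N0 * 10, V0 = 1, V1 = 10) {
  n <- length(time)
  traj <- data.frame(time = time,
                     A = seq(N0[["A"]], N1[["A"]], length.out = n),
                     B = seq(N0[["B"]], N1[["B"]], length.out = n),
                     M = C * seq(V0, V1, length.out = n),
                     V = seq(V0, V1, length.out = n),
                     C = C)
  structure(list(trajectory = traj,
                 events = data.frame(time = numeric(), type = character(),
                                     volume = numeric()),
                 state = list(V = V1, media_used = V1 - V0)),
            class = "simulation_result")
}

# Degenerate (zero-variance) sampler over the reference model's groups.
toy_sampler_ref <- function(sigma = 0) {
  population_sampler(
    cd34_mu = stats::qlogis(0.45), cd34_sigma = sigma,
    cd38_mu = stats::qlogis(0.75), cd38_sigma = sigma,
    mapping = list(
      cd34pos_cd38neg = c(HSC = 0.4, MPP = 0.6),
      cd34pos_cd38pos = c(CMP_GMP = 0.5, MEP = 0.5),
      cd34neg = c(EarlyMature = 0.4, NK = 0.1, T = 0.1, ERY = 0.2,
                  NEUT = 0.2)),
    total_cells = 1e5)
}

ref_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_calibration()
    cache
  }
})
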