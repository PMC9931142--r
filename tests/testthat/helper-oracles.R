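# Independent oracles used across the suite.
#
# The steady-state solvers in the package are algebraic (root finding /
# closed form); the oracles here integrate the corresponding ODEs to their
# long-time limit with deSolve, an entirely separate path to the same fixed
# point.

# Long-time limit of the Ras-GTP balance ODE.
ode_ras_gtp <- function(params, Rb, Qb, T0 = 0.5, t_end = 5000) {
  A <- params$Vs * Rb / (params$Ks + Rb)
  B <- params$Vrg * Qb / (params$Krg + Qb)
  rhs <- function(t, y, parms) {
    T <- y[1]
    list(A * (1 - T) / (params$K1 + 1 - T) -
           B * T / (params$K2 + T) - params$Kb * T)
  }
  out <- deSolve::ode(c(T = T0), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), "T"])
}

# Long-time limit of the activator phosphorylation cycle.
ode_activator <- function(erk_star, params, t_end = 5000) {
  rhs <- function(t, y, parms) {
    Ap <- y[1]
    list(params$kMM3 * erk_star * (1 - Ap) / (params$KMM3 + 1 - Ap) -
           params$vMM4 * Ap / (params$KMM4 + Ap))
  }
  out <- deSolve::ode(c(Ap = 0.5), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), "Ap"])
}

# Long-time limit of the repressor cycle.
ode_repressor <- function(erk_star, params, t_end = 5000) {
  rhs <- function(t, y, parms) {
    I <- y[1]
    list(params$vMM2 * (1 - I) / (params$KMM2 + 1 - I) -
           params$kMM1 * erk_star * I / (params$KMM1 + I))
  }
  out <- deSolve::ode(c(I = 0.5), times = c(0, t_end), func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), "I"])
}

# Residual of the Ras-GTP balance at a proposed root.
ras_residual <- function(params, Rb, Qb, T) {
  A <- params$Vs * Rb / (params$Ks + Rb)
  B <- params$Vrg * Qb / (params$Krg + Qb)
  A * (1 - T) / (params$K1 + 1 - T) - B * T / (params$K2 + T) - params$Kb * T
}

# Random parameter set within +-frac of the defaults (seeded by caller).
perturbed_parameters <- function(frac = 0.2) {
  p <- unclass(default_parameters())
  fields <- setdiff(names(p), c("coop", "I_clamp", "n_erk", "K_erk"))
  for (f in fields) p[[f]] <- p[[f]] * runif(1, 1 - frac, 1 + frac)
  # keep K_erk inside (0, 1) and n_erk >= 1 under perturbation
  p$K_erk <- min(0.99, p$K_erk * runif(1, 1 - frac, 1 + frac))
  p$n_erk <- max(1, p$n_erk * runif(1, 1 - frac, 1 + frac))
  class(p) <- "induction_params"
  validate_parameters(p)
}

# Log-spaced grid reaching the Hill plateau, for potency checks (the
# potency formula's "maximal response" is the domain supremum, so the
# domain must span saturation for the closed-form identity to hold).
saturating_grid <- function(K) c(0, K * 10^seq(-4, 4, length.out = 999))

# Ideal Hill curve generator for estimator self-consistency checks.
ideal_hill_curve <- function(n, K, xs = seq(0, 1, length.out = 201),
                             amplitude = 1, baseline = 0,
                             decreasing = FALSE) {
  frac <- xs^n / (xs^n + K^n)
  if (decreasing) frac <- 1 - frac
  list(xs = xs, ys = baseline + amplitude * frac)
}
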