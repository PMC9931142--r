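p <- default_parameters()

test_that("the empirical S2(S1) relation has the measured coefficients and clamps", {
  expect_equal(s2_from_s1(0), 0.91)
  expect_equal(s2_from_s1(0.91 / 1.13), 0, tolerance = 1e-12)
  expect_identical(s2_from_s1(1), 0)            # clamped, not -0.22
  expect_equal(s2_from_s1(0.3), -1.13 * 0.3 + 0.91)
  expect_error(s2_from_s1(1.2), "S1")
  # inverse relation is consistent on the unclamped branch
  s1 <- seq(0, 0.8, by = 0.05)
  expect_equal(s1_from_s2(s2_from_s1(s1)), s1, tolerance = 1e-12)
})

test_that("receptor occupancy follows equilibrium binding", {
  expect_equal(bound_receptors(2000, 0.3, 25, 25), 300)   # ligand = K: half
  expect_equal(bound_receptors(2000, 0.3, 0, 25), 0)
  expect_equal(bound_receptors(2000, 0.3, 5, 25), 100)    # 600 * 5/30
  expect_error(bound_receptors(2000, -0.1, 5, 25), "non-negative")
  # increasing and saturating in ligand
  lig <- seq(0, 500, by = 10)
  rb <- bound_receptors(2000, 0.3, lig, 25)
  expect_true(all(diff(rb) > 0))
  expect_lt(max(rb), 600)
})

test_that("Ras-GTP steady state handles boundary cases exactly", {
  expect_identical(ras_gtp_steady_state(p, 0, 500), 0)     # no production
  p0 <- apply_scenario(p, list(Kb = 0))
  expect_identical(ras_gtp_steady_state(p0, 300, 0), 1)    # no hydrolysis
})

test_that("Ras-GTP root satisfies the balance to 1e-10 across inputs", {
  grid <- expand.grid(Rb = c(1, 30, 100, 400, 1000),
                      Qb = c(0, 10, 100, 500, 1500))
  T <- ras_gtp_steady_state(p, grid$Rb, grid$Qb)
  expect_true(all(T >= 0 & T <= 1))
  res <- mapply(function(rb, qb, t) ras_residual(p, rb, qb, t),
                grid$Rb, grid$Qb, T)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("algebraic steady state agrees with long-time ODE integration", {
  # a representative default geometry point
  Rb <- bound_receptors(p$R_T, 0.3, p$fgf_conc, p$Kd)
  Qb <- bound_receptors(p$Q_T, s2_from_s1(0.3), p$ephrin_conc, p$Ke)
  expect_equal(ras_gtp_steady_state(p, Rb, Qb), ode_ras_gtp(p, Rb, Qb),
               tolerance = 1e-9)
  # 100 random parameter draws within +-20% of defaults
  set.seed(11)
  for (i in 1:100) {
    q <- perturbed_parameters()
    S1 <- runif(1, 0.02, 0.8)
    Rb <- bound_receptors(q$R_T, S1, q$fgf_conc, q$Kd)
    Qb <- bound_receptors(q$Q_T, s2_from_s1(S1), q$ephrin_conc, q$Ke)
    expect_equal(ras_gtp_steady_state(q, Rb, Qb), ode_ras_gtp(q, Rb, Qb),
                 tolerance = 1e-8)
  }
})

test_that("ERK readout is the stated Hill function of Ras-GTP", {
  expect_equal(erk_activation(p$K_erk, p), 0.5)
  expect_equal(erk_activation(0, p), 0)
  expect_equal(erk_activation(1, p), 1 / (1 + 0.25))   # n = 2, K = 0.5
  T <- seq(0, 1, length.out = 101)
  expect_true(all(diff(erk_activation(T, p)) > 0))
})

test_that("a-line response composes occupancy, Ras cycle and ERK readout", {
  # zero contact with FGF source: no signal regardless of ephrin
  out <- aline_cell_response(p, data.frame(S1 = 0, S2 = 0.91))
  expect_equal(out$erk_star, 0)
  # missing S2 is derived from S1; measured S2 wins when present
  derived <- aline_cell_response(p, data.frame(S1 = 0.3))
  expect_equal(derived$S2, s2_from_s1(0.3))
  measured <- aline_cell_response(p, data.frame(S1 = 0.3, S2 = 0.5))
  expect_equal(measured$S2, 0.5)
  expect_false(isTRUE(all.equal(derived$erk_star, measured$erk_star)))
  # residual-scan oracle: the returned T beats any grid point of the balance
  out <- aline_cell_response(p, data.frame(S1 = 0.3))
  Ts <- seq(0, 1, by = 1e-5)
  res <- abs(ras_residual(p, out$Rb, out$Qb, Ts))
  expect_lt(abs(ras_residual(p, out$Rb, out$Qb, out$T)), min(res) + 1e-12)
  expect_lt(abs(out$T - Ts[which.min(res)]), 1e-5)
})

test_that("dnFGFR collapses ERK activity to ~5e-4 in the strongest cell", {
  pd <- apply_scenario(p, "dnFGFR")
  out <- aline_cell_response(pd, data.frame(S1 = default_s1_means()))
  expect_lt(max(out$erk_star), 1e-3)
  expect_equal(max(out$erk_star), 5e-4, tolerance = 0.2)
})

test_that("Erk* is monotone in each input in the physiological direction", {
  s1 <- seq(0, 0.8, length.out = 41)
  tied <- aline_cell_response(p, data.frame(S1 = s1))$erk_star
  expect_true(all(diff(tied) >= 0))
  fixed_s1 <- vapply(seq(0, 0.7, length.out = 29), function(s2)
    aline_cell_response(p, data.frame(S1 = 0.3, S2 = s2))$erk_star, numeric(1))
  expect_true(all(diff(fixed_s1) <= 0))
  fgf <- vapply(seq(0, 100, length.out = 41), function(f) {
    q <- apply_scenario(p, list(fgf_conc = f))
    aline_cell_response(q, data.frame(S1 = 0.3))$erk_star
  }, numeric(1))
  expect_true(all(diff(fgf) >= 0))
  eph <- vapply(seq(0, 100, length.out = 41), function(e) {
    q <- apply_scenario(p, list(ephrin_conc = e))
    aline_cell_response(q, data.frame(S1 = 0.3))$erk_star
  }, numeric(1))
  expect_true(all(diff(eph) <= 0))
})

test_that("ERK stays well below saturation at the strongest measured contact", {
  # the most responsive cell type sits at S1 ~ 0.40, where activation is
  # under a quarter of its maximum
  out <- aline_cell_response(p, data.frame(S1 = default_s1_means()[["a6.5"]]))
  expect_lt(out$erk_star, 0.25)
})

test_that("b-line occupancy sums the A-line and B6 interface populations", {
  # reduces to the single-population form with no B6 contact
  g0 <- data.frame(S1_A = 0.25)
  expect_equal(bline_bound_receptors(p, g0),
               bound_receptors(p$R_T, 0.25, p$fgf_conc, p$Kd))
  # additivity when every interface sees the same ligand level
  g <- data.frame(S1_A = 0.2, S1_B6.1 = 0.1, S1_B6.2 = 0.05,
                  S1_B6.3 = 0.03, S1_B6.4 = 0.02)
  pooled <- bound_receptors(p$R_T, 0.2 + 0.1 + 0.05 + 0.03 + 0.02,
                            p$fgf_conc, p$Kd)
  expect_equal(bline_bound_receptors(p, g, fgf_b6 = rep(p$fgf_conc, 4)),
               pooled)
  # term-by-term arithmetic oracle at the default interface concentrations
  g2 <- data.frame(S1_A = 0.2, S1_B6.1 = 0.1, S1_B6.2 = 0.1, S1_B6.3 = 0.1,
                   S1_B6.4 = 0)
  by_hand <- 2000 * 0.2 * 5 / (5 + 25) +
    2000 * 0.1 * 5 / (5 + 25) +
    2000 * 0.1 * 0.7 / (0.7 + 25) +
    2000 * 0.1 * 0.08 / (0.08 + 25) +
    0
  expect_equal(bline_bound_receptors(p, g2), by_hand, tolerance = 1e-12)
})

test_that("b-line response matches the a-line path and ranks b6.5 highest", {
  # no contacts at all: silent cell
  silent <- bline_cell_response(p, data.frame(S1_A = 0, S1_B6.1 = 0, S2 = 0))
  expect_equal(silent$erk_star, 0)
  # with all B6 contacts zero the two paths coincide
  a <- aline_cell_response(p, data.frame(S1 = 0.3, S2 = 0.5))
  b <- bline_cell_response(p, data.frame(S1_A = 0.3, S2 = 0.5))
  expect_equal(b$erk_star, a$erk_star, tolerance = 1e-12)
  # a b6.5-like cell (large A-line contact) dominates its siblings
  geom <- data.frame(
    cell_id = c("b6.5", "b6.6", "b6.7", "b6.8"),
    S1_A = c(0.35, 0.02, 0.05, 0.01),
    S1_B6.1 = c(0.05, 0.00, 0.10, 0.02),
    S1_B6.2 = c(0.00, 0.05, 0.05, 0.10),
    S1_B6.3 = c(0.00, 0.10, 0.00, 0.05),
    S1_B6.4 = c(0.00, 0.05, 0.05, 0.10),
    S2 = c(0.45, 0.75, 0.70, 0.70))
  out <- bline_cell_response(p, geom)
  expect_equal(which.max(out$erk_star), 1L)
  expect_gt(out$erk_star[1], 3 * max(out$erk_star[-1]))
})
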