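# ERK activation from cell-surface contacts: receptor occupancy, the
# Ras-GTPase (SOS vs p120RasGAP) cycle at steady state, and the Hill readout
# of the collapsed Raf/MEK/ERK cascade.

#' Empirical relation between the two contact fractions
#'
#' In the embryo the fraction of a cell's surface touching FGF-expressing
#' mesendoderm (S1) and the fraction touching ephrin-expressing ectoderm (S2)
#' are inversely related; the measured per-cell values are well described by
#' the linear law S2 = -1.13 S1 + 0.91. The value is clamped at 0 for
#' S1 > 0.91/1.13, where the line would go negative.
#'
#' @param S1 numeric vector of contact fractions in \[0, 1\].
#' @param slope,intercept coefficients of the linear relation.
#' @return S2 values in \[0, 0.91\].
#' @examples
#' s2_from_s1(0)    # 0.91
#' s2_from_s1(1)    # 0 (clamped)
#' @export
s2_from_s1 <- function(S1, slope = -1.13, intercept = 0.91) {
  if (any(!is.finite(S1)) || any(S1 < 0) || any(S1 > 1))
    stop("S1 must lie in [0, 1]")
  pmax(0, slope * S1 + intercept)
}

#' Inverse of the empirical contact relation (S1 from S2), clamped at 0.
#' @param S2 numeric vector of contact fractions in \[0, 1\].
#' @rdname s2_from_s1
#' @export
s1_from_s2 <- function(S2, slope = -1.13, intercept = 0.91) {
  if (any(!is.finite(S2)) || any(S2 < 0) || any(S2 > 1))
    stop("S2 must lie in [0, 1]")
  pmax(0, (S2 - intercept) / slope)
}

#' Ligand-bound receptor count on a contact surface
#'
#' Number of occupied receptors on the portion of membrane facing the
#' ligand-expressing cells, assuming uniform receptor density and equilibrium
#' binding: `total * contact_fraction * ligand / (ligand + K_bind)`.
#'
#' @param total total receptor count on the cell.
#' @param contact_fraction fraction of the surface facing the ligand source.
#' @param ligand ligand concentration (arbitrary units).
#' @param K_bind binding constant in the same units as `ligand`.
#' @return bound receptor count (vectorized over any argument).
#' @examples
#' bound_receptors(2000, 0.3, 5, 25)   # 100
#' @export
bound_receptors <- function(total, contact_fraction, ligand, K_bind) {
  if (any(c(total, contact_fraction, ligand, K_bind) < 0))
    stop("all arguments must be non-negative")
  occ <- ifelse(ligand + K_bind == 0, 0, ligand / (ligand + K_bind))
  total * contact_fraction * occ
}

# Michaelian lumped rates of the two converter enzymes, given bound-receptor
# counts: SOS activity A and p120RasGAP activity B.
.ras_rates <- function(params, Rb, Qb) {
  list(A = params$Vs * Rb / (params$Ks + Rb),
       B = params$Vrg * Qb / (params$Krg + Qb))
}

#' Steady-state fraction of Ras-GTP
#'
#' Solves the balance between SOS-mediated Ras-GDP -> Ras-GTP conversion and
#' RasGAP-mediated (ephrin-dependent plus basal) hydrolysis:
#' \deqn{V_s \frac{R_b}{K_s+R_b}\frac{1-T}{K_1+1-T} =
#'       V_{rg} \frac{Q_b}{K_{rg}+Q_b}\frac{T}{K_2+T} + K_b T.}
#' The net rate is strictly decreasing in T, so the root in \[0, 1\] is
#' unique; it is bracketed by `uniroot` and polished by Newton steps with the
#' analytic derivative to a residual below 1e-12.
#'
#' @param params an `induction_params` object.
#' @param Rb FGF-bound receptor count(s).
#' @param Qb ephrin-bound Eph receptor count(s).
#' @return the Ras-GTP fraction T in \[0, 1\] (vectorized over `Rb`/`Qb`).
#' @export
ras_gtp_steady_state <- function(params, Rb, Qb) {
  if (any(Rb < 0) || any(Qb < 0)) stop("Rb and Qb must be non-negative")
  n <- max(length(Rb), length(Qb))
  Rb <- rep_len(Rb, n); Qb <- rep_len(Qb, n)
  vapply(seq_len(n), function(i)
    .ras_root(params, Rb[i], Qb[i]), numeric(1))
}

.ras_root <- function(params, Rb, Qb) {
  r <- .ras_rates(params, Rb, Qb)
  A <- r$A; B <- r$B
  K1 <- params$K1; K2 <- params$K2; Kb <- params$Kb
  f <- function(T) A * (1 - T) / (K1 + 1 - T) - B * T / (K2 + T) - Kb * T
  fp <- function(T) -A * K1 / (K1 + 1 - T)^2 - B * K2 / (K2 + T)^2 - Kb
  if (A == 0) return(0)          # no production: all Ras stays GDP-bound
  if (f(1) >= 0) return(1)       # no hydrolysis at all: full conversion
  root <- stats::uniroot(f, c(0, 1), tol = 1e-13)$root
  for (i in 1:8) {               # Newton polish; f is smooth and monotone
    step <- f(root) / fp(root)
    newr <- min(1, max(0, root - step))
    if (abs(newr - root) < 1e-16) { root <- newr; break }
    root <- newr
  }
  root
}

#' ERK activation from the Ras-GTP fraction
#'
#' The full Raf/MEK/ERK cascade is collapsed into a single Hill function:
#' normalized ERK activity is `T^n / (T^n + K_erk^n)` with `n = n_erk`.
#'
#' @param T Ras-GTP fraction(s) in \[0, 1\].
#' @param params an `induction_params` object.
#' @return normalized ERK activity Erk* in \[0, 1\].
#' @examples
#' erk_activation(0.5, default_parameters())   # 0.5 (T = K_erk)
#' @export
erk_activation <- function(T, params) {
  if (any(T < 0) || any(T > 1)) stop("T must lie in [0, 1]")
  n <- params$n_erk; K <- params$K_erk
  T^n / (T^n + K^n)
}

#' Steady-state ERK response of an anterior (a-line) ectoderm cell
#'
#' Composes receptor occupancy on both contact surfaces, the Ras-GTP steady
#' state and the ERK readout for each row of a geometry table. When a row has
#' no measured S2 (missing column or `NA`), S2 is derived from S1 through the
#' empirical linear relation; measured values always win.
#'
#' @param params an `induction_params` object.
#' @param geometry data frame with columns `S1` and optionally `cell_id`,
#'   `cell_type`, `S2`.
#' @return the geometry with columns `S2` (filled), `Rb`, `Qb`, `T` and
#'   `erk_star` appended.
#' @export
aline_cell_response <- function(params, geometry) {
  geometry <- as.data.frame(geometry)
  if (!"S1" %in% names(geometry)) stop("geometry must have an S1 column")
  S1 <- geometry$S1
  if (any(S1 < 0 | S1 > 1)) stop("S1 must lie in [0, 1]")
  S2 <- if ("S2" %in% names(geometry)) geometry$S2 else rep(NA_real_, length(S1))
  S2 <- ifelse(is.na(S2), s2_from_s1(S1), S2)
  if (any(S2 < 0 | S2 > 1)) stop("S2 must lie in [0, 1]")
  if (any(S1 + S2 > 1 + 1e-9))
    warning("S1 + S2 exceeds 1 for some cells; check the geometry")
  Rb <- bound_receptors(params$R_T, S1, params$fgf_conc, params$Kd)
  Qb <- bound_receptors(params$Q_T, S2, params$ephrin_conc, params$Ke)
  T <- ras_gtp_steady_state(params, Rb, Qb)
  out <- geometry
  out$S2 <- S2
  out$Rb <- Rb; out$Qb <- Qb; out$T <- T
  out$erk_star <- erk_activation(T, params)
  out
}

#' Bound FGF receptors of a posterior (b-line) ectoderm cell
#'
#' b-line cells face two FGF sources: A-line mesendoderm with the global FGF
#' concentration, and the four B-line mesendoderm cells B6.1-B6.4 which
#' express different FGF levels. The two receptor populations sum:
#' `R_T * S1_A * [FGF]/([FGF]+Kd) + sum_i R_T * S1_B6.i * f_i/(f_i+Kd)`.
#'
#' @param params an `induction_params` object.
#' @param geometry data frame with columns `S1_A` and `S1_B6.1` .. `S1_B6.4`
#'   (absent interface columns count as zero contact).
#' @param fgf_b6 local FGF concentrations at the four B6 interfaces; the
#'   defaults scale the measured ligand expression of B6.1-B6.4 relative to
#'   the A-line level.
#' @return vector of total bound FGF receptor counts.
#' @export
bline_bound_receptors <- function(params, geometry,
                                  fgf_b6 = c(5, 0.7, 0.08, 0.7)) {
  geometry <- as.data.frame(geometry)
  if (!"S1_A" %in% names(geometry)) stop("geometry must have an S1_A column")
  if (length(fgf_b6) != 4L || any(fgf_b6 < 0))
    stop("fgf_b6 must be four non-negative concentrations")
  Rb <- bound_receptors(params$R_T, geometry$S1_A, params$fgf_conc, params$Kd)
  for (i in 1:4) {
    col <- paste0("S1_B6.", i)
    f <- if (col %in% names(geometry)) geometry[[col]] else 0
    if (any(f < 0 | f > 1)) stop(col, " must lie in [0, 1]")
    Rb <- Rb + bound_receptors(params$R_T, f, fgf_b6[i], params$Kd)
  }
  Rb
}

#' Steady-state ERK response of a b-line cell
#'
#' As [aline_cell_response()], but FGF-bound receptors come from the
#' two-population sum over the A-line and B6 interfaces, and S2 must be
#' supplied (the a-line linear relation does not apply to b-line cells).
#'
#' @inheritParams bline_bound_receptors
#' @return the geometry with `Rb`, `Qb`, `T`, `erk_star` appended.
#' @export
bline_cell_response <- function(params, geometry,
                                fgf_b6 = c(5, 0.7, 0.08, 0.7)) {
  geometry <- as.data.frame(geometry)
  if (!"S2" %in% names(geometry)) stop("b-line geometry must have an S2 column")
  if (any(geometry$S2 < 0 | geometry$S2 > 1)) stop("S2 must lie in [0, 1]")
  Rb <- bline_bound_receptors(params, geometry, fgf_b6)
  Qb <- bound_receptors(params$Q_T, geometry$S2, params$ephrin_conc, params$Ke)
  T <- ras_gtp_steady_state(params, Rb, Qb)
  out <- geometry
  out$Rb <- Rb; out$Qb <- Qb; out$T <- T
  out$erk_star <- erk_activation(T, params)
  out
}
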