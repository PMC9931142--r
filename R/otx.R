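# ERK-driven Otx transcription: phosphorylation cycles of the Ets1/2
# activator and ERF2 repressor (Goldbeter-Koshland form, solved in closed
# form) and the competitive activator/repressor promoter.

# Steady state of a covalent-modification cycle
#   v_fwd (1-x)/(J_fwd + 1-x) = v_rev x/(J_rev + x),   x in [0, 1].
# Cross-multiplying gives the quadratic
#   (v_rev - v_fwd) x^2 + [v_fwd(1 - J_rev) - v_rev(1 + J_fwd)] x
#     + v_fwd J_rev = 0,
# whose unique admissible root is selected; near-degenerate discriminants
# fall back to bisection. Boundary drives (either rate zero) return the
# corresponding boundary exactly.
.gk_steady_state <- function(v_fwd, v_rev, J_fwd, J_rev) {
  if (v_fwd < 0 || v_rev < 0) stop("cycle rates must be non-negative")
  if (v_fwd == 0) return(0)
  if (v_rev == 0) return(1)
  c2 <- v_rev - v_fwd
  c1 <- v_fwd * (1 - J_rev) - v_rev * (1 + J_fwd)
  c0 <- v_fwd * J_rev
  if (abs(c2) < 1e-12 * max(v_fwd, v_rev)) {
    x <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) disc <- 0
    # stable form: q avoids cancellation between -c1 and sqrt(disc)
    q <- -(c1 + sign(c1) * sqrt(disc)) / 2
    roots <- c(q / c2, if (q != 0) c0 / q else NA_real_)
    roots <- roots[is.finite(roots) & roots >= -1e-9 & roots <= 1 + 1e-9]
    x <- if (length(roots) > 0) min(max(roots[1], 0), 1) else NA_real_
  }
  resid <- function(z) v_fwd * (1 - z) / (J_fwd + 1 - z) -
    v_rev * z / (J_rev + z)
  if (!is.finite(x) || abs(resid(x)) > 1e-12 * max(v_fwd, v_rev)) {
    x <- stats::uniroot(resid, c(0, 1), tol = 1e-15)$root
  }
  x
}

#' Steady-state fraction of phosphorylated (active) Ets1/2
#'
#' ERK phosphorylates the activator at rate `kMM3 * erk_star` against a
#' constitutive phosphatase `vMM4`; both legs follow Michaelis-Menten
#' kinetics with constants `KMM3`/`KMM4`. Small constants (default 0.05) put
#' the cycle in the zero-order ultrasensitive regime.
#'
#' @param erk_star normalized ERK activity in \[0, 1\] (vectorized).
#' @param params an `induction_params` object.
#' @return fraction Ap of active activator in \[0, 1\].
#' @export
activator_steady_state <- function(erk_star, params) {
  if (any(erk_star < 0) || any(erk_star > 1)) stop("erk_star must lie in [0, 1]")
  vapply(erk_star, function(e)
    .gk_steady_state(params$kMM3 * e, params$vMM4, params$KMM3, params$KMM4),
    numeric(1))
}

#' Steady-state fraction of unphosphorylated (active) ERF2 repressor
#'
#' The repressor is active when unphosphorylated: a constitutive phosphatase
#' `vMM2` regenerates it while ERK removes it at rate `kMM1 * erk_star`. With
#' no ERK activity the cycle sits at I = 1. If `params$I_clamp` is set (the
#' ERF2-morpholino scenario) the clamp value is returned for every input.
#'
#' @inheritParams activator_steady_state
#' @return fraction I of active repressor in \[0, 1\].
#' @export
repressor_steady_state <- function(erk_star, params) {
  if (any(erk_star < 0) || any(erk_star > 1)) stop("erk_star must lie in [0, 1]")
  if (!is.na(params$I_clamp)) return(rep(params$I_clamp, length(erk_star)))
  vapply(erk_star, function(e)
    .gk_steady_state(params$vMM2, params$kMM1 * e, params$KMM2, params$KMM1),
    numeric(1))
}

#' Steady-state Otx expression level
#'
#' The repressor competes with the activator for the same ETS binding sites,
#' which inflates the activator's effective half-saturation constant to
#' `Ka * (1 + I/Ki)`. The plain promoter gives
#' `O = (vb + vo * Ap / (Ka(1 + I/Ki) + Ap)) / k`; with `params$coop = TRUE`
#' both activator occupancy and the effective constant enter squared
#' (two tandem ETS sites bound cooperatively).
#'
#' @param Ap fraction of active activator in \[0, 1\] (vectorized).
#' @param I fraction of active repressor in \[0, 1\].
#' @param params an `induction_params` object.
#' @return Otx expression level O, bounded by `vb/k` and `(vb+vo)/k`.
#' @examples
#' p <- default_parameters()
#' otx_steady_state(0, 1, p)      # basal level vb/k = 0.005
#' otx_steady_state(0.1, 0, p)    # half-saturated, no repressor: 2.505
#' @export
otx_steady_state <- function(Ap, I, params) {
  if (any(Ap < 0) || any(Ap > 1)) stop("Ap must lie in [0, 1]")
  if (any(I < 0) || any(I > 1)) stop("I must lie in [0, 1]")
  Keff <- params$Ka * (1 + I / params$Ki)
  frac <- if (params$coop) Ap^2 / (Keff^2 + Ap^2) else Ap / (Keff + Ap)
  (params$vb + params$vo * frac) / params$k
}

#' Full steady-state response of a-line cells: contacts to Otx
#'
#' Chains [aline_cell_response()] (receptor occupancy and the Ras/ERK steady
#' state) with the activator and repressor cycles and the promoter model.
#'
#' @param params an `induction_params` object.
#' @param geometry data frame with column `S1` and optionally `cell_id`,
#'   `cell_type`, `S2`.
#' @param repressor set `FALSE` to remove the repressor (I forced to 0),
#'   e.g. to examine the promoter without ERF2.
#' @return data frame with columns of `geometry` plus `Rb`, `Qb`, `T`,
#'   `erk_star`, `Ap`, `I`, `O`.
#' @export
full_response <- function(params, geometry, repressor = TRUE) {
  out <- aline_cell_response(params, geometry)
  out$Ap <- activator_steady_state(out$erk_star, params)
  out$I <- if (repressor) repressor_steady_state(out$erk_star, params)
           else rep(0, nrow(out))
  out$O <- otx_steady_state(out$Ap, out$I, params)
  out
}
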