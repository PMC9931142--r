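# Parameter sensitivity analyses: one-at-a-time +-20% perturbations and
# random simultaneous sampling of pathway-specific parameter subsets.

.fgf_subset <- c("fgf_conc", "Kd", "K1", "Ks", "Vs", "R_T")
.ephrin_subset <- c("ephrin_conc", "Ke", "K2", "Krg", "Vrg", "Q_T")
.otx_subset <- c("kMM1", "KMM1", "vMM2", "KMM2", "kMM3", "KMM3", "vMM4",
                 "KMM4", "vb", "vo", "k", "Ka", "Ki")

#' Parameter subsets used in the sensitivity analyses
#'
#' `"fgf"`: the FGF>FGFR>SOS leg; `"ephrin"`: the ephrin>Eph>p120RasGAP leg;
#' `"all"`: both legs plus the basal GAP rate, the ERK half-activation point
#' and the Otx-module parameters.
#'
#' @param subset one of `"fgf"`, `"ephrin"`, `"all"`.
#' @return character vector of parameter field names.
#' @export
sensitivity_subset <- function(subset = c("fgf", "ephrin", "all")) {
  switch(match.arg(subset),
    fgf = .fgf_subset,
    ephrin = .ephrin_subset,
    all = c(.fgf_subset, .ephrin_subset, "Kb", "K_erk", .otx_subset))
}

# Per-cell-type steady state at given parameters; S1/S2 supplied explicitly
# so the perturbation modes can decouple them.
.cell_type_states <- function(params, S1, S2, types = names(S1)) {
  geom <- data.frame(cell_type = types, S1 = unname(S1), S2 = unname(S2))
  # surface perturbations intentionally decouple S1 and S2, so the
  # S1 + S2 > 1 geometry warning is expected here
  out <- suppressWarnings(full_response(params, geom))
  out[, c("cell_type", "erk_star", "O")]
}

#' One-at-a-time parameter sensitivity
#'
#' Perturbs one parameter at a time by `+-fraction` (default 20%) and reports
#' the ratio of the perturbed to the default steady-state ERK activity and
#' Otx level for each cell type, with the cell types placed at their mean
#' contact fractions. The surfaces are perturbable as independent inputs:
#' `"S1"` rescales S1 with S2 held at its default, `"S2"` the converse, and
#' `"S2_slope"` rescales the slope of the empirical S2(S1) relation while
#' re-anchoring the intercept so the line still passes through the centroid
#' of the default per-type (S1, S2) means.
#'
#' @param params an `induction_params` object.
#' @param s1_means named vector of per-cell-type mean S1 (default
#'   [default_s1_means()]).
#' @param parameters which parameters to perturb; defaults to every numeric
#'   model parameter plus `"S1"`, `"S2"`, `"S2_slope"`.
#' @param fraction perturbation fraction (0.2 = +-20%).
#' @return data frame with columns `parameter`, `direction`, `cell_type`,
#'   `erk_star`, `O`, `ratio_erk`, `ratio_otx`.
#' @export
sensitivity_oat <- function(params, s1_means = default_s1_means(),
                            parameters = NULL, fraction = 0.2) {
  numeric_fields <- setdiff(.param_fields, c("coop", "I_clamp"))
  if (is.null(parameters))
    parameters <- c(numeric_fields, "S1", "S2", "S2_slope")
  bad <- setdiff(parameters, c(numeric_fields, "S1", "S2", "S2_slope"))
  if (length(bad) > 0L)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  S1 <- s1_means
  S2 <- s2_from_s1(S1)
  types <- names(s1_means)
  ref <- .cell_type_states(params, S1, S2, types)
  rows <- list()
  for (par in parameters) for (dir in c(1, -1)) {
    f <- 1 + dir * fraction
    st <- if (par == "S1") {
      .cell_type_states(params, pmin(1, S1 * f), S2, types)
    } else if (par == "S2") {
      .cell_type_states(params, S1, pmin(1, S2 * f), types)
    } else if (par == "S2_slope") {
      slope <- -1.13 * f
      intercept <- mean(S2) - slope * mean(S1)
      .cell_type_states(params, S1,
                        pmin(1, pmax(0, slope * S1 + intercept)), types)
    } else {
      p <- apply_scenario(params,
        stats::setNames(list(unclass(params)[[par]] * f), par))
      .cell_type_states(p, S1, S2, types)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = par,
      direction = if (dir > 0) sprintf("+%d%%", round(100 * fraction))
                  else sprintf("-%d%%", round(100 * fraction)),
      cell_type = st$cell_type,
      erk_star = st$erk_star, O = st$O,
      ratio_erk = st$erk_star / ref$erk_star,
      ratio_otx = st$O / ref$O)
  }
  do.call(rbind, rows)
}

#' Random simultaneous parameter sampling
#'
#' Draws each parameter of the chosen subset independently and uniformly on
#' `[(1 - fraction) * default, (1 + fraction) * default]`, recomputes the
#' per-cell-type steady state for every draw, and returns the sample. With a
#' seed, output is reproducible; the seed, subset and draw count are attached
#' as attributes.
#'
#' @param params an `induction_params` object.
#' @param s1_means named per-cell-type mean S1 ([default_s1_means()]).
#' @param subset `"fgf"`, `"ephrin"` or `"all"` (see [sensitivity_subset()]).
#' @param n_draws number of random draws (default 1000).
#' @param fraction half-width of the sampling interval (default 0.2).
#' @param seed integer seed; required for reproducibility.
#' @return data frame with columns `draw`, `cell_type`, `erk_star`, `O`.
#' @export
sensitivity_random <- function(params, s1_means = default_s1_means(),
                               subset = c("fgf", "ephrin", "all"),
                               n_draws = 1000, fraction = 0.2, seed = NULL) {
  subset <- match.arg(subset)
  pars <- sensitivity_subset(subset)
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  S1 <- s1_means
  S2 <- s2_from_s1(S1)
  base <- unclass(params)
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    fac <- stats::runif(length(pars), 1 - fraction, 1 + fraction)
    p <- base
    p[pars] <- Map(`*`, base[pars], fac)
    class(p) <- "induction_params"
    st <- .cell_type_states(p, S1, S2, names(s1_means))
    rows[[d]] <- data.frame(draw = d, st)
  }
  out <- do.call(rbind, rows)
  attr(out, "subset") <- subset
  attr(out, "n_draws") <- n_draws
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  out
}
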