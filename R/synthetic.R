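# Synthetic per-cell geometry and readout generator. Emulates the measured
# data's structure -- four cell-type clusters of S1 with the near-linear
# inverse S1-S2 relation, and noisy linear IF / smFISH readouts -- so that
# calibration and recovery tests run without any downloaded data.

#' Default per-cell-type mean contact fractions
#'
#' Mean S1 (fraction of surface contacting FGF-expressing mesendoderm) per
#' a-line cell type. These are calibrated values, not measurements: each mean
#' is chosen so that the average of the model's ERK activity over
#' `S1 ~ N(mean, 0.04)` (clipped to \[0, 1\]) at default parameters equals
#' the reported mean per-type activity (0.1787, 0.0551, 0.0078, 0.0021 for
#' a6.5, a6.7, a6.6, a6.8).
#'
#' @return named numeric vector ordered a6.5 > a6.7 > a6.6 > a6.8.
#' @export
default_s1_means <- function() {
  c(a6.5 = 0.4000, a6.7 = 0.2226, a6.6 = 0.0834, a6.8 = 0.0324)
}

#' Configuration of the synthetic-data generator
#'
#' @param n_per_type cells per cell type (default 25, the measured sample
#'   size per type).
#' @param s1_means named per-type mean S1 (see [default_s1_means()]); must be
#'   ordered a6.5 > a6.7 > a6.6 > a6.8.
#' @param s1_sd within-type standard deviation of S1 (default 0.04).
#' @param s2_slope,s2_intercept the linear S2(S1) relation (defaults -1.13
#'   and 0.91, the measured fit).
#' @param s2_residual_sd residual noise around the line; the default 0.015
#'   reproduces the reported R^2 of about 0.99 given the overall S1 spread.
#' @param calibration a [readout_calibration()] used to map model outputs to
#'   IF signals and spot counts.
#' @param if_noise_sd Gaussian noise SD on the IF readout (default 25,
#'   roughly 1.4% of the IF scale A).
#' @param seed default seed for generation.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_type = 25,
                             s1_means = default_s1_means(),
                             s1_sd = 0.04,
                             s2_slope = -1.13, s2_intercept = 0.91,
                             s2_residual_sd = 0.015,
                             calibration = readout_calibration(),
                             if_noise_sd = 25,
                             seed = 1L) {
  if (any(s1_means < 0 | s1_means > 1)) stop("s1_means must lie in [0, 1]")
  want <- c("a6.5", "a6.7", "a6.6", "a6.8")
  if (!all(want %in% names(s1_means)))
    stop("s1_means must be named for cell types ", paste(want, collapse = ", "))
  if (any(diff(s1_means[want]) >= 0))
    stop("s1_means must be ordered a6.5 > a6.7 > a6.6 > a6.8")
  if (s1_sd < 0 || s2_residual_sd < 0 || if_noise_sd < 0)
    stop("noise parameters must be non-negative")
  structure(list(n_per_type = n_per_type, s1_means = s1_means[want],
                 s1_sd = s1_sd, s2_slope = s2_slope,
                 s2_intercept = s2_intercept,
                 s2_residual_sd = s2_residual_sd,
                 calibration = calibration, if_noise_sd = if_noise_sd,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic per-cell geometry table
#'
#' Draws `n_per_type` cells per a-line type: S1 normal around the type mean
#' (clipped to \[0, 1\]), S2 from the linear relation plus residual noise
#' (clipped). Generation is a pure function of `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` if given.
#' @return data frame with columns `cell_id`, `cell_type`, `S1`, `S2`.
#' @export
generate_geometry <- function(config, seed = config$seed) {
  set.seed(seed)
  types <- names(config$s1_means)
  rows <- lapply(types, function(ct) {
    S1 <- pmin(1, pmax(0, stats::rnorm(config$n_per_type,
                                       config$s1_means[[ct]], config$s1_sd)))
    S2 <- config$s2_slope * S1 + config$s2_intercept +
      stats::rnorm(config$n_per_type, 0, config$s2_residual_sd)
    data.frame(cell_id = sprintf("%s_%02d", ct, seq_len(config$n_per_type)),
               cell_type = ct, S1 = S1, S2 = pmin(1, pmax(0, S2)))
  })
  do.call(rbind, rows)
}

#' Generate synthetic noisy readouts for a geometry table
#'
#' Runs the full steady-state pipeline per cell, then emits a dpERK IF signal
#' `A * Erk* + B` plus Gaussian noise, and an Otx smFISH spot count drawn
#' Poisson around `C * O + D` (a stand-in dispersion model; the count noise
#' of the real assay is not characterized).
#'
#' @param geometry a geometry table (from [generate_geometry()] or measured).
#' @param params an `induction_params` object.
#' @param config a [synthetic_config()] (calibration and noise levels).
#' @param seed overrides `config$seed` if given.
#' @return data frame with columns `cell_id`, `cell_type`, `dpERK_IF`,
#'   `otx_spots`.
#' @export
generate_readouts <- function(geometry, params, config, seed = config$seed) {
  set.seed(seed)
  resp <- full_response(params, geometry)
  cal <- config$calibration
  n <- nrow(resp)
  if_sig <- erk_to_if(resp$erk_star, cal) +
    stats::rnorm(n, 0, config$if_noise_sd)
  spots <- stats::rpois(n, lambda = pmax(0, otx_to_smfish(resp$O, cal)))
  data.frame(cell_id = resp$cell_id, cell_type = resp$cell_type,
             dpERK_IF = if_sig, otx_spots = spots)
}
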