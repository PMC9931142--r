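# Linear calibration between model outputs and experimental readouts:
# dpERK immunofluorescence (IF) for ERK activity, smFISH spot counts for Otx
# expression, and the propagation of background uncertainties.

#' Readout calibration constants
#'
#' Linear maps between model scale and experimental scale:
#' `IF = A * Erk* + B` and `spots = C * O + D`. `dB`/`dD` are the
#' uncertainties of the background levels (standard deviation of the
#' background cell type's measured values).
#'
#' @param A maximal dpERK IF scale (slope), > 0.
#' @param B background IF level.
#' @param C maximal smFISH spot scale (slope), > 0.
#' @param D basal smFISH spot count.
#' @param dB,dD uncertainties on `B` and `D` (>= 0).
#' @return an object of class `readout_calibration`.
#' @export
readout_calibration <- function(A = 1850, B = 155.11, C = 66, D = 2.75,
                                dB = 0, dD = 0) {
  if (A <= 0 || C <= 0) stop("A and C must be strictly positive")
  if (B < 0 || D < 0 || dB < 0 || dD < 0)
    stop("B, D, dB, dD must be non-negative")
  structure(list(A = A, B = B, C = C, D = D, dB = dB, dD = dD),
            class = "readout_calibration")
}

#' @export
print.readout_calibration <- function(x, ...) {
  cat(sprintf("dpERK IF : A = %g, B = %g (dB = %g)\n", x$A, x$B, x$dB))
  cat(sprintf("Otx smFISH: C = %g, D = %g (dD = %g)\n", x$C, x$D, x$dD))
  invisible(x)
}

#' Convert between model ERK activity and dpERK IF signal
#'
#' Forward map `A * erk_star + B`; inverse `(signal - B) / A`. The two are
#' exact inverses.
#'
#' @param erk_star normalized ERK activity.
#' @param signal measured IF signal.
#' @param cal a `readout_calibration` object.
#' @export
erk_to_if <- function(erk_star, cal) cal$A * erk_star + cal$B

#' @rdname erk_to_if
#' @export
if_to_erk <- function(signal, cal) {
  if (cal$A == 0) stop("cannot invert a calibration with A = 0")
  (signal - cal$B) / cal$A
}

#' Convert between model Otx level and smFISH spot count
#'
#' Forward map `C * O + D`; inverse `(count - D) / C`.
#'
#' @param O Otx expression level.
#' @param count measured spot count.
#' @param cal a `readout_calibration` object.
#' @export
otx_to_smfish <- function(O, cal) cal$C * O + cal$D

#' @rdname otx_to_smfish
#' @export
smfish_to_otx <- function(count, cal) {
  if (cal$C == 0) stop("cannot invert a calibration with C = 0")
  (count - cal$D) / cal$C
}

#' Fit calibration constants from per-cell measurements
#'
#' The backgrounds are pinned to the least-responsive cell type: `B` (`D`) is
#' the mean measured IF (spot count) in `background_cell_type`, and `dB`
#' (`dD`) its standard deviation. The slopes `A` and `C` are then the
#' through-origin least-squares slopes of the background-subtracted
#' measurements against the model values over all cells.
#'
#' @param model data frame from [full_response()] (columns `cell_type`,
#'   `erk_star`, `O`), row-aligned with `measured`.
#' @param measured data frame with columns `cell_type` and at least one of
#'   `dpERK_IF`, `otx_spots`.
#' @param background_cell_type cell type whose mean defines the background
#'   (default `"a6.8"`).
#' @return a `readout_calibration`; slopes for readouts absent from
#'   `measured` are left at their defaults of 1.
#' @export
fit_calibration <- function(model, measured, background_cell_type = "a6.8") {
  if (nrow(model) != nrow(measured))
    stop("model and measured tables must be row-aligned")
  bg <- measured$cell_type == background_cell_type
  if (!any(bg)) stop("no cells of background type '", background_cell_type, "'")
  if (sum(bg) == 1L)
    warning("background group has a single cell; background SD set to 0")
  slope <- function(x, y, label) {
    sxx <- sum(x^2)
    if (sxx < 1e-12 * length(x))
      stop("degenerate fit for ", label, ": model values are all ~0")
    sum(x * y) / sxx
  }
  A <- 1; B <- 0; dB <- 0; C <- 1; D <- 0; dD <- 0
  if ("dpERK_IF" %in% names(measured)) {
    B <- mean(measured$dpERK_IF[bg])
    dB <- if (sum(bg) > 1L) stats::sd(measured$dpERK_IF[bg]) else 0
    A <- slope(model$erk_star, measured$dpERK_IF - B, "A")
  }
  if ("otx_spots" %in% names(measured)) {
    D <- mean(measured$otx_spots[bg])
    dD <- if (sum(bg) > 1L) stats::sd(measured$otx_spots[bg]) else 0
    C <- slope(model$O, measured$otx_spots - D, "C")
  }
  readout_calibration(A = A, B = B, C = C, D = D, dB = dB, dD = dD)
}

#' Uncertainty of a mean calibrated readout
#'
#' Propagates the spread of the model values and the background uncertainty
#' in quadrature: `sqrt((A * mean_erk_sd)^2 + dB^2)` for IF, and analogously
#' `sqrt((C * mean_otx_sd)^2 + dD^2)` for smFISH counts.
#'
#' @param mean_erk_sd standard deviation of the per-cell model Erk* values.
#' @param mean_otx_sd standard deviation of the per-cell model O values.
#' @param cal a `readout_calibration` object.
#' @return absolute uncertainty on the mean calibrated readout.
#' @export
mean_if_uncertainty <- function(mean_erk_sd, cal) {
  if (any(mean_erk_sd < 0)) stop("mean_erk_sd must be non-negative")
  sqrt((cal$A * mean_erk_sd)^2 + cal$dB^2)
}

#' @rdname mean_if_uncertainty
#' @export
mean_smfish_uncertainty <- function(mean_otx_sd, cal) {
  if (any(mean_otx_sd < 0)) stop("mean_otx_sd must be non-negative")
  sqrt((cal$C * mean_otx_sd)^2 + cal$dD^2)
}

#' Ratio of two readouts with propagated uncertainty
#'
#' For injected/control comparisons: the relative uncertainty of the ratio is
#' the root-sum-square of the two relative uncertainties.
#'
#' @param num,den numerator and denominator values (`den` must be > 0).
#' @param dnum,dden their absolute uncertainties.
#' @return list with elements `ratio` and `uncertainty` (absolute).
#' @export
ratio_with_uncertainty <- function(num, dnum, den, dden) {
  if (any(den <= 0)) stop("denominator must be strictly positive")
  ratio <- num / den
  rel <- sqrt((dnum / num)^2 + (dden / den)^2)
  list(ratio = ratio, uncertainty = abs(ratio) * rel)
}

#' Published per-panel calibration constants
#'
#' The calibration slopes and backgrounds used for individual figure panels
#' are experiment-specific (each immunostaining or smFISH batch has its own
#' scale); this lookup table ships them as data for reproduction scripts.
#' `NA` marks constants not applicable to a panel.
#'
#' @return data frame with columns `panel`, `condition`, `A`, `B`, `C`, `D`.
#' @export
figure_calibrations <- function() {
  data.frame(
    panel = c("fig2A", "fig2B", "fig2C", "fig3A", "fig3B", "fig3B", "fig3B",
              "fig3C", "fig3D", "fig3D", "fig3E", "s1B", "s1C", "s2B",
              "s7A", "s7C"),
    condition = c("control", "control", "dnFGFR/Eph3dC", "control",
                  "control+dnFGFR", "Eph3dC", "RGdGAP", "NVP/U0126",
                  "erk_axis", "otx_axis", "ERF2_MO", "NVP", "NVP", "b-line",
                  "cooperative", "cooperative ERF2_MO"),
    A = c(1850, 3000, 1850, NA, NA, NA, NA, NA, 3200, NA, NA, 2500, 2280,
          1500, NA, NA),
    B = c(155.11, 324.52, 155.11, NA, NA, NA, NA, NA, 0, NA, NA, 256.3,
          196.5, 144.9, NA, NA),
    C = c(NA, NA, NA, 66, 92, 95, 122, 94, NA, 120, 75, NA, NA, NA, 60, 73.4),
    D = c(NA, NA, NA, 2.75, 1.5, 2.71, 1.61, 1.2, NA, 0, 73.4, NA, NA, NA,
          2.75, 65)
  )
}
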