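# Dose-response sweeps of the steady-state pipeline and Hill-coefficient
# estimation, by nonlinear least squares and by the EC10/EC90 potency
# formula; Hill-difference heatmaps over parameter scans.

.s1_tied_max <- function(slope = -1.13, intercept = 0.91) -intercept / slope

#' Sweep a model input and record the steady-state response
#'
#' Evaluates the steady-state pipeline along a grid of one input while the
#' others are held fixed. With `coupling = "tied"` the two contact fractions
#' follow the empirical linear relation (sweeping S1 sets S2 and vice versa);
#' with `"independent"` the non-swept fraction is taken from `fixed`.
#'
#' Default domains: tied S1 sweeps run over \[0, 0.91/1.13\] (where the
#' linear relation keeps S2 non-negative), independent surface sweeps over
#' \[0, 1 - other surface\], ligand sweeps over \[0, 100\] (four times the
#' FGF binding constant, spanning receptor saturation), and `erk_star` over
#' \[0, 1\].
#'
#' @param params an `induction_params` object.
#' @param x_name one of `"S1"`, `"S2"`, `"FGF"`, `"ephrin"`, `"erk_star"`.
#' @param from,to sweep limits (defaults above).
#' @param n number of grid points (default 201).
#' @param fixed named list of held-fixed inputs: `S1` (default 0.3 for ligand
#'   sweeps), `S2` (required for independent surface sweeps).
#' @param coupling `"tied"` or `"independent"`.
#' @param response `"erk"` (normalized ERK activity) or `"otx"` (expression
#'   level O).
#' @param repressor only for `response = "otx"`: `FALSE` removes the
#'   repressor (I = 0).
#' @return an object of class `response_curve`: list with `x_name`, `xs`,
#'   `ys`, `fixed`, `coupling`, `response`.
#' @examples
#' p <- default_parameters()
#' curve <- sweep_response(p, "S1")
#' fit_hill(curve)$n_hill
#' @export
sweep_response <- function(params, x_name = c("S1", "S2", "FGF", "ephrin", "erk_star"),
                           from = NULL, to = NULL, n = 201, fixed = list(),
                           coupling = c("tied", "independent"),
                           response = c("erk", "otx"), repressor = TRUE) {
  x_name <- match.arg(x_name)
  coupling <- match.arg(coupling)
  response <- match.arg(response)
  if (x_name == "erk_star" && response != "otx")
    stop("an erk_star sweep only makes sense with response = 'otx'")
  if (coupling == "independent" && x_name %in% c("S1", "S2") &&
      is.null(fixed[[setdiff(c("S1", "S2"), x_name)]]))
    stop("independent ", x_name, " sweep requires the other surface in `fixed`")
  if (coupling == "tied" && x_name == "S1" && !is.null(fixed$S2))
    stop("cannot fix S2 while sweeping S1 with tied coupling")
  if (coupling == "tied" && x_name == "S2" && !is.null(fixed$S1))
    stop("cannot fix S1 while sweeping S2 with tied coupling")

  if (is.null(from)) from <- 0
  if (is.null(to)) to <- switch(x_name,
    S1 = if (coupling == "tied") .s1_tied_max() else 1 - fixed$S2,
    S2 = if (coupling == "tied") 0.91 else 1 - fixed$S1,
    FGF = 100, ephrin = 100, erk_star = 1)
  xs <- seq(from, to, length.out = n)

  erk_of <- function(S1, S2, fgf = params$fgf_conc, eph = params$ephrin_conc) {
    Rb <- bound_receptors(params$R_T, S1, fgf, params$Kd)
    Qb <- bound_receptors(params$Q_T, S2, eph, params$Ke)
    erk_activation(ras_gtp_steady_state(params, Rb, Qb), params)
  }
  erk <- switch(x_name,
    S1 = {
      S2 <- if (coupling == "tied") s2_from_s1(xs) else rep(fixed$S2, n)
      erk_of(xs, S2)
    },
    S2 = {
      S1 <- if (coupling == "tied") s1_from_s2(xs) else rep(fixed$S1, n)
      erk_of(S1, xs)
    },
    FGF = {
      S1 <- if (is.null(fixed$S1)) 0.3 else fixed$S1
      S2 <- if (!is.null(fixed$S2)) fixed$S2 else s2_from_s1(S1)
      erk_of(rep(S1, n), rep(S2, n), fgf = xs)
    },
    ephrin = {
      S1 <- if (is.null(fixed$S1)) 0.3 else fixed$S1
      S2 <- if (!is.null(fixed$S2)) fixed$S2 else s2_from_s1(S1)
      vapply(xs, function(e) erk_of(S1, S2, eph = e), numeric(1))
    },
    erk_star = xs)

  ys <- if (response == "erk") erk else {
    Ap <- activator_steady_state(erk, params)
    I <- if (repressor) repressor_steady_state(erk, params) else rep(0, n)
    otx_steady_state(Ap, I, params)
  }
  structure(list(x_name = x_name, xs = xs, ys = ys, fixed = fixed,
                 coupling = coupling, response = response,
                 repressor = repressor),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("response curve: %s(%s), %d points on [%g, %g], coupling %s\n",
              x$response, x$x_name, length(x$xs), min(x$xs), max(x$xs),
              x$coupling))
  invisible(x)
}

#' Hill coefficient by nonlinear curve fitting
#'
#' Fits `y = baseline + amplitude * x^n / (x^n + K^n)` by Levenberg-Marquardt
#' least squares. Decreasing curves (detected from the overall trend) are
#' reflected into the drop from their top and fit with the same increasing
#' form. With `baseline = "zero"` (default) the baseline is fixed at 0 -- the
#' model's sweeps all start from zero response (or zero drop), so the free
#' intercept adds nothing; `"free"` estimates it.
#'
#' @param curve a `response_curve`, or a list/data frame with `xs` and `ys`.
#' @param baseline `"zero"` or `"free"`.
#' @param n_start initial Hill exponent (bounded to \[0.1, 50\]).
#' @return an object of class `hill_fit`: list with `n_hill`, `half_point`,
#'   `amplitude`, `baseline`, `direction`, `method = "curve_fit"`, `fit_rmse`.
#' @export
fit_hill <- function(curve, baseline = c("zero", "free"), n_start = 1) {
  baseline <- match.arg(baseline)
  x <- curve$xs; y <- curve$ys
  if (length(x) < 4L) stop("need at least 4 points to fit a Hill function")
  increasing <- y[length(y)] >= y[1]
  yy <- if (increasing) y else max(y) - y
  amp0 <- max(yy) - min(yy)
  if (amp0 < 1e-9) stop("curve is flat (amplitude ", signif(amp0, 3),
                        "); cannot fit a Hill function")
  K0 <- x[which.min(abs(yy - (min(yy) + amp0 / 2)))]
  if (K0 <= min(x)) K0 <- mean(range(x))
  df <- data.frame(x = x, y = yy)
  fit <- if (baseline == "free") {
    minpack.lm::nlsLM(y ~ b + a * x^n / (x^n + K^n), data = df,
      start = list(b = min(yy), a = amp0, K = K0, n = n_start),
      lower = c(-Inf, 1e-12, 1e-12, 0.1), upper = c(Inf, Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(y ~ a * x^n / (x^n + K^n), data = df,
      start = list(a = amp0, K = K0, n = n_start),
      lower = c(1e-12, 1e-12, 0.1), upper = c(Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  co <- stats::coef(fit)
  structure(list(
    n_hill = unname(co["n"]),
    half_point = unname(co["K"]),
    amplitude = unname(co["a"]),
    baseline = if (baseline == "free") unname(co["b"]) else 0,
    direction = if (increasing) "increasing" else "decreasing",
    method = "curve_fit",
    fit_rmse = sqrt(mean(stats::resid(fit)^2))
  ), class = "hill_fit")
}

#' Hill coefficient by the potency (EC10/EC90) formula
#'
#' `n_H = log(81) / log(x90 / x10)`, where `x10` and `x90` are the inputs
#' producing 10% and 90% of the maximal response. The maximal response is the
#' supremum over the evaluated domain after subtracting the response at the
#' low-x end; decreasing curves use the drop from their top, reflecting the
#' quantiles. Crossings are located on a monotone spline interpolant of the
#' curve.
#'
#' The estimate is invariant to affine rescaling of the response. It equals
#' the exponent exactly for an ideal Hill curve, but in general differs from
#' the curve-fit estimate: the two are distinct estimators of steepness.
#'
#' @param curve a `response_curve`, or a list/data frame with `xs` and `ys`.
#' @return a `hill_fit` with `method = "potency"`.
#' @export
hill_from_potency <- function(curve) {
  x <- curve$xs; y <- curve$ys
  increasing <- y[length(y)] >= y[1]
  yy <- if (increasing) y - y[1] else y[1] - y
  amp <- max(yy)
  if (amp < 1e-9) stop("curve is flat; potency formula undefined")
  attained <- max(yy) / amp
  if (attained < 0.9 - 1e-12)
    stop("curve attains only ", round(100 * attained), "% of its maximum in ",
         "the domain; 90% level not reached")
  if (any(diff(yy) < -1e-9 * amp))
    warning("curve is not monotone after reflection; potency quantiles may ",
            "be ambiguous")
  f <- stats::splinefun(x, cummax(yy), method = "hyman")
  crossing <- function(level) {
    stats::uniroot(function(z) f(z) - level, range(x), tol = 1e-12)$root
  }
  x10 <- crossing(0.1 * amp)
  x90 <- crossing(0.9 * amp)
  structure(list(
    n_hill = log(81) / log(x90 / x10),
    half_point = crossing(0.5 * amp),
    amplitude = amp,
    baseline = y[1],
    direction = if (increasing) "increasing" else "decreasing",
    method = "potency",
    fit_rmse = NA_real_
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s, %s): n = %.4g, half-point = %.4g\n",
              x$method, x$direction, x$n_hill, x$half_point))
  invisible(x)
}

#' Hill-coefficient difference along a parameter scan
#'
#' For each value of `scan_param` on `scan_values`, rebuilds two response
#' curves and fits both; reports the difference of the second minus the first
#' Hill coefficient, as used in the sensitivity heatmaps comparing e.g.
#' Erk*(S1) against Erk*(\[FGF\]). Fit failures leave `NA` cells.
#'
#' @param params baseline `induction_params`.
#' @param curve_a,curve_b named lists of arguments to [sweep_response()]
#'   (everything except `params`) defining the two curves.
#' @param scan_param name of the parameter field to scan.
#' @param scan_values numeric vector of values for `scan_param`.
#' @param method `"fit"` (curve fitting) or `"potency"`.
#' @return data frame with columns `scan_value`, `n_a`, `n_b`, `delta`
#'   (= `n_b - n_a`).
#' @export
hill_difference_heatmap <- function(params, curve_a, curve_b, scan_param,
                                    scan_values, method = c("fit", "potency")) {
  method <- match.arg(method)
  if (!scan_param %in% .param_fields)
    stop("scan_param must be a model parameter field, got: ", scan_param)
  est <- function(p, args) {
    cv <- do.call(sweep_response, c(list(params = p), args))
    if (method == "fit") fit_hill(cv)$n_hill else hill_from_potency(cv)$n_hill
  }
  rows <- lapply(scan_values, function(v) {
    p <- apply_scenario(params, stats::setNames(list(v), scan_param))
    na <- tryCatch(est(p, curve_a), error = function(e) NA_real_)
    nb <- tryCatch(est(p, curve_b), error = function(e) NA_real_)
    data.frame(scan_value = v, n_a = na, n_b = nb, delta = nb - na)
  })
  do.call(rbind, rows)
}
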