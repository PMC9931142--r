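# Model parameterization and perturbation scenarios.
#
# All parameters are in arbitrary but mutually consistent units: ligand
# concentrations share units with the binding constants Kd/Ke, receptor
# numbers with Ks/Krg, and all rates with the Otx degradation rate k.

.param_fields <- c(
  "fgf_conc", "ephrin_conc", "Kd", "Ke", "R_T", "Q_T",
  "Vs", "Ks", "Vrg", "Krg", "K1", "K2", "Kb", "n_erk", "K_erk",
  "kMM1", "KMM1", "vMM2", "KMM2", "kMM3", "KMM3", "vMM4", "KMM4",
  "vb", "vo", "k", "Ka", "Ki", "coop", "I_clamp"
)

#' Default model parameters
#'
#' Returns the calibrated parameter set of the neural-induction model: ligand
#' concentrations, receptor numbers and binding constants for the FGF and
#' ephrin inputs, the SOS / p120RasGAP / basal-GAP rates of the Ras-GTPase
#' cycle, the Hill description of the ERK cascade, the phosphorylation cycles
#' of the Ets1/2 activator and ERF2 repressor, and the Otx expression rates.
#'
#' Units are arbitrary but consistent. `coop` selects the cooperative (two
#' tandem ETS sites) promoter variant; `I_clamp` optionally fixes the active
#' repressor fraction (used by the ERF2-morpholino scenario) and is `NA` by
#' default.
#'
#' @return An object of class `induction_params`: a named list with fields
#'   `fgf_conc`, `ephrin_conc`, `Kd`, `Ke`, `R_T`, `Q_T`, `Vs`, `Ks`, `Vrg`,
#'   `Krg`, `K1`, `K2`, `Kb`, `n_erk`, `K_erk`, `kMM1`, `KMM1`, `vMM2`,
#'   `KMM2`, `kMM3`, `KMM3`, `vMM4`, `KMM4`, `vb`, `vo`, `k`, `Ka`, `Ki`,
#'   `coop`, `I_clamp`.
#' @examples
#' p <- default_parameters()
#' p$K_erk   # 0.5
#' @export
default_parameters <- function() {
  p <- list(
    fgf_conc = 5, ephrin_conc = 5,
    Kd = 25, Ke = 50,
    R_T = 2000, Q_T = 2000,
    Vs = 1, Ks = 1200,
    Vrg = 0.4, Krg = 1200,
    K1 = 0.5, K2 = 0.2, Kb = 0.2,
    n_erk = 2, K_erk = 0.5,
    kMM1 = 12, KMM1 = 0.05, vMM2 = 1, KMM2 = 0.05,
    kMM3 = 12, KMM3 = 0.05, vMM4 = 1, KMM4 = 0.05,
    vb = 0.001, vo = 1, k = 0.2,
    Ka = 0.1, Ki = 0.1,
    coop = FALSE, I_clamp = NA_real_
  )
  class(p) <- "induction_params"
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks field names and the physical invariants of the model: rates and
#' constants non-negative, strictly positive half-saturation constants,
#' `n_erk >= 1`, `K_erk` in (0, 1).
#'
#' @param params an `induction_params` object or a named list with the same
#'   fields.
#' @return the validated `induction_params` object, invisibly usable in a
#'   pipeline.
#' @export
validate_parameters <- function(params) {
  p <- unclass(params)
  unknown <- setdiff(names(p), .param_fields)
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.param_fields, names(p))
  if (length(missing) > 0L)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  num <- p[setdiff(.param_fields, c("coop", "I_clamp"))]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, logical(1))]
  if (length(bad) > 0L)
    stop("parameter(s) must be finite non-negative scalars: ",
         paste(bad, collapse = ", "))
  pos <- c("K1", "K2", "KMM1", "KMM2", "KMM3", "KMM4", "Ka", "Ki", "k")
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad) > 0L)
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$n_erk < 1) stop("n_erk must be >= 1")
  if (p$K_erk <= 0 || p$K_erk >= 1) stop("K_erk must lie in (0, 1)")
  if (!is.logical(p$coop) || length(p$coop) != 1L || is.na(p$coop))
    stop("coop must be TRUE or FALSE")
  if (!is.na(p$I_clamp) && (p$I_clamp < 0 || p$I_clamp > 1))
    stop("I_clamp must be in [0, 1] or NA")
  p <- p[.param_fields]
  class(p) <- "induction_params"
  p
}

#' @export
print.induction_params <- function(x, ...) {
  cat("Neural-induction model parameters\n")
  num <- unlist(x[setdiff(.param_fields, c("coop", "I_clamp"))])
  print(num)
  cat("coop:", x$coop, " I_clamp:", x$I_clamp, "\n")
  invisible(x)
}

# Named perturbation scenarios and the parameter overrides that represent
# them. dnFGFR and Eph3dC are dominant-negative receptor injections (reduced
# functional receptor numbers), RGdGAP a dominant-negative p120RasGAP, NVP a
# pharmacological Eph inhibitor (ligand effectively removed), U0126_low a
# moderate MEK inhibition (raised ERK half-activation point), and ERF2_MO a
# morpholino preventing ERF2 translation (active repressor clamped low).
.scenario_registry <- list(
  control   = list(),
  dnFGFR    = list(R_T = 100),
  Eph3dC    = list(Q_T = 10),
  RGdGAP    = list(Vrg = 0.01),
  NVP       = list(ephrin_conc = 0.001),
  U0126_low = list(K_erk = 0.6),
  ERF2_MO   = list(I_clamp = 0.01)
)

#' List available perturbation scenarios
#'
#' @return named list mapping scenario names to their parameter overrides.
#' @export
scenario_registry <- function() .scenario_registry

#' Apply a perturbation scenario to a parameter set
#'
#' Returns a copy of `params` with the scenario's overrides applied; the
#' input object is never modified. `"control"` returns an unchanged copy.
#' Several scenarios can be combined (e.g. `c("NVP", "U0126_low")` for Eph
#' inhibition plus moderate MEK inhibition); later overrides win on conflict.
#'
#' @param params an `induction_params` object.
#' @param scenario character vector of registered scenario names, or a named
#'   list of explicit overrides (keys must be parameter fields).
#' @return a new validated `induction_params` object.
#' @examples
#' p <- apply_scenario(default_parameters(), "dnFGFR")
#' p$R_T   # 100
#' @export
apply_scenario <- function(params, scenario) {
  params <- validate_parameters(params)
  if (is.character(scenario)) {
    unknown <- setdiff(scenario, names(.scenario_registry))
    if (length(unknown) > 0L)
      stop("unknown scenario name(s): ", paste(unknown, collapse = ", "),
           "; registered: ", paste(names(.scenario_registry), collapse = ", "))
    overrides <- list()
    for (s in scenario) overrides <- utils::modifyList(overrides, .scenario_registry[[s]])
  } else if (is.list(scenario)) {
    overrides <- scenario
  } else stop("scenario must be a character vector or a named list of overrides")
  bad <- setdiff(names(overrides), .param_fields)
  if (length(bad) > 0L)
    stop("scenario overrides unknown parameter field(s): ",
         paste(bad, collapse = ", "))
  out <- unclass(params)
  out[names(overrides)] <- overrides
  class(out) <- "induction_params"
  validate_parameters(out)
}

#' Read / write parameter files
#'
#' Parameters are stored as one flat YAML or JSON document keyed by the
#' parameter field names. Unknown keys are rejected; omitted keys keep their
#' default values.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_parameters` returns an `induction_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: .", ext)
  )
  if (!is.list(raw)) raw <- as.list(raw)
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown) > 0L)
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  # null entries (JSON null / YAML ~) fall back to their defaults; modifyList
  # would otherwise delete the field outright
  raw <- raw[!vapply(raw, is.null, logical(1))]
  p <- utils::modifyList(unclass(default_parameters()), raw)
  class(p) <- "induction_params"
  validate_parameters(p)
}

#' @param params an `induction_params` object to serialize.
#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 17),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
    stop("unsupported parameter file extension: .", ext)
  )
  invisible(path)
}
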