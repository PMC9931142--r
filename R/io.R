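# CSV interchange, run manifests, and the figure-reproduction driver.

.check_fraction_cols <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0L)
      stop("column ", col, " of ", path, " outside [0, 1] in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(df)
}

#' Read a per-cell geometry CSV
#'
#' Expected columns: `cell_id`, `cell_type`, `S1`; optional `S2` and the
#' b-line columns `S1_A`, `S1_B6.1` .. `S1_B6.4`. All fractions must be
#' decimals in \[0, 1\]; offending rows are named in the error.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_geometry_csv <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "cell_type", "S1")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("geometry file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  frac_cols <- intersect(c("S1", "S2", "S1_A", paste0("S1_B6.", 1:4)),
                         names(df))
  .check_fraction_cols(df, frac_cols, path)
  df
}

#' Read a per-cell measured-readout CSV
#'
#' Expected columns: `cell_id`, `cell_type`, and at least one of `dpERK_IF`
#' (numeric IF signal) and `otx_spots` (non-negative spot count).
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_readouts_csv <- function(path) {
  if (!file.exists(path)) stop("readout file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "cell_type"), names(df))
  if (length(miss) > 0L)
    stop("readout file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!any(c("dpERK_IF", "otx_spots") %in% names(df)))
    stop("readout file ", path, " needs a dpERK_IF or otx_spots column")
  if ("otx_spots" %in% names(df) && any(df$otx_spots < 0))
    stop("otx_spots must be non-negative")
  df
}

#' Write a table as CSV with full-precision floats
#'
#' Floats are serialized at 17 significant digits so that re-reading
#' round-trips bit-for-bit.
#'
#' @param df data frame to write.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce an output bit-for-bit:
#' the command tag, the full parameter snapshot, scenario, seed, package
#' version and input-file digests.
#'
#' @param command character tag of the operation.
#' @param params the `induction_params` used.
#' @param scenario scenario name(s) applied, or `"control"`.
#' @param seed seed used by stochastic steps (`NA` for deterministic runs).
#' @param inputs character vector of input file paths to digest.
#' @return a list; serialize with [write_manifest()].
#' @export
run_manifest <- function(command, params, scenario = "control", seed = NA,
                         inputs = character(0)) {
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  list(command = command,
       package_version = as.character(utils::packageVersion("otxinduction")),
       scenario = scenario,
       seed = seed,
       parameters = unclass(validate_parameters(params)),
       input_digests = digests)
}

#' @param manifest a manifest from [run_manifest()].
#' @param path output JSON path.
#' @rdname run_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Fully symmetric two-pathway parameter configuration
#'
#' Equalizes the FGF>SOS and ephrin>RasGAP legs (same maximal rates,
#' half-saturations, binding constants, receptor numbers and ligand
#' concentrations) with a near-zero basal GAP rate, the configuration used to
#' compare the intrinsic steepnesses of the two inputs.
#'
#' @param params base parameters (default [default_parameters()]).
#' @return an `induction_params` with `Vs = Vrg = 1`, `K1 = K2 = 0.5`,
#'   `Ks = Krg = 1200`, `Kd = Ke = 25`, `R_T = Q_T = 2000`, `Kb = 1e-6`,
#'   both ligands at 5.
#' @export
symmetric_parameters <- function(params = default_parameters()) {
  apply_scenario(params, list(Vs = 1, Vrg = 1, K1 = 0.5, K2 = 0.5,
                              Ks = 1200, Krg = 1200, Kd = 25, Ke = 25,
                              R_T = 2000, Q_T = 2000, Kb = 1e-6,
                              fgf_conc = 5, ephrin_conc = 5))
}

# Cooperative-promoter parameter set used for the cooperativity analyses:
# the two tandem ETS sites replace zero-order ultrasensitivity, so the
# Michaelis constants move out of the zero-order regime.
.cooperative_parameters <- function(params = default_parameters()) {
  apply_scenario(params, list(coop = TRUE, KMM1 = 0.3, KMM2 = 0.3,
                              KMM3 = 0.3, KMM4 = 0.3, kMM1 = 14, kMM3 = 14))
}

.figure_registry <- function() {
  list(
    fig2B = function(p) {
      cv <- sweep_response(p, "S1")
      list(curves = list(erk_vs_S1 = cv),
           coefficients = c(n_erk_S1 = fit_hill(cv)$n_hill))
    },
    fig3F = function(p) {
      with_rep <- sweep_response(p, "erk_star", n = 2001, response = "otx")
      no_rep <- sweep_response(p, "erk_star", n = 2001, response = "otx",
                               repressor = FALSE)
      list(curves = list(otx_with_repressor = with_rep,
                         otx_without_repressor = no_rep),
           coefficients = c(
             n_with_repressor = hill_from_potency(with_rep)$n_hill,
             n_without_repressor = hill_from_potency(no_rep)$n_hill))
    },
    fig5B = function(p) {
      a <- sweep_response(p, "S1")
      b <- sweep_response(p, "FGF", fixed = list(S1 = 0.3))
      list(curves = list(erk_vs_S1 = a, erk_vs_FGF = b),
           coefficients = c(n_erk_S1 = fit_hill(a)$n_hill,
                            n_erk_FGF = fit_hill(b)$n_hill))
    },
    fig5C = function(p) {
      a <- sweep_response(p, "S2")
      b <- sweep_response(p, "ephrin", fixed = list(S1 = 0.3))
      list(curves = list(erk_vs_S2 = a, erk_vs_ephrin = b),
           coefficients = c(n_erk_S2 = fit_hill(a)$n_hill,
                            n_erk_ephrin = fit_hill(b)$n_hill))
    },
    fig5D = function(p) {
      pn <- apply_scenario(p, "NVP")
      cv <- sweep_response(pn, "S1")
      list(curves = list(erk_vs_S1_no_ephrin = cv),
           coefficients = c(n_erk_S1_no_ephrin = fit_hill(cv)$n_hill))
    },
    fig5E = function(p) {
      pn <- apply_scenario(p, "NVP")
      cv <- sweep_response(pn, "FGF", fixed = list(S1 = 0.3))
      list(curves = list(erk_vs_FGF_no_ephrin = cv),
           coefficients = c(n_erk_FGF_no_ephrin = fit_hill(cv)$n_hill))
    },
    fig6A = function(p) {
      a <- sweep_response(p, "S1", fixed = list(S2 = 0.3),
                          coupling = "independent")
      b <- sweep_response(p, "S2", fixed = list(S1 = 0.3),
                          coupling = "independent")
      list(curves = list(erk_vs_S1_fixed_S2 = a, erk_vs_S2_fixed_S1 = b),
           coefficients = c(n_erk_S1 = fit_hill(a)$n_hill,
                            n_erk_S2 = fit_hill(b)$n_hill))
    },
    fig6C = function(p) {
      ps <- symmetric_parameters(p)
      a <- sweep_response(ps, "FGF", fixed = list(S1 = 0.5, S2 = 0.5),
                          coupling = "independent")
      b <- sweep_response(ps, "ephrin", fixed = list(S1 = 0.5, S2 = 0.5),
                          coupling = "independent")
      list(curves = list(erk_vs_FGF_sym = a, erk_vs_ephrin_sym = b),
           coefficients = c(n_erk_FGF_sym = fit_hill(a)$n_hill,
                            n_erk_ephrin_sym = fit_hill(b)$n_hill))
    },
    fig6E = function(p) {
      with_rep <- sweep_response(p, "S1", n = 2001, response = "otx")
      no_rep <- sweep_response(p, "S1", n = 2001, response = "otx",
                               repressor = FALSE)
      list(curves = list(otx_vs_S1_with_repressor = with_rep,
                         otx_vs_S1_without_repressor = no_rep),
           coefficients = c(
             n_with_repressor = hill_from_potency(with_rep)$n_hill,
             n_without_repressor = hill_from_potency(no_rep)$n_hill))
    },
    s7E = function(p) {
      pc <- .cooperative_parameters(p)
      with_rep <- sweep_response(pc, "erk_star", n = 2001, response = "otx")
      no_rep <- sweep_response(pc, "erk_star", n = 2001, response = "otx",
                               repressor = FALSE)
      list(curves = list(otx_coop_with_repressor = with_rep,
                         otx_coop_without_repressor = no_rep),
           coefficients = c(
             n_with_repressor = hill_from_potency(with_rep)$n_hill,
             n_without_repressor = hill_from_potency(no_rep)$n_hill))
    }
  )
}

#' Reproduce a published figure panel's numeric content
#'
#' Runs the exact sweep-and-fit configuration behind a panel and returns the
#' curves and Hill coefficients, together with a manifest. If `out_dir` is
#' given, each curve is written as a full-precision CSV and the manifest as
#' JSON; repeated runs produce byte-identical files.
#'
#' @param tag one of `"fig2B"`, `"fig3F"`, `"fig5B"`, `"fig5C"`, `"fig5D"`,
#'   `"fig5E"`, `"fig6A"`, `"fig6C"`, `"fig6E"`, `"s7E"`.
#' @param params base parameters (default [default_parameters()]).
#' @param out_dir optional output directory.
#' @return list with `tag`, `curves` (named `response_curve`s),
#'   `coefficients` (named numeric) and `manifest`.
#' @export
reproduce_figure <- function(tag, params = default_parameters(),
                             out_dir = NULL) {
  reg <- .figure_registry()
  if (!tag %in% names(reg))
    stop("unknown figure tag: ", tag, "; available: ",
         paste(names(reg), collapse = ", "))
  res <- reg[[tag]](params)
  res$tag <- tag
  res$manifest <- run_manifest(paste0("figure:", tag), params)
  res$manifest$coefficients <- as.list(res$coefficients)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$curves)) {
      cv <- res$curves[[nm]]
      write_table_csv(data.frame(x = cv$xs, y = cv$ys),
                      file.path(out_dir, paste0(tag, "_", nm, ".csv")))
    }
    write_manifest(res$manifest,
                   file.path(out_dir, paste0(tag, "_manifest.json")))
  }
  res
}
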