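# Packaged study fixtures: the two opioid compounds, their five dosing
# regimens, the skin-disposition parameter table, and the printed
# calculated/predicted PK-output pairs used by the fold-error golden tests.

.fixture_cache <- new.env(parent = emptyenv())

#' Packaged study fixtures
#'
#' Returns the versioned fixture document shipped with the package: compound
#' parameter sets, dosing regimens, per-compound skin partition/resistance
#' parameters, and the calculated/predicted PK-output pairs from the source
#' validation study.
#'
#' @return A named list (parsed JSON).
#' @keywords internal
study_fixtures <- function() {
  if (is.null(.fixture_cache$data)) {
    path <- system.file("extdata", "study_fixtures.json", package = "skinsim")
    .fixture_cache$data <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .fixture_cache$data
}

#' Load a packaged compound fixture
#'
#' The two study compounds are a hydrophilic full opioid agonist (oxycodone,
#' logP 0.255) and a highly lipophilic agonist-antagonist (buprenorphine,
#' logP 4.98). All pharmacokinetic constants are packaged verbatim from the
#' source study; molecular weights are standard-reference values.
#'
#' @param name `"oxycodone"` or `"buprenorphine"`.
#' @return A [compound_profile()].
#' @examples
#' load_fixture_compound("oxycodone")
#' @export
load_fixture_compound <- function(name) {
  fx <- study_fixtures()$compounds
  if (!name %in% names(fx))
    stop_user("unknown compound fixture '", name, "'; available: ",
              paste(names(fx), collapse = ", "))
  p <- fx[[name]]
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  compound_profile(name = p$name, logP = p$logP, mw = p$mw,
                   fu_plasma = p$fu_plasma, bp_ratio = p$bp_ratio,
                   clearance = p$clearance, kp_tissue = p$kp_tissue,
                   f_derm = p$f_derm, k_perm_total = p$k_perm_total,
                   pka_acid = num(p$pka_acid), pka_base = num(p$pka_base),
                   f_oral = num(p$f_oral), ka_oral = num(p$ka_oral))
}

#' Load a packaged dosing regimen
#'
#' Five regimens are packaged: `oxycodone_iv` (6.75 mg bolus, 0.1 mg/kg for a
#' 67.5 kg subject), `oxycodone_oral` (15 mg), `oxycodone_td` (three 40 cm^2
#' patches of 23.4 mg each worn 72 h), `buprenorphine_iv` (1.2 mg bolus) and
#' `buprenorphine_td` (10 ug/h system, 1.68 mg over a 168 h wear).
#'
#' @param name Regimen identifier.
#' @return A [dose_regimen()].
#' @examples
#' load_fixture_regimen("buprenorphine_td")
#' @export
load_fixture_regimen <- function(name) {
  fx <- study_fixtures()$regimens
  if (!name %in% names(fx))
    stop_user("unknown regimen fixture '", name, "'; available: ",
              paste(names(fx), collapse = ", "))
  r <- fx[[name]]
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  dose_regimen(route = r$route, dose_mg = r$dose_mg,
               sim_duration_h = r$sim_duration_h,
               surface_area_cm2 = num(r$surface_area_cm2),
               wear_duration_h = num(r$wear_duration_h))
}

#' Packaged skin-disposition parameters for a fixture compound
#'
#' Per-compound water-referenced partition coefficients of the stratum
#' corneum and dermis, and the raw per-layer permeation resistances whose
#' ratios define the layer resistance split. The raw resistances are
#' renormalized against the compound's fitted total permeability by
#' [compound_skin_state()].
#'
#' @param name Compound fixture name.
#' @return A list with elements `k_sc_water`, `k_de_water` and
#'   `raw_resistance` (named vector `sc`, `ve`, `de`, h/cm).
#' @export
load_fixture_skin_params <- function(name) {
  fx <- study_fixtures()$skin_params
  if (!name %in% names(fx))
    stop_user("unknown skin-parameter fixture '", name, "'; available: ",
              paste(names(fx), collapse = ", "))
  p <- fx[[name]]
  list(k_sc_water = p$k_sc_water, k_de_water = p$k_de_water,
       raw_resistance = unlist(p$raw_resistance)[c("sc", "ve", "de")])
}

#' Printed calculated/predicted PK-output pairs of the source study
#'
#' One row per compound x route x PK output (AUC_0-t, Cmax, tmax) with the
#' noncompartmentally recalculated ("calculated", treated as observed) and
#' model-predicted values, plus the fold-error statistics printed alongside
#' them. Cells whose printed statistic cannot be recovered from the printed
#' concentration pairs at 2 decimal places (the source evidently used
#' unrounded values) are flagged `rounding_limited`.
#'
#' @return A data frame; see also [recompute_study_fold_errors()].
#' @export
study_fold_error_cells <- function() {
  as.data.frame(study_fixtures()$fold_error_cells)
}

#' @rdname study_fold_error_cells
#' @export
study_fold_error_columns <- function() {
  as.data.frame(study_fixtures()$fold_error_columns)
}
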