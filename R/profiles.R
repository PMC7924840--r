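# Domain types: compound profiles, dosing regimens, concentration-time profiles.

stop_user <- function(...) {
  stop(structure(class = c("skinsim_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("skinsim_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_fraction <- function(x, what) {
  if (!is.na(x) && (!is.numeric(x) || x < 0 || x > 1))
    stop_user(what, " must be a fraction in [0, 1], got ", x)
  invisible(x)
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || is.na(x) || x <= 0)
    stop_user(what, " must be strictly positive, got ", x)
  invisible(x)
}

#' Create a compound profile
#'
#' Bundles the physicochemical descriptors and pharmacokinetic constants that
#' drive both the skin-barrier algebra and the systemic disposition model.
#'
#' @param name Compound name.
#' @param logP Octanol-water log10 partition coefficient (dimensionless).
#' @param mw Molecular weight (g/mol).
#' @param fu_plasma Fraction unbound in plasma, in `[0, 1]`.
#' @param bp_ratio Blood:plasma concentration ratio (dimensionless).
#' @param clearance Systemic clearance (L/h).
#' @param kp_tissue Tissue:plasma partition coefficient (dimensionless).
#' @param f_derm Dermal bioavailability fraction, in `[0, 1]`.
#' @param k_perm_total Total skin permeability coefficient (cm/h).
#' @param pka_acid,pka_base Acidic/basic pKa. Carried as free descriptor
#'   fields; no ionization correction is applied by the default models.
#' @param f_oral Oral bioavailability fraction, or `NA` when the compound has
#'   no oral route.
#' @param ka_oral First-order oral absorption rate constant (1/h), or `NA`.
#' @return An object of class `compound_profile`.
#' @seealso [load_fixture_compound()] for the packaged study compounds.
#' @export
compound_profile <- function(name, logP, mw, fu_plasma, bp_ratio, clearance,
                             kp_tissue, f_derm, k_perm_total,
                             pka_acid = NA_real_, pka_base = NA_real_,
                             f_oral = NA_real_, ka_oral = NA_real_) {
  check_positive(mw, "mw")
  check_positive(clearance, "clearance")
  check_positive(k_perm_total, "k_perm_total")
  check_fraction(fu_plasma, "fu_plasma")
  check_fraction(f_derm, "f_derm")
  check_fraction(f_oral, "f_oral")
  structure(list(
    name = as.character(name), logP = as.numeric(logP), mw = as.numeric(mw),
    pka_acid = as.numeric(pka_acid), pka_base = as.numeric(pka_base),
    fu_plasma = as.numeric(fu_plasma), bp_ratio = as.numeric(bp_ratio),
    clearance = as.numeric(clearance), kp_tissue = as.numeric(kp_tissue),
    f_oral = as.numeric(f_oral), f_derm = as.numeric(f_derm),
    ka_oral = as.numeric(ka_oral), k_perm_total = as.numeric(k_perm_total)
  ), class = "compound_profile")
}

#' @export
print.compound_profile <- function(x, ...) {
  cat("<compound_profile> ", x$name, "\n", sep = "")
  cat(sprintf("  logP %.3g | MW %.4g g/mol | fu,p %.3g | B:P %.3g\n",
              x$logP, x$mw, x$fu_plasma, x$bp_ratio))
  cat(sprintf("  CL %.4g L/h | Kp %.4g | k_perm %.3g cm/h | F_derm %.4g\n",
              x$clearance, x$kp_tissue, x$k_perm_total, x$f_derm))
  if (!is.na(x$f_oral))
    cat(sprintf("  F_oral %.4g | ka %.4g 1/h\n", x$f_oral, x$ka_oral))
  invisible(x)
}

#' Create a dosing regimen
#'
#' @param route One of `"IV"`, `"ORAL"`, `"TD"`.
#' @param dose_mg Dose (mg); for transdermal regimens the total drug content
#'   of the applied formulation.
#' @param sim_duration_h Simulated observation window (h).
#' @param surface_area_cm2 Application surface area (cm^2); required for TD.
#' @param wear_duration_h Patch wear time (h); required for TD. Input to the
#'   body is cut to zero at patch removal.
#' @param vehicle Vehicle label; the packaged models treat the vehicle as
#'   water-like with respect to partitioning.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(route, dose_mg, sim_duration_h,
                         surface_area_cm2 = NA_real_,
                         wear_duration_h = NA_real_,
                         vehicle = "water-like") {
  route <- toupper(route)
  if (!route %in% c("IV", "ORAL", "TD"))
    stop_user("route must be one of IV, ORAL, TD, got '", route, "'")
  check_positive(dose_mg, "dose_mg")
  check_positive(sim_duration_h, "sim_duration_h")
  if (route == "TD") {
    check_positive(surface_area_cm2, "surface_area_cm2 (TD regimen)")
    check_positive(wear_duration_h, "wear_duration_h (TD regimen)")
  }
  structure(list(route = route, dose_mg = as.numeric(dose_mg),
                 surface_area_cm2 = as.numeric(surface_area_cm2),
                 wear_duration_h = as.numeric(wear_duration_h),
                 sim_duration_h = as.numeric(sim_duration_h),
                 vehicle = vehicle),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat("<dose_regimen> ", x$route, " ", x$dose_mg, " mg", sep = "")
  if (x$route == "TD")
    cat(sprintf(" | %g cm2 | wear %g h", x$surface_area_cm2, x$wear_duration_h))
  cat(sprintf(" | simulate %g h\n", x$sim_duration_h))
  invisible(x)
}

#' Create a concentration-time profile
#'
#' Carrier for plasma or skin-layer concentration time series, used as the
#' common currency between the simulator, the noncompartmental analysis and
#' the fold-error validation machinery.
#'
#' @param times Sampling times (h); strictly increasing, first value >= 0.
#' @param values Concentrations (same length as `times`, all >= 0).
#' @param label Compartment or layer tag.
#' @param units Unit tag (plasma in ug/L, skin layers in mg/cm3).
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(times, values, label = "plasma", units = "ug/L") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop_user("times and values must have equal length")
  if (length(times) < 1 || times[1] < 0 || any(diff(times) <= 0))
    stop_user("times must be strictly increasing with first value >= 0")
  if (any(!is.finite(values)) || any(values < 0))
    stop_user("values must be finite and non-negative")
  structure(list(times = times, values = values,
                 label = label, units = units),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s [%s], %d points on [%g, %g] h, Cmax %.4g\n",
              x$label, x$units, length(x$times), min(x$times), max(x$times),
              max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(time_h = x$times, conc = x$values,
             unit = x$units, label = x$label,
             stringsAsFactors = FALSE)
}

#' Read / write concentration profiles as CSV
#'
#' The on-disk format is a plain CSV with header `time_h,conc,unit,label`,
#' the format emitted by the simulation commands and consumed by the NCA and
#' validation commands.
#'
#' @param path File path.
#' @return `read_profile_csv()` returns a `conc_profile`.
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop_user("profile CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc")
  if (!all(need %in% names(df)))
    stop_user("profile CSV must have columns time_h, conc (got: ",
              paste(names(df), collapse = ", "), ")")
  conc_profile(df$time_h, df$conc,
               label = if ("label" %in% names(df)) df$label[1] else "profile",
               units = if ("unit" %in% names(df)) df$unit[1] else "ug/L")
}

#' @rdname read_profile_csv
#' @param profile A `conc_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Generate a synthetic observed profile
#'
#' Applies multiplicative lognormal noise to a noise-free simulated profile,
#' standing in for digitized literature observations when exercising the NCA
#' and fold-error validation machinery. The noise is median-unbiased
#' (`log`-scale mean zero) with `sdlog = sqrt(log(1 + cv^2))`, so the
#' expected value of a noisy point is `truth * exp(sdlog^2 / 2)` and the
#' median of the generated/truth ratio tends to 1.
#'
#' @param truth A `conc_profile` of noise-free values.
#' @param cv Coefficient of variation of the multiplicative error (>= 0);
#'   `cv = 0` returns the input unchanged. When imputing observation error
#'   from a reported percent SD of Cmax, pass that percent / 100.
#' @param seed Integer seed; generation is reproducible for a fixed seed and
#'   the global RNG state is left untouched.
#' @return A `conc_profile` with the same times.
#' @export
generate_observed_profile <- function(truth, cv, seed) {
  if (!inherits(truth, "conc_profile")) stop_user("truth must be a conc_profile")
  if (!is.numeric(cv) || is.na(cv) || cv < 0)
    stop_user("cv must be a non-negative number")
  if (cv == 0) return(truth)
  sdlog <- sqrt(log1p(cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  noisy <- truth$values * exp(stats::rnorm(length(truth$values), 0, sdlog))
  conc_profile(truth$times, noisy, label = paste0(truth$label, "_observed"),
               units = truth$units)
}
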