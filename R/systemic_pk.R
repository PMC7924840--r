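# Reduced lumped-compartment systemic disposition model driven by the
# transdermal input law. The body is central (plasma + well-perfused) plus
# one perfusion-limited lumped tissue; elimination is linear clearance from
# central. Transdermal input follows the flux law
#   rate = SA * C_vehicle(t) * F_derm * k_perm_effective,
# with C_vehicle(t) = depot_mass / (SA * vehicle_thickness), i.e. a finite
# first-order-depleting vehicle depot; input is hard-zeroed at patch removal.

#' Construct the reduced systemic disposition model
#'
#' @param compound A [compound_profile()] supplying clearance, the
#'   tissue:plasma partition coefficient and the blood:plasma ratio.
#' @param v_central Central (plasma + well-perfused) volume (L).
#' @param v_tissue Lumped peripheral tissue volume (L).
#' @param q_tissue Tissue perfusion flow (L/h).
#' @return An object of class `systemic_model`.
#' @export
systemic_model <- function(compound, v_central = 15, v_tissue = 35,
                           q_tissue = 5) {
  if (!inherits(compound, "compound_profile"))
    stop_user("compound must be a compound_profile")
  check_positive(v_central, "v_central")
  check_positive(v_tissue, "v_tissue")
  check_positive(q_tissue, "q_tissue")
  structure(list(v_central = v_central, v_tissue = v_tissue,
                 q_tissue = q_tissue, clearance = compound$clearance,
                 kp_tissue = compound$kp_tissue, bp_ratio = compound$bp_ratio),
            class = "systemic_model")
}

#' @export
print.systemic_model <- function(x, ...) {
  cat(sprintf(
    "<systemic_model> Vc %g L | Vt %g L | Q %g L/h | CL %g L/h | Kp %.4g\n",
    x$v_central, x$v_tissue, x$q_tissue, x$clearance, x$kp_tissue))
  invisible(x)
}

# First-order depot rate constant of the transdermal input law (1/h).
# SA cancels: rate = SA * [A/(SA*h)] * F_derm * k = A * F_derm * k / h.
td_depot_rate_constant <- function(f_derm, k_perm_effective, vehicle_thickness) {
  f_derm * k_perm_effective / vehicle_thickness
}

pk_derivs <- function(t, y, p) {
  in_td <- if (p$route == "TD" && t <= p$wear) p$k_dep * y[["depot"]] else 0
  in_oral <- if (p$route == "ORAL") p$ka * y[["gut"]] else 0
  cc <- y[["central"]] / p$vc
  ct <- y[["tissue"]] / p$vt
  list(c(
    depot = -in_td,
    gut = -in_oral,
    central = in_td + in_oral + p$q * (ct / p$kp - cc) - p$cl * cc,
    tissue = p$q * (cc - ct / p$kp),
    eliminated = p$cl * cc
  ))
}

#' Simulate a plasma concentration-time profile
#'
#' Routes: `IV` is a bolus into the central compartment; `ORAL` is
#' first-order absorption of the bioavailable fraction (`ka_oral`,
#' `f_oral`); `TD` drives the central compartment with the transdermal flux
#' law from a finite vehicle depot that depletes by exactly the absorbed
#' mass, with input forced to zero after the patch wear time. Disposition is
#' linear two-compartment (perfusion-limited lumped tissue) with clearance
#' from central.
#'
#' @param compound A [compound_profile()].
#' @param regimen A [dose_regimen()] route-consistent with the compound
#'   (oral requires `f_oral`/`ka_oral`).
#' @param skin Optional [skin_state()]; for TD its
#'   [effective_total_permeability()] replaces the compound's healthy
#'   `k_perm_total` (lesioned states permeate faster). Ignored for IV/ORAL.
#' @param model A [systemic_model()]; defaults to `systemic_model(compound)`.
#' @param grid Output time grid (h), strictly increasing from 0; defaults to
#'   `n_points` equally spaced points over the regimen's window.
#' @param n_points Size of the default grid.
#' @param vehicle_thickness Applied vehicle film thickness (cm), defining
#'   the vehicle volume `SA * thickness`.
#' @param rtol,atol Solver tolerances (lsoda).
#' @return A [conc_profile()] in ug/L with attribute `"balance"`: a data
#'   frame of compartment amounts (mg) over time for mass-balance auditing.
#' @examples
#' bup <- load_fixture_compound("buprenorphine")
#' prof <- simulate_plasma(bup, load_fixture_regimen("buprenorphine_td"))
#' @export
simulate_plasma <- function(compound, regimen, skin = NULL,
                            model = systemic_model(compound), grid = NULL,
                            n_points = 1000, vehicle_thickness = 0.01,
                            rtol = 1e-8, atol = 1e-12) {
  if (!inherits(regimen, "dose_regimen"))
    stop_user("regimen must be a dose_regimen")
  if (is.null(grid))
    grid <- seq(0, regimen$sim_duration_h, length.out = n_points)
  if (grid[1] != 0 || any(diff(grid) <= 0))
    stop_user("grid must be strictly increasing and start at 0")
  route <- regimen$route

  k_eff <- NA_real_
  if (route == "TD") {
    k_eff <- if (is.null(skin)) compound$k_perm_total else
      effective_total_permeability(skin)
    if (k_eff < 0) stop_user("effective permeability must be non-negative")
    check_positive(vehicle_thickness, "vehicle_thickness")
  }
  if (route == "ORAL" && (is.na(compound$f_oral) || is.na(compound$ka_oral)))
    stop_user("compound '", compound$name,
              "' has no oral parameters (f_oral/ka_oral)")

  y0 <- c(depot = 0, gut = 0, central = 0, tissue = 0, eliminated = 0)
  if (route == "IV") y0[["central"]] <- regimen$dose_mg
  if (route == "ORAL") y0[["gut"]] <- compound$f_oral * regimen$dose_mg
  if (route == "TD") y0[["depot"]] <- regimen$dose_mg

  p <- list(route = route, vc = model$v_central, vt = model$v_tissue,
            q = model$q_tissue, cl = model$clearance, kp = model$kp_tissue,
            ka = compound$ka_oral,
            k_dep = if (route == "TD")
              td_depot_rate_constant(compound$f_derm, k_eff, vehicle_thickness)
            else 0,
            wear = if (route == "TD") regimen$wear_duration_h else Inf)

  solve_segment <- function(times, y) {
    out <- tryCatch(
      deSolve::ode(y = y, times = times, func = pk_derivs, parms = p,
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop_numeric("ODE solver warning: ",
                                         conditionMessage(w)))
    as.data.frame(out)
  }

  wear <- p$wear
  if (route == "TD" && wear < max(grid)) {
    # patch removal is a derivative discontinuity: integrate piecewise
    t1 <- sort(unique(c(grid[grid <= wear], wear)))
    seg1 <- solve_segment(t1, y0)
    y1 <- unlist(seg1[nrow(seg1), names(y0)])
    t2 <- sort(unique(c(wear, grid[grid > wear])))
    seg2 <- solve_segment(t2, y1)
    out <- rbind(seg1[seg1$time %in% grid, ],
                 seg2[seg2$time %in% grid & seg2$time > wear, ])
  } else {
    out <- solve_segment(grid, y0)
  }

  conc <- pmax(out$central / model$v_central * 1000, 0)  # mg/L -> ug/L
  prof <- conc_profile(out$time, conc,
                       label = paste0(compound$name, "_plasma_", tolower(route)),
                       units = "ug/L")
  attr(prof, "balance") <- out
  attr(prof, "k_perm_effective") <- k_eff
  prof
}

#' Time-dependent skin-layer concentration profiles
#'
#' For a transdermal regimen, each intact layer's apical concentration is
#' the quasi-steady barrier solution evaluated at the instantaneous vehicle
#' concentration, i.e. the steady-state value scaled by the fraction of
#' depot remaining: the depot depletes exponentially with rate constant
#' `F_derm * k_perm_effective / vehicle_thickness` during wear, and the
#' profiles drop to zero at patch removal. Lesioned runs emit no stratum
#' corneum profile.
#'
#' @inheritParams simulate_plasma
#' @param skin A [skin_state()]; defaults to the healthy fixture/QSPR state
#'   of the compound.
#' @return Named list of [conc_profile()] objects (mg/cm^3), one per intact
#'   layer (`sc`, `ve`, `de` or `ve`, `de` for lesioned skin).
#' @export
simulate_skin_layers <- function(compound, regimen, skin = NULL, grid = NULL,
                                 n_points = 1000, vehicle_thickness = 0.01) {
  if (!inherits(regimen, "dose_regimen"))
    stop_user("regimen must be a dose_regimen")
  if (regimen$route != "TD")
    stop_user("skin-layer simulation requires a TD regimen, got ",
              regimen$route)
  if (is.null(skin)) skin <- compound_skin_state(compound)
  if (is.null(grid))
    grid <- seq(0, regimen$sim_duration_h, length.out = n_points)
  check_positive(vehicle_thickness, "vehicle_thickness")

  c_dose0 <- regimen$dose_mg / (regimen$surface_area_cm2 * vehicle_thickness)
  k_dep <- td_depot_rate_constant(compound$f_derm,
                                  effective_total_permeability(skin),
                                  vehicle_thickness)
  frac <- ifelse(grid <= regimen$wear_duration_h, exp(-k_dep * grid), 0)

  ss <- if (skin$lesion)
    lesion_skin_concentrations(c_dose0, skin, compound$f_derm)
  else
    healthy_skin_concentrations(c_dose0, skin, compound$f_derm)

  layers <- if (skin$lesion) c(ve = ss$c_ve, de = ss$c_de)
            else c(sc = ss$c_sc, ve = ss$c_ve, de = ss$c_de)
  lapply(stats::setNames(names(layers), names(layers)), function(l)
    conc_profile(grid, layers[[l]] * frac,
                 label = paste0(compound$name, "_", l), units = "mg/cm3"))
}

#' Lesion-to-healthy fold change of a plasma exposure metric
#'
#' Runs paired transdermal simulations on a shared grid with the healthy and
#' the lesioned (stratum corneum removed) barrier and reports the ratio of
#' the chosen exposure metric.
#'
#' @inheritParams simulate_plasma
#' @param metric `"cmax"` or `"auc_0t"` (linear-trapezoid AUC over the grid).
#' @param ... Passed on to [simulate_plasma()].
#' @return Dimensionless fold change (lesion / healthy).
#' @examples
#' bup <- load_fixture_compound("buprenorphine")
#' lesion_fold_change(bup, load_fixture_regimen("buprenorphine_td"), "cmax")
#' @export
lesion_fold_change <- function(compound, regimen, metric = c("cmax", "auc_0t"),
                               grid = NULL, n_points = 1000, ...) {
  metric <- match.arg(metric)
  if (regimen$route != "TD")
    stop_user("lesion fold change requires a TD regimen")
  if (is.null(grid))
    grid <- seq(0, regimen$sim_duration_h, length.out = n_points)
  healthy <- simulate_plasma(compound, regimen,
                             skin = compound_skin_state(compound, lesion = FALSE),
                             grid = grid, ...)
  lesion <- simulate_plasma(compound, regimen,
                            skin = compound_skin_state(compound, lesion = TRUE),
                            grid = grid, ...)
  if (metric == "cmax") {
    max(lesion$values) / max(healthy$values)
  } else {
    trapezoid_auc(grid, lesion$values) / trapezoid_auc(grid, healthy$values)
  }
}
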