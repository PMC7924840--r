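# QSPR layer-property prediction and the resistance-in-series barrier
# algebra: per-layer permeability k_i = D_i / delta_i, resistance R_i = 1/k_i,
# serial addition R_total = R_SC + R_VE + R_De, and renormalization of raw
# QSPR permeabilities against an observed total skin permeability.

#' Default skin layer thicknesses
#'
#' Stratum corneum 20 um, viable epidermis 100 um, dermis 3000 um.
#'
#' @return Named numeric vector (cm) with elements `sc`, `ve`, `de`.
#' @export
skin_thickness_defaults <- function() {
  c(sc = 0.002, ve = 0.01, de = 0.3)
}

#' Viable-epidermis : stratum-corneum partition coefficient
#'
#' No direct QSPR model exists for VE:SC partitioning; it is closed through
#' water as K_VE:SC = K_VE:water / K_SC:water. Under the standard assumption
#' that the viable epidermis partitions like the dermis, callers pass the
#' dermis:water coefficient as `k_ve_water`.
#'
#' @param k_ve_water VE(= dermis):water partition coefficient (> 0).
#' @param k_sc_water SC:water partition coefficient (> 0).
#' @return Dimensionless partition coefficient K_VE:SC.
#' @examples
#' partition_ve_sc(57.29, 5.29)  # ~10.83
#' @export
partition_ve_sc <- function(k_ve_water, k_sc_water) {
  check_positive(k_ve_water, "k_ve_water")
  check_positive(k_sc_water, "k_sc_water")
  k_ve_water / k_sc_water
}

# --- model registries ------------------------------------------------------

# SC permeability models return cm/h. The Potts-Guy relation is fitted in
# cm/s; converted at this boundary (x 3600).
.sc_perm_models <- list(
  potts_guy = function(logP, mw) 10^(-6.3 + 0.71 * logP - 0.0061 * mw) * 3600
)

# Dermis/viable-epidermis diffusivity models return cm^2/h.
.de_diffusivity_models <- list(
  kretsos = function(mw) 10^(-4.15 - 0.655 * log10(mw)) * 3600
)

registry_get <- function(registry, key, what) {
  if (!key %in% names(registry))
    stop_user("unknown ", what, " model '", key, "'; available: ",
              paste(names(registry), collapse = ", "))
  registry[[key]]
}

#' Predict stratum corneum permeability from compound descriptors
#'
#' Default model is the Potts-Guy QSPR,
#' `log10 kp[cm/s] = -6.3 + 0.71 logP - 0.0061 MW`, converted to cm/h.
#'
#' @param logP Octanol-water log10 partition coefficient.
#' @param mw Molecular weight (g/mol, >= 0).
#' @param model Registry key; currently `"potts_guy"`.
#' @return Permeability coefficient (cm/h).
#' @examples
#' predict_sc_permeability(0.255, 315.36)
#' @export
predict_sc_permeability <- function(logP, mw, model = "potts_guy") {
  if (!is.numeric(mw) || is.na(mw) || mw < 0)
    stop_user("mw must be non-negative")
  f <- registry_get(.sc_perm_models, model, "stratum corneum permeability")
  f(logP, mw)
}

#' Predict dermis (and viable epidermis) diffusivity
#'
#' Kretsos-style molecular-weight power law for free diffusion in the mostly
#' aqueous dermis; the viable epidermis is assigned the same diffusivity
#' (equivalent-diffusivity assumption for the two living layers).
#'
#' @param mw Molecular weight (g/mol, > 0).
#' @param model Registry key; currently `"kretsos"`.
#' @return Diffusivity (cm^2/h).
#' @export
predict_de_diffusivity <- function(mw, model = "kretsos") {
  check_positive(mw, "mw")
  f <- registry_get(.de_diffusivity_models, model, "dermis diffusivity")
  f(mw)
}

# Calibrated log-linear partition model: log10 K = a + b * logP per layer,
# with (a, b) solved from the two packaged anchor compounds so the packaged
# skin parameter table is reproduced exactly. Computed lazily from fixtures.
calibrated_partition_coefs <- function() {
  if (is.null(.fixture_cache$part_coefs)) {
    cmp <- study_fixtures()$compounds
    skn <- study_fixtures()$skin_params
    lp <- c(cmp$oxycodone$logP, cmp$buprenorphine$logP)
    fit <- function(k) {
      b <- (log10(k[2]) - log10(k[1])) / (lp[2] - lp[1])
      c(a = log10(k[1]) - b * lp[1], b = b)
    }
    .fixture_cache$part_coefs <- list(
      SC = fit(c(skn$oxycodone$k_sc_water, skn$buprenorphine$k_sc_water)),
      De = fit(c(skn$oxycodone$k_de_water, skn$buprenorphine$k_de_water))
    )
  }
  .fixture_cache$part_coefs
}

#' Predict a layer:water partition coefficient
#'
#' Two registry models are available. `"calibrated"` (default) is a
#' log-linear model in logP per layer whose two coefficients are anchored to
#' the packaged skin parameter table for the two study compounds, so it
#' reproduces those values exactly. `"kow_power"` is a generic
#' lipophilicity power law `K = Kow^e` (exponent 0.76 for the lipid-rich
#' stratum corneum, 0.33 for the mostly aqueous dermis) provided as a
#' literature-style fallback for unanchored compounds.
#'
#' @param logP Octanol-water log10 partition coefficient (finite).
#' @param layer `"SC"` or `"De"`.
#' @param model Registry key.
#' @return Dimensionless layer:water partition coefficient.
#' @examples
#' predict_partition_water(0.255, "SC")  # ~3.73
#' @export
predict_partition_water <- function(logP, layer = c("SC", "De"),
                                    model = "calibrated") {
  layer <- match.arg(layer)
  if (!is.numeric(logP) || !is.finite(logP)) stop_user("logP must be finite")
  if (model == "calibrated") {
    cf <- calibrated_partition_coefs()[[layer]]
    10^(cf[["a"]] + cf[["b"]] * logP)
  } else if (model == "kow_power") {
    e <- if (layer == "SC") 0.76 else 0.33
    (10^logP)^e
  } else {
    stop_user("unknown partition model '", model,
              "'; available: calibrated, kow_power")
  }
}

# --- layer and partition containers ---------------------------------------

#' Construct a skin layer set
#'
#' Holds, per layer (stratum corneum, viable epidermis, dermis), the
#' thickness, permeability, permeation resistance and back-computed
#' diffusivity, plus serial-resistor totals: `R_total = R_SC + R_VE + R_De`
#' and `k_total = 1 / R_total`.
#'
#' @param k_perm Named numeric vector of per-layer permeabilities (cm/h),
#'   names `sc`, `ve`, `de`, all > 0.
#' @param thickness Named per-layer thicknesses (cm);
#'   defaults to [skin_thickness_defaults()].
#' @return An object of class `layer_set` with fields `thickness`,
#'   `diffusivity`, `k_perm`, `resistance`, `r_total`, `k_total`.
#' @export
layer_set <- function(k_perm, thickness = skin_thickness_defaults()) {
  lay <- c("sc", "ve", "de")
  k_perm <- unlist(k_perm)[lay]
  thickness <- unlist(thickness)[lay]
  if (any(is.na(k_perm)) || any(k_perm <= 0))
    stop_user("k_perm must be positive for layers sc, ve, de")
  if (any(is.na(thickness)) || any(thickness <= 0))
    stop_user("thickness must be positive for layers sc, ve, de")
  resistance <- 1 / k_perm
  structure(list(
    thickness = thickness,
    k_perm = k_perm,
    resistance = resistance,
    diffusivity = k_perm * thickness,
    r_total = sum(resistance),
    k_total = 1 / sum(resistance)
  ), class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  cat("<layer_set>\n")
  df <- data.frame(thickness_cm = x$thickness,
                   k_perm_cm_h = signif(x$k_perm, 4),
                   resistance_h_cm = signif(x$resistance, 6),
                   share = signif(x$resistance / x$r_total, 4))
  print(df)
  cat(sprintf("  total: k %.4g cm/h, R %.6g h/cm\n", x$k_total, x$r_total))
  invisible(x)
}

#' Construct a partition coefficient set
#'
#' Water-referenced partitions for the stratum corneum and dermis, with the
#' VE:SC coefficient closed through water (dermis standing in for the viable
#' epidermis), a unit dermis:viable-epidermis coefficient, and a unit
#' vehicle:water coefficient (water-like vehicle).
#'
#' @param k_sc_water SC:water partition coefficient (> 0).
#' @param k_de_water dermis:water partition coefficient (> 0).
#' @return An object of class `partition_set`.
#' @export
partition_set <- function(k_sc_water, k_de_water) {
  check_positive(k_sc_water, "k_sc_water")
  check_positive(k_de_water, "k_de_water")
  structure(list(
    k_sc_water = k_sc_water,
    k_de_water = k_de_water,
    k_ve_sc = partition_ve_sc(k_de_water, k_sc_water),
    k_de_ve = 1,
    k_vehicle_water = 1
  ), class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf(
    "<partition_set> SC/w %.4g | De/w %.4g | VE/SC %.4g | De/VE %g | veh/w %g\n",
    x$k_sc_water, x$k_de_water, x$k_ve_sc, x$k_de_ve, x$k_vehicle_water))
  invisible(x)
}

#' Renormalize raw layer permeabilities to an observed total
#'
#' Raw QSPR-predicted layer permeabilities rarely add (reciprocally) to the
#' total skin permeability fitted from in vivo data. This operation rescales
#' all raw layer resistances by the single factor
#' `R_target_total / sum(R_raw)`, so that the serial-resistor identity
#' `1/k_total = sum(1/k_i)` holds exactly at the target total while the raw
#' inter-layer resistance proportions are preserved. Layer diffusivities are
#' back-computed from the rescaled permeabilities and thicknesses.
#'
#' @param raw_k Named per-layer permeabilities (cm/h), names `sc`, `ve`, `de`.
#' @param k_perm_total_target Observed/fitted total skin permeability (cm/h).
#' @param thickness Per-layer thicknesses (cm).
#' @return A [layer_set()] with `k_total` equal to the target.
#' @export
renormalize_layer_permeabilities <- function(raw_k, k_perm_total_target,
                                             thickness = skin_thickness_defaults()) {
  check_positive(k_perm_total_target, "k_perm_total_target")
  raw_k <- unlist(raw_k)[c("sc", "ve", "de")]
  if (any(is.na(raw_k)) || any(raw_k <= 0))
    stop_user("raw_k must be positive for layers sc, ve, de")
  raw_r <- 1 / raw_k
  scale <- (1 / k_perm_total_target) / sum(raw_r)
  layer_set(k_perm = 1 / (raw_r * scale), thickness = thickness)
}
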