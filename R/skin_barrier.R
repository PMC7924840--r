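# Steady-state intra-skin concentration algebra for healthy and lesioned
# skin, and the effective barrier permeability used by the systemic model.
#
# Healthy skin (unidirectional diffusion, vehicle ~ water):
#   C_SC = C_Dose * K_SC:vehicle * F_derm
#   C_VE = C_SC * (1 - R_SC / R_total) * K_VE:SC
#   C_De = C_SC * (1 - (R_SC + R_VE) / R_total) * K_VE:SC * K_De:VE
# Lesioned skin (stratum corneum completely disrupted, VE and dermis intact,
# F_derm unchanged):
#   C_VE = C_Dose * K_VE:vehicle * F_derm
#   C_De = C_VE * (1 - R_VE / (R_VE + R_De)) * K_De:VE

#' Construct a skin state
#'
#' Couples a [layer_set()] and [partition_set()] with a lesion flag. In the
#' lesioned state the stratum corneum is treated as completely disrupted:
#' its resistance is excluded from every downstream resistance sum while the
#' viable epidermis and dermis remain intact.
#'
#' @param layers A `layer_set`.
#' @param partitions A `partition_set`.
#' @param lesion Logical; `TRUE` models skin with the stratum corneum removed.
#' @return An object of class `skin_state`.
#' @export
skin_state <- function(layers, partitions, lesion = FALSE) {
  if (!inherits(layers, "layer_set")) stop_user("layers must be a layer_set")
  if (!inherits(partitions, "partition_set"))
    stop_user("partitions must be a partition_set")
  structure(list(lesion = isTRUE(lesion), layers = layers,
                 partitions = partitions),
            class = "skin_state")
}

#' @export
print.skin_state <- function(x, ...) {
  cat("<skin_state>", if (x$lesion) "lesion (SC disrupted)" else "healthy", "\n")
  print(x$layers); print(x$partitions)
  invisible(x)
}

#' Build the skin state for a compound
#'
#' For the packaged study compounds (default `source = "fixture"`), layer
#' resistances take the packaged raw per-layer resistance ratios and are
#' renormalized so the total permeability equals the compound's fitted
#' `k_perm_total`; partition coefficients come from the packaged table. With
#' `source = "qspr"` the full prediction pipeline is used instead: stratum
#' corneum permeability from the Potts-Guy model, a shared dermis/viable
#' epidermis diffusivity from the molecular-weight power law (converted to
#' permeabilities through the layer thicknesses), renormalization to
#' `k_perm_total`, and registry partition models.
#'
#' @param compound A [compound_profile()].
#' @param lesion Logical lesion flag.
#' @param source `"fixture"` (packaged parameters; requires a packaged
#'   compound) or `"qspr"` (descriptor-driven prediction).
#' @param partition_model,sc_model,de_model Registry keys for the QSPR path.
#' @param thickness Layer thicknesses (cm).
#' @return A [skin_state()].
#' @examples
#' oxy <- load_fixture_compound("oxycodone")
#' compound_skin_state(oxy)
#' @export
compound_skin_state <- function(compound, lesion = FALSE,
                                source = c("fixture", "qspr"),
                                partition_model = "calibrated",
                                sc_model = "potts_guy",
                                de_model = "kretsos",
                                thickness = skin_thickness_defaults()) {
  source <- match.arg(source)
  if (!inherits(compound, "compound_profile"))
    stop_user("compound must be a compound_profile")
  if (source == "fixture") {
    p <- load_fixture_skin_params(compound$name)
    layers <- renormalize_layer_permeabilities(
      raw_k = 1 / p$raw_resistance, compound$k_perm_total, thickness)
    parts <- partition_set(p$k_sc_water, p$k_de_water)
  } else {
    d_live <- predict_de_diffusivity(compound$mw, de_model)
    raw_k <- c(sc = predict_sc_permeability(compound$logP, compound$mw, sc_model),
               ve = d_live / thickness[["ve"]],
               de = d_live / thickness[["de"]])
    layers <- renormalize_layer_permeabilities(raw_k, compound$k_perm_total,
                                               thickness)
    parts <- partition_set(
      predict_partition_water(compound$logP, "SC", partition_model),
      predict_partition_water(compound$logP, "De", partition_model))
  }
  skin_state(layers, parts, lesion)
}

new_skin_concentrations <- function(c_dose, c_sc, c_ve, c_de, lesion) {
  structure(list(c_dose = c_dose, c_sc = c_sc, c_ve = c_ve, c_de = c_de,
                 lesion = lesion),
            class = "skin_concentrations")
}

#' @export
print.skin_concentrations <- function(x, ...) {
  cat("<skin_concentrations> [mg/cm3]",
      if (x$lesion) "(lesion)" else "(healthy)", "\n")
  cat(sprintf("  C_Dose %.4g | C_SC %s | C_VE %.4g | C_De %.4g\n",
              x$c_dose, if (is.na(x$c_sc)) "-" else sprintf("%.4g", x$c_sc),
              x$c_ve, x$c_de))
  invisible(x)
}

#' @export
as.data.frame.skin_concentrations <- function(x, ...) {
  layers <- c("sc", "ve", "de")
  conc <- c(x$c_sc, x$c_ve, x$c_de)
  keep <- !is.na(conc)
  data.frame(layer = layers[keep], conc_mg_per_cm3 = conc[keep],
             stringsAsFactors = FALSE)
}

#' Steady-state apical layer concentrations in healthy skin
#'
#' Evaluates the serial-barrier concentration relations at the apical
#' surface of each layer: the applied (vehicle) concentration partitions
#' into the stratum corneum scaled by the dermal bioavailability, and deeper
#' layers see the flux-driven concentration drop `1 - R_cum/R_total` chained
#' through the inter-layer partition coefficients.
#'
#' @param c_dose Drug concentration in the applied vehicle (mg/cm^3, >= 0).
#' @param state A healthy [skin_state()].
#' @param f_derm Dermal bioavailability fraction.
#' @return A `skin_concentrations` object (fields in mg/cm^3).
#' @export
healthy_skin_concentrations <- function(c_dose, state, f_derm) {
  if (!inherits(state, "skin_state")) stop_user("state must be a skin_state")
  if (state$lesion)
    stop_user("state is lesioned; use lesion_skin_concentrations()")
  if (!is.numeric(c_dose) || is.na(c_dose) || c_dose < 0)
    stop_user("c_dose must be non-negative")
  check_fraction(f_derm, "f_derm")
  r <- state$layers$resistance; r_tot <- state$layers$r_total
  p <- state$partitions
  c_sc <- c_dose * p$k_sc_water * p$k_vehicle_water * f_derm
  c_ve <- c_sc * (1 - r[["sc"]] / r_tot) * p$k_ve_sc
  c_de <- c_sc * (1 - (r[["sc"]] + r[["ve"]]) / r_tot) * p$k_ve_sc * p$k_de_ve
  new_skin_concentrations(c_dose, c_sc, c_ve, c_de, lesion = FALSE)
}

#' Steady-state apical layer concentrations in lesioned skin
#'
#' With the stratum corneum completely disrupted, the vehicle partitions
#' directly into the viable epidermis. The VE:vehicle coefficient is closed
#' through water as `K_VE:SC * K_SC:water` (water-like vehicle), and the
#' dermal bioavailability is kept at its healthy value.
#'
#' @inheritParams healthy_skin_concentrations
#' @param state A lesioned [skin_state()].
#' @return A `skin_concentrations` object; `c_sc` is `NA` (layer disrupted).
#' @export
lesion_skin_concentrations <- function(c_dose, state, f_derm) {
  if (!inherits(state, "skin_state")) stop_user("state must be a skin_state")
  if (!state$lesion)
    stop_user("state is healthy; use healthy_skin_concentrations()")
  if (!is.numeric(c_dose) || is.na(c_dose) || c_dose < 0)
    stop_user("c_dose must be non-negative")
  check_fraction(f_derm, "f_derm")
  r <- state$layers$resistance
  p <- state$partitions
  k_ve_vehicle <- p$k_ve_sc * p$k_sc_water * p$k_vehicle_water
  c_ve <- c_dose * k_ve_vehicle * f_derm
  c_de <- c_ve * (1 - r[["ve"]] / (r[["ve"]] + r[["de"]])) * p$k_de_ve
  new_skin_concentrations(c_dose, NA_real_, c_ve, c_de, lesion = TRUE)
}

#' Effective total skin permeability of a skin state
#'
#' Healthy skin: `1 / (R_SC + R_VE + R_De)`. Lesioned skin: the stratum
#' corneum resistance is dropped, `1 / (R_VE + R_De)`, which is always larger
#' -- dramatically so for compounds whose barrier is dominated by the
#' stratum corneum.
#'
#' @param state A [skin_state()].
#' @return Permeability coefficient (cm/h).
#' @export
effective_total_permeability <- function(state) {
  if (!inherits(state, "skin_state")) stop_user("state must be a skin_state")
  r <- state$layers$resistance
  if (state$lesion) 1 / (r[["ve"]] + r[["de"]]) else 1 / sum(r)
}
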