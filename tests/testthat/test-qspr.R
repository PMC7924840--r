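# QSPR layer-property prediction and the serial-resistor renormalization.

test_that("VE:SC partition chains through water as the published ratios", {
  expect_equal(round(partition_ve_sc(57.29, 5.29), 2), 10.83)
  expect_equal(round(partition_ve_sc(10.29, 3.73), 2), 2.76)
  for (x in c(0.01, 1, 57.3)) expect_equal(partition_ve_sc(x, x), 1)
  expect_error(partition_ve_sc(-1, 2), "positive")
  expect_error(partition_ve_sc(2, 0), "positive")
})

test_that("Potts-Guy stratum corneum permeability evaluates correctly", {
  # zero-descriptor baseline: 10^-6.3 cm/s x 3600
  expect_equal(predict_sc_permeability(0, 0), 1.804274e-3, tolerance = 1e-6)
  # frozen direct evaluation at the hydrophilic fixture's descriptors
  expect_equal(predict_sc_permeability(0.255, 315.36), 3.263296e-5,
               tolerance = 1e-6)
  # monotonicity in logP at fixed MW
  k <- vapply(seq(-2, 5, by = 0.5), predict_sc_permeability, numeric(1),
              mw = 300)
  expect_true(all(diff(k) > 0))
  expect_error(predict_sc_permeability(1, 300, model = "nope"), "unknown")
})

test_that("calibrated partition model reproduces the packaged layer table", {
  expect_equal(predict_partition_water(0.255, "SC"), 3.73, tolerance = 1e-9)
  expect_equal(predict_partition_water(0.255, "De"), 10.29, tolerance = 1e-9)
  expect_equal(predict_partition_water(4.98, "SC"), 5.29, tolerance = 1e-9)
  expect_equal(predict_partition_water(4.98, "De"), 57.29, tolerance = 1e-9)
  expect_error(predict_partition_water(1, "SC", model = "nope"), "unknown")
})

test_that("partition models increase with lipophilicity", {
  for (model in c("calibrated", "kow_power")) {
    for (layer in c("SC", "De")) {
      k <- vapply(seq(-1, 5, by = 0.5), predict_partition_water, numeric(1),
                  layer = layer, model = model)
      expect_true(all(diff(k) > 0), info = paste(model, layer))
    }
  }
})

test_that("layer sets satisfy the Fick / serial-resistor identities", {
  ls <- layer_set(k_perm = c(sc = 1e-4, ve = 0.5, de = 0.02))
  expect_equal(ls$k_perm, ls$diffusivity / ls$thickness)
  expect_equal(ls$resistance, 1 / ls$k_perm)
  expect_equal(ls$r_total, sum(ls$resistance))
  expect_equal(ls$k_total, 1 / ls$r_total)
  expect_error(layer_set(c(sc = -1, ve = 1, de = 1)), "positive")
})

test_that("renormalization hits the target total and preserves proportions", {
  # hydrophilic fixture: raw resistances renormalize onto R_total = 1/k
  raw_r <- c(sc = 9952.99, ve = 1.21, de = 45.49)
  ls <- renormalize_layer_permeabilities(1 / raw_r, 1.000e-4)
  expect_equal(ls$k_total, 1.000e-4, tolerance = 1e-12)
  expect_equal(ls$r_total, 10000, tolerance = 1e-12)
  expect_equal(ls$resistance / ls$r_total, raw_r / sum(raw_r),
               tolerance = 1e-12)
  # the renormalized layer values stay within table rounding of the raw ones
  expect_equal(unname(ls$resistance), unname(raw_r), tolerance = 5e-3)

  # lipophilic fixture: dermis carries ~60% of the resistance
  raw_b <- c(sc = 641.39, ve = 26.98, de = 1011.71)
  lb <- renormalize_layer_permeabilities(1 / raw_b, 5.93e-4)
  expect_equal(lb$r_total, 1 / 5.93e-4, tolerance = 1e-12)
  expect_equal(unname(lb$resistance[["de"]] / lb$r_total),
               1011.71 / sum(raw_b), tolerance = 1e-12)
  expect_equal(unname(lb$resistance[["de"]] / lb$r_total), 0.60,
               tolerance = 0.01)
  expect_error(renormalize_layer_permeabilities(1 / raw_b, -1), "positive")
})

test_that("renormalization is idempotent and conserves serial resistance", {
  set.seed(101)
  for (i in 1:25) {
    raw <- random_layer_k()
    target <- 10^stats::runif(1, -5, -1)
    ls <- renormalize_layer_permeabilities(raw, target)
    # serial-resistor conservation to machine precision
    expect_lt(abs(1 / ls$k_total - sum(1 / ls$k_perm)) * ls$k_total, 1e-12)
    expect_equal(ls$k_total, target, tolerance = 1e-12)
    # proportionality with the raw resistances
    expect_equal(ls$resistance / ls$r_total, (1 / raw) / sum(1 / raw),
                 tolerance = 1e-12)
    # renormalizing the output to its own total is the identity
    again <- renormalize_layer_permeabilities(ls$k_perm, ls$k_total)
    expect_equal(again$k_perm, ls$k_perm, tolerance = 1e-12)
  }
})

test_that("QSPR-constructed states share one living-layer diffusivity", {
  for (cmp in list(oxy, bup)) {
    st <- compound_skin_state(cmp, source = "qspr")
    # renormalization rescales resistances uniformly, so the equal raw
    # diffusivity of viable epidermis and dermis survives
    expect_equal(st$layers$diffusivity[["ve"]], st$layers$diffusivity[["de"]],
                 tolerance = 1e-12)
    expect_equal(st$layers$k_total, cmp$k_perm_total, tolerance = 1e-12)
  }
})
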