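# Reduced systemic disposition model: route handling, the transdermal depot
# law, mass balance, and closed-form linear-kinetics oracles.

auc_inf_from_sim <- function(profile, f_dose_mg, cl) {
  nca <- run_nca(profile)
  list(sim = nca$auc_0inf, oracle = f_dose_mg * 1000 / cl)  # ug*h/L
}

test_that("IV exposure matches the Dose/CL closed form", {
  p <- simulate_plasma(bup, load_fixture_regimen("buprenorphine_iv"))
  chk <- auc_inf_from_sim(p, 1.2, 85.5)  # 14.04 ug*h/L
  expect_equal(chk$sim, chk$oracle, tolerance = 0.005)

  p2 <- simulate_plasma(oxy, load_fixture_regimen("oxycodone_iv"))
  chk2 <- auc_inf_from_sim(p2, 6.75, 28.3)
  expect_equal(chk2$sim, chk2$oracle, tolerance = 0.005)
})

test_that("exposure is F x Dose / CL for every route (linear kinetics)", {
  # oral: bioavailable fraction only
  po <- simulate_plasma(oxy, load_fixture_regimen("oxycodone_oral"),
                        grid = seq(0, 96, length.out = 2000))
  chk <- auc_inf_from_sim(po, 0.735 * 15, 28.3)
  expect_equal(chk$sim, chk$oracle, tolerance = 0.01)

  # transdermal: the absorbed-eligible dose is what left the depot by patch
  # removal, dose * (1 - exp(-k_dep * wear))
  reg <- load_fixture_regimen("buprenorphine_td")
  ptd <- simulate_plasma(bup, reg, grid = seq(0, 400, length.out = 3000))
  k_dep <- bup$f_derm * bup$k_perm_total / 0.01
  absorbed <- reg$dose_mg * (1 - exp(-k_dep * reg$wear_duration_h))
  chk_td <- auc_inf_from_sim(ptd, absorbed, 85.5)
  expect_equal(chk_td$sim, chk_td$oracle, tolerance = 0.01)
})

test_that("plasma output is linear in dose", {
  reg1 <- load_fixture_regimen("buprenorphine_td")
  reg2 <- dose_regimen("TD", 2 * reg1$dose_mg, reg1$sim_duration_h,
                       reg1$surface_area_cm2, reg1$wear_duration_h)
  p1 <- simulate_plasma(bup, reg1)
  p2 <- simulate_plasma(bup, reg2)
  nz <- p1$values > max(p1$values) * 1e-6
  expect_equal(p2$values[nz] / p1$values[nz], rep(2, sum(nz)),
               tolerance = 1e-6)
})

test_that("zero dermal bioavailability yields no input and a full depot", {
  no_derm <- compound_profile("inert", bup$logP, bup$mw, bup$fu_plasma,
                              bup$bp_ratio, bup$clearance, bup$kp_tissue,
                              f_derm = 0, k_perm_total = bup$k_perm_total)
  p <- simulate_plasma(no_derm, load_fixture_regimen("buprenorphine_td"))
  expect_true(all(p$values == 0))
  bal <- attr(p, "balance")
  expect_true(all(bal$depot == 1.68))
})

test_that("mass is conserved on the whole grid for every route", {
  runs <- list(
    list(cmp = bup, reg = load_fixture_regimen("buprenorphine_iv")),
    list(cmp = oxy, reg = load_fixture_regimen("oxycodone_oral")),
    list(cmp = oxy, reg = load_fixture_regimen("oxycodone_td")),
    list(cmp = bup, reg = load_fixture_regimen("buprenorphine_td")))
  for (r in runs) {
    p <- simulate_plasma(r$cmp, r$reg)
    bal <- attr(p, "balance")
    total <- bal$depot + bal$gut + bal$central + bal$tissue + bal$eliminated
    initial <- total[1]
    expect_true(all(abs(total - initial) / initial < 1e-3),
                info = r$reg$route)
    # depot never grows; plasma never goes negative
    expect_true(all(diff(bal$depot) <= 1e-12))
    expect_true(all(p$values >= 0))
  }
})

test_that("solution is converged: halving tolerances barely moves Cmax", {
  reg <- load_fixture_regimen("buprenorphine_td")
  c1 <- max(simulate_plasma(bup, reg, rtol = 1e-8)$values)
  c2 <- max(simulate_plasma(bup, reg, rtol = 5e-9, atol = 5e-13)$values)
  expect_equal(c1, c2, tolerance = 1e-3)
})

test_that("route/parameter mismatches are rejected", {
  expect_error(simulate_plasma(bup, dose_regimen("ORAL", 10, 24)), "oral")
  expect_error(simulate_plasma(bup, load_fixture_regimen("buprenorphine_iv"),
                               grid = c(1, 2, 3)), "start at 0")
  expect_error(simulate_skin_layers(bup, load_fixture_regimen("buprenorphine_iv")),
               "TD")
  expect_error(lesion_fold_change(bup, load_fixture_regimen("buprenorphine_iv")),
               "TD")
})

test_that("skin-layer profiles start at steady state and deplete with the depot", {
  reg <- load_fixture_regimen("buprenorphine_td")
  skin <- compound_skin_state(bup)
  layers <- simulate_skin_layers(bup, reg, skin = skin)
  c_dose0 <- reg$dose_mg / (reg$surface_area_cm2 * 0.01)
  ss <- healthy_skin_concentrations(c_dose0, skin, bup$f_derm)
  expect_equal(layers$sc$values[1], ss$c_sc, tolerance = 1e-9)
  expect_equal(layers$ve$values[1], ss$c_ve, tolerance = 1e-9)
  expect_equal(layers$de$values[1], ss$c_de, tolerance = 1e-9)
  # profiles are proportional to the depleting depot, zero after removal
  expect_true(all(diff(layers$de$values) <= 1e-15))
  expect_true(all(layers$de$values[layers$de$times > reg$wear_duration_h] == 0))

  lesion_layers <- simulate_skin_layers(
    bup, reg, skin = compound_skin_state(bup, lesion = TRUE))
  expect_named(lesion_layers, c("ve", "de"))
})

test_that("lesion shortens the depot half-life by the permeability fold", {
  reg <- load_fixture_regimen("oxycodone_td")
  grid <- seq(0, 72, length.out = 500)
  healthy <- simulate_skin_layers(oxy, reg,
                                  skin = compound_skin_state(oxy), grid = grid)
  lesion <- simulate_skin_layers(
    oxy, reg, skin = compound_skin_state(oxy, lesion = TRUE), grid = grid)
  # layer profiles decay as exp(-k_dep t): recover the rate from two points
  rate <- function(prof) {
    (log(prof$values[1]) - log(prof$values[2])) / (prof$times[2] - prof$times[1])
  }
  k_fold <- effective_total_permeability(compound_skin_state(oxy, TRUE)) /
    effective_total_permeability(compound_skin_state(oxy))
  expect_equal(rate(lesion$de) / rate(healthy$de), k_fold, tolerance = 1e-6)
  expect_equal(k_fold, 214.1, tolerance = 1e-3)
})

test_that("lesion fold change is bounded by the input-rate fold and ordered", {
  reg <- load_fixture_regimen("buprenorphine_td")
  perm_fold <- effective_total_permeability(compound_skin_state(bup, TRUE)) /
    5.93e-4
  cmax_fold <- lesion_fold_change(bup, reg, "cmax")
  expect_lt(cmax_fold, perm_fold + 1e-9)  # linear-system bound
  expect_lt(cmax_fold, 2)
  expect_gt(cmax_fold, 1)
  auc_fold <- lesion_fold_change(bup, reg, "auc_0t")
  expect_lt(auc_fold, 2)
  expect_gt(auc_fold, 1)
  # the SC-limited hydrophilic compound is hit far harder by lesioning
  expect_gt(lesion_fold_change(oxy, load_fixture_regimen("oxycodone_td"),
                               "cmax"),
            cmax_fold)
})

test_that("identical skin states give a unit fold", {
  reg <- load_fixture_regimen("buprenorphine_td")
  skin <- compound_skin_state(bup)
  a <- simulate_plasma(bup, reg, skin = skin)
  b <- simulate_plasma(bup, reg, skin = skin)
  expect_equal(max(a$values) / max(b$values), 1, tolerance = 1e-12)
})
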