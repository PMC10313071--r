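test_that("solubility polynomial reproduces hand-evaluated values and monotonicity", {
  # hand evaluation of the dry-gas fit at 25 degC, S = 0 (spreadsheet check)
  k0 <- n2o_solubility_k0(solubility_context(temperature_c = 25), form = "dry")
  expect_equal(k0, 0.0247836, tolerance = 1e-4)

  # strictly decreasing in temperature (0-40 degC) and salinity (0-40)
  temps <- seq(0.5, 39.5, by = 0.5)
  for (form in c("dry", "moist")) {
    ks <- vapply(temps, function(tc)
      n2o_solubility_k0(solubility_context(tc, salinity = 2), form), numeric(1))
    expect_true(all(diff(ks) < 0))
    sals <- seq(0, 40, by = 2)
    ks_s <- vapply(sals, function(s)
      n2o_solubility_k0(solubility_context(25, salinity = s), form), numeric(1))
    expect_true(all(diff(ks_s) < 0))
  }

  expect_error(solubility_context(temperature_k = -1), "temperature")
  expect_warning(n2o_solubility_k0(solubility_context(45)), "fit range")
})

test_that("air-equilibrium concentration is linear in mole fraction and in-range for field temperatures", {
  ctx <- solubility_context(33.8, salinity = 2)
  expect_equal(
    equilibrium_concentration(solubility_context(33.8, salinity = 2,
                                                 atm_mole_fraction = 0)), 0)
  ctx2 <- solubility_context(33.8, salinity = 2,
                             atm_mole_fraction = 2 * ATM_N2O_MOLE_FRACTION)
  expect_equal(equilibrium_concentration(ctx2),
               2 * equilibrium_concentration(ctx))

  # every field temperature (31.3-36.7 degC, salinity 2, 331 ppb) yields an
  # equilibrium concentration in the ~6 nmol/L band the printed deltas imply
  for (tc in seq(31.3, 36.7, by = 0.3)) {
    ceq <- equilibrium_concentration(solubility_context(tc, salinity = 2))
    expect_gt(ceq, 5.5)
    expect_lt(ceq, 6.6)
  }
})

test_that("headspace back-calculation satisfies the mass balance and round-trips", {
  ctx <- solubility_context(temperature_k = 306.95, salinity = 2)
  # limiting cases: empty headspace; insoluble gas expels everything
  m0 <- headspace_measurement(0, 5, 7.5, ctx)
  expect_equal(headspace_to_dissolved(m0), 0)

  # mass-balance identity C_L V_L = C_G K0 R T V_L + C_G V_G, relative
  # error < 1e-12, across a grid of vial geometries and temperatures
  set.seed(42)
  for (i in 1:50) {
    tc <- runif(1, 5, 39)
    ctx_i <- solubility_context(tc, salinity = runif(1, 0, 35))
    vg <- runif(1, 1, 20); vl <- runif(1, 1, 20)
    cg <- runif(1, 1, 500)
    cl <- headspace_to_dissolved(headspace_measurement(cg, vg, vl, ctx_i))
    k0 <- n2o_solubility_k0(ctx_i, form = "dry")
    lhs <- cl * vl
    rhs <- cg * k0 * 0.0820574 * ctx_i$temperature_k * vl + cg * vg
    expect_equal(lhs, rhs, tolerance = 1e-12)
    # forward partition inverts the back-calculation exactly
    expect_equal(dissolved_to_headspace(cl, vg, vl, ctx_i), cg,
                 tolerance = 1e-12)
  }
  expect_error(headspace_measurement(10, 5, 0, ctx), "liquid volume")
})

test_that("delta and saturation satisfy their defining identities", {
  ctx <- solubility_context(33.8, salinity = 2)
  ceq <- equilibrium_concentration(ctx)

  # at equilibrium: delta 0, saturation 100 %
  at_eq <- delta_and_saturation(ceq, ctx)
  expect_equal(at_eq$delta_nmol_l, 0)
  expect_equal(at_eq$saturation_pct, 100)

  # supersaturation iff positive delta; direct-division saturation oracle
  res <- delta_and_saturation(235.59, ctx)
  expect_equal(res$delta_nmol_l, 235.59 - ceq)
  expect_equal(res$saturation_pct, 100 * 235.59 / ceq)
  expect_gt(res$saturation_pct, 100)
  expect_gt(res$saturation_pct, 3800)  # ~39x supersaturated
  under <- delta_and_saturation(ceq / 2, ctx)
  expect_lt(under$delta_nmol_l, 0)
  expect_lt(under$saturation_pct, 100)

  expect_error(delta_and_saturation(-1, ctx), ">= 0")
})

test_that("gas transfer presets obey their scaling identities", {
  ctx <- solubility_context(25, salinity = 2)
  # constant preset is a passthrough
  expect_equal(gas_transfer_velocity(model = "constant", k_m_d = 3.25), 3.25)
  expect_error(gas_transfer_velocity(model = "constant"), "k_m_d")

  # Sc = 600 normalization identity: k equals k600 exactly
  k600_cm_h <- 4.045 + 2.58 * 5
  tc600 <- uniroot(function(t) schmidt_number_n2o(t, 2) - 600,
                   c(20, 35))$root
  k <- gas_transfer_velocity(5, solubility_context(tc600, salinity = 2),
                             model = "borges2004")
  expect_equal(k, k600_cm_h * 24 / 100, tolerance = 1e-6)

  # exponent -0.5: halving Sc multiplies k by sqrt(2)
  sc <- schmidt_number_n2o(25, 2)
  tc_half <- uniroot(function(t) schmidt_number_n2o(t, 2) - sc / 2,
                     c(25, 40))$root
  k1 <- gas_transfer_velocity(5, ctx, model = "borges2004")
  k2 <- gas_transfer_velocity(5, solubility_context(tc_half, salinity = 2),
                              model = "borges2004")
  expect_equal(k2 / k1, sqrt(2), tolerance = 1e-6)
  expect_error(gas_transfer_velocity(5, ctx, model = "nosuch"))
})

test_that("air-water flux is bilinear with the nmol/L x m/d unit identity", {
  expect_equal(air_water_flux(0, 3.25), 0)
  expect_equal(air_water_flux(1, 1), 1)  # 1 nmol/L x 1 m/d = 1 umol/m2/d
  expect_equal(air_water_flux(229.62, 3.2534), 229.62 * 3.2534)
  expect_equal(air_water_flux(229.62, 3.2534), 747.03, tolerance = 1e-4)
  expect_equal(air_water_flux(100, 2 * 3), 2 * air_water_flux(100, 3))
  expect_equal(air_water_flux(2 * 100, 3), 2 * air_water_flux(100, 3))
  expect_error(air_water_flux(10, -1), ">= 0")
})

test_that("field-survey processing accepts both headspace and direct dissolved input", {
  survey <- data.frame(sample_id = c("A", "B"), temp_c = c(33.8, 33.1),
                       salinity = 2, dissolved_nmol_l = c(235.59, 123.65))
  out <- process_field_survey(survey, k_m_d = 3.25)
  expect_equal(nrow(out), 2)
  expect_equal(out$flux_umol_m2_d, out$delta_nmol_l * 3.25)

  ctx <- solubility_context(30, salinity = 2)
  cg <- dissolved_to_headspace(200, 5, 7.5, ctx)
  survey2 <- data.frame(sample_id = "C", temp_c = 30, salinity = 2,
                        headspace_conc_nmol_l = cg, gas_volume_ml = 5,
                        liquid_volume_ml = 7.5)
  out2 <- process_field_survey(survey2, k_m_d = 1)
  expect_equal(out2$dissolved_nmol_l, 200, tolerance = 1e-12)
})
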