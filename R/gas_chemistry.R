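# Dissolved-N2O chemistry: solubility, static-headspace back-calculation,
# saturation and air-water flux.

# Ideal gas constant, L atm mol^-1 K^-1
R_GAS_L_ATM <- 0.0820574

#' Default atmospheric N2O dry mole fraction (mol/mol)
#'
#' Contemporary tropospheric N2O mixing ratio, 331 ppb. Overridable in every
#' function that takes a solubility context; the real atmospheric value drifts
#' upward by roughly 0.25 % per year.
#' @export
ATM_N2O_MOLE_FRACTION <- 331e-9

# Weiss & Price (1980) N2O solubility coefficient sets, natural-log form,
# mol L^-1 atm^-1. "dry": K0, dissolved concentration per atm of dry-gas
# partial pressure (the Henry constant used in the headspace mass balance).
# "moist": F, dissolved concentration in equilibrium with water-vapor-saturated
# air at 1 atm total pressure per dry-air mole fraction (the right function for
# air-water equilibrium).
.WP_COEF <- list(
  dry = list(A = c(-62.7062, 97.3066, 24.1406),
             B = c(-0.058420, 0.033193, -0.0051313)),
  moist = list(A = c(-165.8806, 222.8743, 92.0792, -1.48425),
               B = c(-0.056235, 0.031619, -0.0048472))
)

#' Build a solubility context
#'
#' Bundles the state variables every solubility / equilibrium computation
#' needs: temperature, salinity, atmospheric N2O mole fraction and total
#' pressure.
#'
#' @param temperature_c water temperature in degrees Celsius. Exactly one of
#'   `temperature_c` / `temperature_k` must be given.
#' @param temperature_k thermodynamic temperature in kelvin.
#' @param salinity practical salinity (dimensionless), >= 0.
#' @param atm_mole_fraction atmospheric N2O dry mole fraction (mol/mol).
#' @param pressure_atm total pressure in atm.
#' @return an object of class `solubility_context`.
#' @examples
#' ctx <- solubility_context(temperature_c = 33.8, salinity = 2)
#' n2o_solubility_k0(ctx)
#' @export
solubility_context <- function(temperature_c = NULL, temperature_k = NULL,
                               salinity = 0,
                               atm_mole_fraction = ATM_N2O_MOLE_FRACTION,
                               pressure_atm = 1) {
  if (is.null(temperature_k)) {
    if (is.null(temperature_c)) {
      stop("supply temperature_c or temperature_k", call. = FALSE)
    }
    temperature_k <- temperature_c + 273.15
  }
  if (any(!is.finite(temperature_k)) || any(temperature_k <= 0)) {
    stop("temperature must be a positive, finite kelvin value", call. = FALSE)
  }
  if (any(salinity < 0)) stop("salinity must be >= 0", call. = FALSE)
  if (any(atm_mole_fraction < 0) || any(atm_mole_fraction >= 1)) {
    stop("atm_mole_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (any(pressure_atm <= 0)) stop("pressure_atm must be > 0", call. = FALSE)
  structure(list(temperature_k = temperature_k, salinity = salinity,
                 atm_mole_fraction = atm_mole_fraction,
                 pressure_atm = pressure_atm),
            class = "solubility_context")
}

#' N2O solubility from the Weiss-Price fit
#'
#' Evaluates ln K = A1 + A2(100/T) + A3 ln(T/100) [+ A4 (T/100)^2] +
#' S (B1 + B2 (T/100) + B3 (T/100)^2) with the mol L^-1 atm^-1 coefficient
#' sets of Weiss & Price (1980). The `dry` form is the Henry constant K0
#' against dry-gas partial pressure; the `moist` form is the equilibrium
#' solubility against water-vapor-saturated air at 1 atm total pressure.
#' Strictly decreasing in both temperature and salinity over the fit range.
#'
#' @param ctx a [solubility_context()].
#' @param form `"dry"` (Henry constant K0) or `"moist"` (moist-air
#'   equilibrium function).
#' @return solubility in mol L^-1 atm^-1.
#' @export
n2o_solubility_k0 <- function(ctx, form = c("dry", "moist")) {
  stopifnot(inherits(ctx, "solubility_context"))
  form <- match.arg(form)
  tk <- ctx$temperature_k
  tc <- tk - 273.15
  if (any(tc < 0) || any(tc > 40)) {
    warning("temperature outside the 0-40 degC fit range of the solubility polynomial",
            call. = FALSE)
  }
  co <- .WP_COEF[[form]]
  t100 <- tk / 100
  lnk <- co$A[1] + co$A[2] / t100 + co$A[3] * log(t100)
  if (length(co$A) == 4) lnk <- lnk + co$A[4] * t100^2
  lnk <- lnk + ctx$salinity * (co$B[1] + co$B[2] * t100 + co$B[3] * t100^2)
  exp(lnk)
}

#' Air-equilibrium dissolved N2O concentration
#'
#' Concentration of dissolved N2O in equilibrium with the atmosphere:
#' solubility times atmospheric mole fraction times total pressure. Uses the
#' moist-air solubility form by default, appropriate for surface water in
#' contact with water-vapor-saturated air.
#'
#' @inheritParams n2o_solubility_k0
#' @return equilibrium concentration C_N2Oeq in nmol L^-1.
#' @examples
#' equilibrium_concentration(solubility_context(33.8, salinity = 2))
#' @export
equilibrium_concentration <- function(ctx, form = c("moist", "dry")) {
  form <- match.arg(form)
  k <- n2o_solubility_k0(ctx, form = form)
  # mol/L -> nmol/L
  k * ctx$atm_mole_fraction * ctx$pressure_atm * 1e9
}

#' Headspace measurement record
#'
#' One vial's gas-phase reading after He replacement and equilibration:
#' headspace molar concentration, gas and liquid volumes, and the solubility
#' context at equilibration.
#'
#' @param headspace_conc_nmol_l gas-phase N2O concentration C_G (nmol L^-1).
#' @param gas_volume_ml headspace volume V_G (mL).
#' @param liquid_volume_ml liquid volume V_L (mL).
#' @param ctx [solubility_context()] at the equilibration temperature.
#' @return object of class `headspace_measurement`.
#' @export
headspace_measurement <- function(headspace_conc_nmol_l, gas_volume_ml,
                                  liquid_volume_ml, ctx) {
  stopifnot(inherits(ctx, "solubility_context"))
  if (any(gas_volume_ml <= 0)) stop("gas volume must be > 0", call. = FALSE)
  if (any(liquid_volume_ml <= 0)) stop("liquid volume must be > 0", call. = FALSE)
  if (any(headspace_conc_nmol_l < 0)) {
    stop("headspace concentration must be >= 0", call. = FALSE)
  }
  structure(list(headspace_conc_nmol_l = headspace_conc_nmol_l,
                 gas_volume_ml = gas_volume_ml,
                 liquid_volume_ml = liquid_volume_ml,
                 ctx = ctx),
            class = "headspace_measurement")
}

#' Back-calculate the original dissolved concentration from a headspace reading
#'
#' Static-headspace mass balance: all gas originally dissolved in the liquid is
#' partitioned at equilibrium between the liquid (via the Henry constant,
#' C_G K0 R T) and the headspace (C_G V_G / V_L per litre of liquid), so
#' C_L = C_G (K0 R T + V_G / V_L). Satisfies C_L V_L = C_G K0 R T V_L +
#' C_G V_G exactly.
#'
#' @param m a [headspace_measurement()].
#' @return original dissolved concentration C_L in nmol L^-1.
#' @export
headspace_to_dissolved <- function(m) {
  stopifnot(inherits(m, "headspace_measurement"))
  k0 <- n2o_solubility_k0(m$ctx, form = "dry")
  m$headspace_conc_nmol_l *
    (k0 * R_GAS_L_ATM * m$ctx$temperature_k +
       m$gas_volume_ml / m$liquid_volume_ml)
}

#' Forward partition of a known dissolved concentration into headspace
#'
#' Exact inverse of [headspace_to_dissolved()]: given the pre-equilibration
#' dissolved concentration, the headspace concentration after equilibration.
#' Used by the synthetic generator and by round-trip tests.
#'
#' @param c_l_nmol_l dissolved concentration before He replacement (nmol L^-1).
#' @inheritParams headspace_measurement
#' @return headspace concentration C_G in nmol L^-1.
#' @export
dissolved_to_headspace <- function(c_l_nmol_l, gas_volume_ml, liquid_volume_ml,
                                   ctx) {
  k0 <- n2o_solubility_k0(ctx, form = "dry")
  c_l_nmol_l / (k0 * R_GAS_L_ATM * ctx$temperature_k +
                  gas_volume_ml / liquid_volume_ml)
}

#' Excess dissolved N2O and saturation
#'
#' Delta-N2O is the dissolved concentration in excess of air equilibrium,
#' C_L - C_N2Oeq; saturation is 100 C_L / C_N2Oeq. Positive delta means the
#' water outgasses to the atmosphere.
#'
#' @param c_l_nmol_l dissolved concentration (nmol L^-1), >= 0.
#' @param ctx [solubility_context()].
#' @inheritParams equilibrium_concentration
#' @return data.frame with columns `dissolved_nmol_l`, `equilibrium_nmol_l`,
#'   `delta_nmol_l`, `saturation_pct`.
#' @export
delta_and_saturation <- function(c_l_nmol_l, ctx, form = c("moist", "dry")) {
  if (any(c_l_nmol_l < 0)) stop("dissolved concentration must be >= 0", call. = FALSE)
  form <- match.arg(form)
  ceq <- equilibrium_concentration(ctx, form = form)
  delta <- c_l_nmol_l - ceq
  sat <- ifelse(ceq > 0, 100 * c_l_nmol_l / ceq, NA_real_)
  if (any(ceq == 0 & c_l_nmol_l > 0)) {
    warning("equilibrium concentration is zero; saturation undefined", call. = FALSE)
  }
  data.frame(dissolved_nmol_l = c_l_nmol_l,
             equilibrium_nmol_l = ceq,
             delta_nmol_l = delta,
             saturation_pct = sat)
}

#' Gas transfer velocity presets
#'
#' Piston velocity K relating air-water flux to the concentration excess.
#' Wind-based presets compute k600 (cm h^-1) from wind speed at 10 m and
#' rescale to the N2O Schmidt number as k600 (Sc/600)^exponent:
#' \describe{
#'   \item{constant}{passthrough: returns `k_m_d` regardless of wind.}
#'   \item{borges2004}{estuarine fit k600 = 4.045 + 2.58 U10.}
#'   \item{wanninkhof1992}{quadratic k600 = 0.31 U10^2.}
#' }
#' The N2O Schmidt number uses the Wanninkhof (1992) cubic in temperature,
#' linearly interpolated in salinity between the freshwater and 35-salinity
#' fits.
#'
#' @param wind_speed_m_s wind speed at 10 m (m s^-1); required for wind-based
#'   presets.
#' @param ctx [solubility_context()] supplying temperature and salinity for
#'   the Schmidt number.
#' @param model preset name.
#' @param k_m_d constant piston velocity (m d^-1) for the `constant` preset.
#' @param sc_exponent Schmidt-number exponent (default -0.5, wavy unbroken
#'   surface).
#' @return K in m d^-1.
#' @examples
#' gas_transfer_velocity(model = "constant", k_m_d = 3.25)
#' @export
gas_transfer_velocity <- function(wind_speed_m_s = NULL, ctx = NULL,
                                  model = c("constant", "borges2004",
                                            "wanninkhof1992"),
                                  k_m_d = NULL, sc_exponent = -0.5) {
  model <- match.arg(model)
  if (model == "constant") {
    if (is.null(k_m_d)) stop("constant preset requires k_m_d", call. = FALSE)
    return(k_m_d)
  }
  if (is.null(wind_speed_m_s) || is.null(ctx)) {
    stop("wind-based presets require wind_speed_m_s and a solubility context",
         call. = FALSE)
  }
  if (any(wind_speed_m_s < 0)) stop("wind speed must be >= 0", call. = FALSE)
  k600_cm_h <- switch(model,
    borges2004 = 4.045 + 2.58 * wind_speed_m_s,
    wanninkhof1992 = 0.31 * wind_speed_m_s^2
  )
  sc <- schmidt_number_n2o(ctx$temperature_k - 273.15, ctx$salinity)
  k_cm_h <- k600_cm_h * (sc / 600)^sc_exponent
  k_cm_h * 24 / 100  # cm h^-1 -> m d^-1
}

#' Schmidt number of N2O in water
#'
#' Wanninkhof (1992) cubic fits Sc = A - B t + C t^2 - D t^3 (t in degC) for
#' freshwater and salinity-35 seawater, interpolated linearly in salinity.
#'
#' @param temperature_c temperature in degrees Celsius.
#' @param salinity practical salinity.
#' @return dimensionless Schmidt number.
#' @export
schmidt_number_n2o <- function(temperature_c, salinity = 0) {
  sc_fresh <- 2055.6 - 137.11 * temperature_c + 4.3173 * temperature_c^2 -
    0.054350 * temperature_c^3
  sc_sea <- 2301.1 - 151.1 * temperature_c + 4.7364 * temperature_c^2 -
    0.059431 * temperature_c^3
  w <- pmin(pmax(salinity / 35, 0), 1)
  (1 - w) * sc_fresh + w * sc_sea
}

#' Air-water N2O flux
#'
#' F = K * delta-N2O. With K in m d^-1 and delta in nmol L^-1 (= umol m^-3)
#' the product is already in umol m^-2 d^-1; no further conversion factor.
#'
#' @param delta_nmol_l concentration excess over air equilibrium (nmol L^-1).
#' @param k_m_d gas transfer velocity (m d^-1), >= 0.
#' @return flux in umol m^-2 d^-1; positive values are emission to the
#'   atmosphere.
#' @export
air_water_flux <- function(delta_nmol_l, k_m_d) {
  if (any(k_m_d < 0)) stop("transfer velocity must be >= 0", call. = FALSE)
  k_m_d * delta_nmol_l
}

#' Process a field-survey table into dissolved N2O, saturation and flux
#'
#' Column contract: `sample_id`, `temp_c`, `salinity`, and either
#' `headspace_conc_nmol_l` with `gas_volume_ml` + `liquid_volume_ml` (static
#' headspace back-calculation) or `dissolved_nmol_l` directly.
#'
#' @param survey data.frame of field samples.
#' @param k_m_d gas transfer velocity passed to [air_water_flux()].
#' @param atm_mole_fraction atmospheric N2O mole fraction.
#' @return data.frame with one row per sample: dissolved, equilibrium, delta,
#'   saturation and flux columns.
#' @export
process_field_survey <- function(survey, k_m_d,
                                 atm_mole_fraction = ATM_N2O_MOLE_FRACTION) {
  stopifnot(is.data.frame(survey),
            all(c("sample_id", "temp_c", "salinity") %in% names(survey)))
  out <- lapply(seq_len(nrow(survey)), function(i) {
    row <- survey[i, ]
    ctx <- solubility_context(temperature_c = row$temp_c,
                              salinity = row$salinity,
                              atm_mole_fraction = atm_mole_fraction)
    c_l <- if ("dissolved_nmol_l" %in% names(survey)) {
      row$dissolved_nmol_l
    } else {
      m <- headspace_measurement(row$headspace_conc_nmol_l, row$gas_volume_ml,
                                 row$liquid_volume_ml, ctx)
      headspace_to_dissolved(m)
    }
    res <- delta_and_saturation(c_l, ctx)
    cbind(data.frame(sample_id = row$sample_id), res,
          data.frame(flux_umol_m2_d = air_water_flux(res$delta_nmol_l, k_m_d)))
  })
  do.call(rbind, out)
}
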