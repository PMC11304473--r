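PARTICLE_DENSITY <- 2.65  # quartz-dominated mineral soil, g/cm^3

#' Total porosity from bulk density
#'
#' Standard relation `porosity = 1 - BD / 2.65`, with particle density fixed
#' at 2.65 g/cm^3.
#'
#' @param bd_g_cm3 Bulk density, g/cm^3, in (0, 2.65).
#' @return Porosity as a fraction.
#' @export
porosity <- function(bd_g_cm3) {
  if (any(is.na(bd_g_cm3)) || any(bd_g_cm3 <= 0 | bd_g_cm3 >= PARTICLE_DENSITY)) {
    abort("bulk density must lie in (0, 2.65) g/cm^3")
  }
  1 - bd_g_cm3 / PARTICLE_DENSITY
}

#' Bulk density at a given porosity (inverse of [porosity()])
#'
#' Algebraic rearrangement `BD = 2.65 * (1 - porosity)`; at zero porosity the
#' bulk density equals the 2.65 g/cm^3 particle density.
#'
#' @param porosity_frac Porosity fraction in \[0, 1).
#' @return Bulk density, g/cm^3.
#' @export
bd_from_porosity <- function(porosity_frac) {
  if (any(porosity_frac < 0 | porosity_frac >= 1)) {
    abort("porosity must lie in [0, 1)")
  }
  PARTICLE_DENSITY * (1 - porosity_frac)
}

#' Bulk density from organic carbon (Abdelbaki 2018 pedotransfer function)
#'
#' Estimates bulk density from organic carbon with the exponential PTF of
#' Abdelbaki (2018), `BD = 1.449 * exp(-0.03 * OC)` with OC in %; strictly
#' decreasing in OC. Outputs outside the physically plausible (0.8, 1.8)
#' g/cm^3 range are clamped with a warning.
#'
#' @param oc_pct Organic carbon, % by mass, > 0.
#' @return Bulk density, g/cm^3.
#' @references Abdelbaki, A.M. (2018). Evaluation of pedotransfer functions
#'   for predicting soil bulk density for U.S. soils. Ain Shams Engineering
#'   Journal 9(4), 1611-1619.
#' @export
bd_from_oc <- function(oc_pct) {
  if (any(is.na(oc_pct)) || any(oc_pct <= 0)) {
    abort("organic carbon must be positive")
  }
  bd <- 1.449 * exp(-0.03 * oc_pct)
  if (any(bd <= 0.8 | bd >= 1.8)) {
    warn("PTF bulk density outside (0.8, 1.8) g/cm^3; clamped")
    bd <- pmin(pmax(bd, 0.8 + 1e-6), 1.8 - 1e-6)
  }
  bd
}

#' Soil water retention and saturated conductivity (Saxton & Rawls 2006)
#'
#' Implements the Saxton & Rawls (2006) pedotransfer equations for volumetric
#' water content at wilting point (1500 kPa) and field capacity (33 kPa),
#' saturation, and saturated hydraulic conductivity. Texture enters as mass
#' fractions; organic matter is taken as 1.724 x organic carbon (Van Bemmelen
#' factor).
#'
#' @param sand_pct,clay_pct Sand and clay, % by mass (with silt closing the
#'   simplex to 100).
#' @param oc_pct Organic carbon, % by mass.
#' @return A tibble with `theta_wp`, `theta_fc`, `theta_s` (volumetric
#'   fractions) and `ksat_mm_hr`.
#' @references Saxton, K.E. & Rawls, W.J. (2006). Soil water characteristic
#'   estimates by texture and organic matter for hydrologic solutions.
#'   Soil Science Society of America Journal 70, 1569-1578.
#' @export
ksat_and_retention <- function(sand_pct, clay_pct, oc_pct) {
  if (any(sand_pct < 0 | clay_pct < 0 | sand_pct + clay_pct > 100)) {
    abort("texture outside the simplex: need sand, clay >= 0 and sand + clay <= 100")
  }
  S <- sand_pct / 100
  C <- clay_pct / 100
  OM <- 1.724 * oc_pct

  th1500t <- -0.024 * S + 0.487 * C + 0.006 * OM + 0.005 * S * OM -
    0.013 * C * OM + 0.068 * S * C + 0.031
  th1500 <- th1500t + (0.14 * th1500t - 0.02)

  th33t <- -0.251 * S + 0.195 * C + 0.011 * OM + 0.006 * S * OM -
    0.027 * C * OM + 0.452 * S * C + 0.299
  th33 <- th33t + (1.283 * th33t^2 - 0.374 * th33t - 0.015)

  ths33t <- 0.278 * S + 0.034 * C + 0.022 * OM - 0.018 * S * OM -
    0.027 * C * OM - 0.584 * S * C + 0.078
  ths33 <- ths33t + (0.636 * ths33t - 0.107)

  thS <- th33 + ths33 - 0.097 * S + 0.043

  B <- (log(1500) - log(33)) / (log(th33) - log(th1500))
  lambda <- 1 / B
  ksat <- 1930 * (thS - th33)^(3 - lambda)

  tibble::tibble(
    theta_wp = th1500, theta_fc = th33, theta_s = thS, ksat_mm_hr = ksat
  )
}

#' Water-filled pore space
#'
#' `WFPS% = 100 * theta / porosity`.
#'
#' @param theta Volumetric water content (fraction), with 0 < theta <
#'   porosity.
#' @param porosity_frac Total porosity (fraction).
#' @return WFPS in percent.
#' @export
wfps <- function(theta, porosity_frac) {
  if (any(theta <= 0)) abort("theta must be positive")
  if (any(theta >= porosity_frac)) {
    abort("theta must be below porosity")
  }
  100 * theta / porosity_frac
}

#' Derive model-ready soil hydraulic parameters for a soils table
#'
#' Fills missing bulk density from organic carbon (Abdelbaki 2018), derives
#' porosity from bulk density (particle density 2.65 g/cm^3), retention and
#' saturated conductivity from texture and organic carbon (Saxton & Rawls
#' 2006), and converts the retention water contents to water-filled pore
#' space. Measured bulk densities are never overwritten; the `bd_source`
#' column records the provenance of each value.
#'
#' @param soils A soils tibble (see [validate_soils()]).
#' @return A tibble with `field_id`, `bd_g_cm3`, `bd_source` (`"measured"` or
#'   `"ptf"`), `porosity_frac`, `ksat_mm_hr`, `wfps_fc_pct`, `wfps_wp_pct`.
#' @export
soil_ptf <- function(soils) {
  soils <- validate_soils(soils)
  measured <- !is.na(soils$bd_g_cm3)
  bd <- soils$bd_g_cm3
  if (any(!measured)) bd[!measured] <- bd_from_oc(soils$oc_pct[!measured])
  phi <- porosity(bd)
  sr <- ksat_and_retention(soils$sand_pct, soils$clay_pct, soils$oc_pct)
  # retention contents can exceed BD-derived porosity in dense clayey soils;
  # cap WFPS just below saturation rather than report > 100 %
  fc <- pmin(sr$theta_fc, phi * 0.999)
  wp <- pmin(sr$theta_wp, fc * 0.999)
  tibble::tibble(
    field_id = soils$field_id,
    bd_g_cm3 = bd,
    bd_source = ifelse(measured, "measured", "ptf"),
    porosity_frac = phi,
    ksat_mm_hr = sr$ksat_mm_hr,
    wfps_fc_pct = wfps(fc, phi),
    wfps_wp_pct = wfps(wp, phi)
  )
}
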