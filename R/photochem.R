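#' Photochemical constants
#'
#' Container for the rate constants behind the quantum-yield and
#' steady-state calculations. Defaults: the bimolecular rate constant of
#' furfuryl alcohol with singlet oxygen `k_rxn_ffa = 1.0e8` M^-1 s^-1 at
#' 25 C (halide enhancement would raise it; configurable), the
#' pseudo-first-order deactivation rate constant of singlet oxygen by
#' water `k_d_delta = 2.76e5` s^-1 (a ~3.6 microsecond lifetime), and the
#' p-nitroanisole/pyridine actinometer quantum-yield coefficients
#' `phi_PNA = 0.29 * [pyridine] + 0.00029`.
#'
#' @param k_rxn_ffa FFA + 1O2 rate constant, M^-1 s^-1.
#' @param k_d_delta 1O2 deactivation rate constant by water, s^-1.
#' @param phi_pna_slope,phi_pna_intercept Actinometer quantum-yield
#'   coefficients versus pyridine concentration (M^-1 and dimensionless).
#' @return A named list of class `photo_constants`.
#' @export
photo_constants <- function(k_rxn_ffa = 1.0e8, k_d_delta = 2.76e5,
                            phi_pna_slope = 0.29,
                            phi_pna_intercept = 0.00029) {
  for (nm in c("k_rxn_ffa", "k_d_delta", "phi_pna_slope",
               "phi_pna_intercept")) {
    stop_if_not_positive(get(nm), nm)
  }
  structure(list(k_rxn_ffa = k_rxn_ffa, k_d_delta = k_d_delta,
                 phi_pna_slope = phi_pna_slope,
                 phi_pna_intercept = phi_pna_intercept),
            class = "photo_constants")
}

#' Daily-average light field for the steady-state model
#'
#' Bundles the wavelength-gridded daily-average solar spectral photon
#' irradiance (290-550 nm) with the scalar correction factors of the
#' depth-averaged model: the non-clear-sky correction `cf` (0.60 for the
#' Adirondack region), the fraction of sunlight backscattered out of the
#' water column, the fraction of water-column absorbance attributable to
#' CDOM (scalar or per wavelength), the air-water surface reflection
#' loss, and the in-water path-length amplification for diffuse light.
#'
#' @param spectrum Tibble with `wavelength_nm` and `z_daily`
#'   (mol-photons cm^-2 s^-1 nm^-1) covering 290-550 nm.
#' @param cf Non-clear-sky correction factor.
#' @param f_backscatter Backscattered fraction, in \[0, 1\].
#' @param f_abs_cdom CDOM-absorbed fraction, scalar or one value per
#'   grid wavelength, in \[0, 1\].
#' @param surface_reflection Surface reflection loss fraction.
#' @param pathlength_factor Geometric path-length factor (>= 1).
#' @return A list of class `light_field`.
#' @export
light_field <- function(spectrum = gen_solar_spectrum(), cf = 0.60,
                        f_backscatter = 0.02, f_abs_cdom = 1.0,
                        surface_reflection = 0.066,
                        pathlength_factor = 1.2) {
  if (!all(c("wavelength_nm", "z_daily") %in% names(spectrum))) {
    abort_invalid("`spectrum` needs columns wavelength_nm and z_daily.")
  }
  if (min(spectrum$wavelength_nm) > 290 ||
      max(spectrum$wavelength_nm) < 550) {
    abort_invalid("`spectrum` must cover 290-550 nm.")
  }
  fracs <- c(f_backscatter, f_abs_cdom, surface_reflection)
  if (any(fracs < 0 | fracs > 1)) {
    abort_invalid("fractions must lie in [0, 1].")
  }
  if (!length(f_abs_cdom) %in% c(1L, nrow(spectrum))) {
    abort_invalid("`f_abs_cdom` must be scalar or one value per wavelength.")
  }
  if (pathlength_factor < 1) {
    abort_invalid("`pathlength_factor` must be >= 1.")
  }
  structure(list(spectrum = as_tibble(spectrum), cf = cf,
                 f_backscatter = f_backscatter, f_abs_cdom = f_abs_cdom,
                 surface_reflection = surface_reflection,
                 pathlength_factor = pathlength_factor),
            class = "light_field")
}

#' First-order decay rate from a kinetics trace
#'
#' Ordinary least squares of ln(concentration) on time; the observed
#' rate constant is the negated slope.
#'
#' @param trace Tibble with `time_s` and `conc_M` (> 0), >= 4 points.
#' @return One-row tibble: `k_obs` (s^-1), `se`, `n`.
#' @export
fit_first_order <- function(trace) {
  if (nrow(trace) < 4L) abort_invalid("need >= 4 kinetic points.")
  if (any(trace$conc_M <= 0)) {
    abort_invalid("all concentrations must be > 0.")
  }
  fit <- lm(log(conc_M) ~ time_s, data = trace)
  # noise-free traces fit perfectly; the summary warning is expected
  se <- suppressWarnings(
    summary(fit)$coefficients["time_s", "Std. Error"])
  tibble(k_obs = -unname(coef(fit)[2]), se = se, n = nrow(trace))
}

# Synthetic single-band PNA molar absorptivity (M^-1 cm^-1): Gaussian in
# wavelength, peak 314 nm, width 22 nm, eps_max 1.0e4. A stand-in curve
# used consistently by the kinetics generator and the actinometry
# inversion; round-trip calibration does not depend on its exact shape.
pna_epsilon <- function(lambda_nm) {
  1.0e4 * exp(-(lambda_nm - 314)^2 / (2 * 22^2))
}

# Specific light-absorption rate of dilute PNA under a light field
# (s^-1 per unit quantum yield): sum over the grid of
# ln(10) * eps * Z * 1000.
pna_absorption_rate <- function(field) {
  sp <- field$spectrum
  trapz(sp$wavelength_nm,
        log(10) * pna_epsilon(sp$wavelength_nm) * sp$z_daily * 1000)
}

#' Lamp intensity scale from a PNA/pyridine actinometer trace
#'
#' The actinometer quantum yield is `phi_PNA = slope * [pyridine] +
#' intercept`; the recovered scale is the ratio of the observed PNA decay
#' rate to the decay rate the reference light field would produce at that
#' quantum yield. Multiplying the reference spectrum by the scale gives
#' the calibrated in-vial spectrum.
#'
#' @param pna_trace Kinetics tibble (see [gen_kinetics()]).
#' @param pyridine_M Pyridine concentration, M, > 0.
#' @param field Reference [light_field()].
#' @param constants A [photo_constants()] list.
#' @return Dimensionless scale factor.
#' @export
actinometry_scale <- function(pna_trace, pyridine_M,
                              field = light_field(),
                              constants = photo_constants()) {
  stop_if_not_positive(pyridine_M, "pyridine_M")
  phi_pna <- constants$phi_pna_slope * pyridine_M +
    constants$phi_pna_intercept
  if (phi_pna <= 0) {
    abort("actinometer quantum yield is not positive",
          class = "lakephoto_invalid_configuration")
  }
  k_obs <- fit_first_order(pna_trace)$k_obs
  k_obs / (phi_pna * pna_absorption_rate(field))
}

#' In-vial rate of light absorption by a sample
#'
#' Trapezoidal sum over 290-550 nm of the (calibrated) spectral photon
#' irradiance times the fraction of light absorbed over the vial path,
#' converted to a volumetric photon absorption rate (M s^-1, i.e.
#' mol-photons L^-1 s^-1).
#'
#' @param spec Sample [absorbance_spectrum()] (must cover 290-550 nm).
#' @param field [light_field()] whose spectrum is used as-is (apply the
#'   actinometry scale via `scale`).
#' @param pathlength_cm In-vial optical path, cm.
#' @param scale Lamp intensity scale from [actinometry_scale()].
#' @return Rate of light absorption, M s^-1.
#' @export
rate_light_absorption <- function(spec, field = light_field(),
                                  pathlength_cm = 1.1, scale = 1) {
  stop_if_not_positive(pathlength_cm, "pathlength_cm")
  sp <- field$spectrum
  if (min(spec$wavelength_nm) > min(sp$wavelength_nm) ||
      max(spec$wavelength_nm) < max(sp$wavelength_nm)) {
    abort_invalid("sample spectrum does not cover the irradiance grid.")
  }
  a_cm <- napierian_at(spec, sp$wavelength_nm) / 100
  frac <- 1 - exp(-a_cm * pathlength_cm)
  trapz(sp$wavelength_nm,
        scale * sp$z_daily * frac / pathlength_cm * 1000)
}

#' Apparent singlet-oxygen quantum yield from FFA probe kinetics
#'
#' The in-vial steady-state singlet-oxygen concentration is
#' `k_obs / k_rxn_ffa`; the apparent quantum yield is that concentration
#' times the water deactivation rate constant divided by the rate of
#' light absorption: `phi = [1O2]ss * k_d_delta / Ra`.
#'
#' @param k_obs_ffa Observed FFA decay rate, s^-1 (>= 0).
#' @param ra Rate of light absorption, M s^-1, > 0.
#' @param constants A [photo_constants()] list.
#' @param phi_srnom Optional quantum yield of a Suwannee River NOM
#'   reference measured in parallel, for normalisation.
#' @return One-row tibble: `phi_app`, `one_o2_ss_exp` (M), `ra`,
#'   `phi_ratio_srnom`.
#' @export
apparent_quantum_yield <- function(k_obs_ffa, ra,
                                   constants = photo_constants(),
                                   phi_srnom = NULL) {
  stop_if_not_positive(ra, "ra")
  if (k_obs_ffa < 0) abort_invalid("`k_obs_ffa` must be >= 0.")
  ss <- k_obs_ffa / constants$k_rxn_ffa
  phi <- ss * constants$k_d_delta / ra
  if (phi <= 0 || phi >= 1) {
    warn(sprintf("apparent quantum yield %.3g outside (0, 1); suspect result",
                 phi),
         class = "lakephoto_suspect_result")
  }
  tibble(phi_app = phi, one_o2_ss_exp = ss, ra = ra,
         phi_ratio_srnom = if (is.null(phi_srnom)) NA_real_ else
           phi / phi_srnom)
}

#' Euphotic-zone depth from DOC
#'
#' Empirical Adirondack relationship
#' `z = 4.6 / (0.15 * DOC^1.08) * 100` (cm); strictly decreasing in DOC.
#'
#' @param doc DOC, mg C/L, > 0.
#' @return Depth, cm.
#' @export
euphotic_depth <- function(doc) {
  if (any(doc <= 0)) abort_invalid("`doc` must be > 0.")
  4.6 / (0.15 * doc^1.08) * 100
}

#' Diffuse attenuation coefficient from DOC
#'
#' Empirical UV-based relationship
#' `Kd = exp(-0.01347 * lambda + 5.36 * DOC^0.157)`. The formula output
#' is read in the units named by `formula_units` and always returned in
#' cm^-1 for use in the depth-averaged model. The default reads it as
#' m^-1: taken as cm^-1 the formula would confine light to millimetres,
#' which is inconsistent with the metre-scale euphotic depths the DOC
#' relationship itself produces.
#'
#' @param doc DOC, mg C/L, > 0.
#' @param lambda_nm Wavelength(s) in \[290, 550\] nm.
#' @param formula_units `"m"` (default) or `"cm"`: units the raw formula
#'   value is interpreted in before conversion to cm^-1.
#' @return Attenuation coefficient(s), cm^-1.
#' @export
kd_lambda <- function(doc, lambda_nm, formula_units = c("m", "cm")) {
  formula_units <- match.arg(formula_units)
  if (any(doc <= 0)) abort_invalid("`doc` must be > 0.")
  if (any(lambda_nm < 290 | lambda_nm > 550)) {
    abort_invalid("`lambda_nm` must lie in [290, 550].")
  }
  value <- exp(-0.01347 * lambda_nm + 5.36 * doc^0.157)
  if (formula_units == "m") value / 100 else value
}

#' Optical sub-model of one lake
#'
#' Euphotic depth and the wavelength-gridded diffuse attenuation
#' coefficient, both driven by DOC.
#'
#' @inheritParams kd_lambda
#' @param wavelengths Grid, nm (1 nm, 290-550 by default).
#' @return List of class `lake_optical_model`: `doc`, `z_euphotic_cm`,
#'   `kd` tibble (`wavelength_nm`, `kd_cm`).
#' @export
lake_optical_model <- function(doc, wavelengths = 290:550,
                               formula_units = c("m", "cm")) {
  stop_if_not_positive(doc, "doc")
  formula_units <- match.arg(formula_units)
  structure(list(
    doc = doc,
    z_euphotic_cm = euphotic_depth(doc),
    kd = tibble(wavelength_nm = as.numeric(wavelengths),
                kd_cm = kd_lambda(doc, wavelengths, formula_units))),
    class = "lake_optical_model")
}

#' Depth-averaged steady-state singlet-oxygen concentration
#'
#' Implements the daily-average steady-state model term for term:
#' `[1O2]ss = phi / k_d_delta * CF * sum_lambda( Z / z * (1 - exp(-Kd z))
#' * (1 - f_backscatter) * f_abs_CDOM )`, with surface-reflection and
#' path-length adjustments applied to the irradiance, on a 1 nm grid
#' over 290-550 nm (trapezoidal integration). The near-surface variant
#' replaces the depth-average absorption factor `(1 - exp(-Kd z)) / z`
#' by its surface limit `Kd`; an epilimnion variant (identical formula,
#' user-supplied depth) is computed only when `epilimnion_depth_cm` is
#' given.
#'
#' @param phi Apparent quantum yield (number, or an
#'   [apparent_quantum_yield()] row whose `phi_app` is used).
#' @param field A [light_field()].
#' @param lake A [lake_optical_model()].
#' @param constants A [photo_constants()] list.
#' @param epilimnion_depth_cm Optional epilimnion depth, cm.
#' @return One-row tibble: `c_euphotic`, `c_near_surface`,
#'   `c_epilimnion` (M; NA when no depth is supplied), `ra_vol`
#'   (mol-photons L^-1 s^-1 absorbed in the euphotic zone),
#'   `z_euphotic_cm`, `doc`.
#' @export
steady_state_1o2 <- function(phi, field, lake,
                             constants = photo_constants(),
                             epilimnion_depth_cm = NULL) {
  if (is.data.frame(phi)) phi <- phi$phi_app
  stop_if_not_scalar_number(phi, "phi")
  if (phi < 0) abort_invalid("`phi` must be >= 0.")
  sp <- field$spectrum
  grid <- sp$wavelength_nm
  if (!isTRUE(all.equal(grid, lake$kd$wavelength_nm))) {
    abort_invalid("light-field and lake Kd grids differ.")
  }
  z <- lake$z_euphotic_cm
  if (z <= 0) abort_invalid("euphotic depth must be > 0.")
  kd <- lake$kd$kd_cm

  z_eff <- sp$z_daily * (1 - field$surface_reflection) *
    field$pathlength_factor
  weight <- (1 - field$f_backscatter) * field$f_abs_cdom

  depth_avg <- function(zz) {
    trapz(grid, z_eff * (1 - exp(-kd * zz)) / zz * weight) * 1000
  }
  sum_ns <- trapz(grid, z_eff * kd * weight) * 1000

  ra_vol <- field$cf * depth_avg(z)
  pref <- phi / constants$k_d_delta
  tibble(
    c_euphotic = pref * ra_vol,
    c_near_surface = pref * field$cf * sum_ns,
    c_epilimnion = if (is.null(epilimnion_depth_cm)) NA_real_ else
      pref * field$cf * depth_avg(epilimnion_depth_cm),
    ra_vol = ra_vol,
    z_euphotic_cm = z,
    doc = lake$doc
  )
}

#' Contaminant half-life due to reaction with singlet oxygen
#'
#' `t_1/2 = ln 2 / (k_rxn * [1O2]ss)`, converted from seconds to months
#' using a 30.44-day month.
#'
#' @param k_rxn Bimolecular rate constant, M^-1 s^-1, > 0.
#' @param c Steady-state singlet-oxygen concentration, M, > 0.
#' @param seconds_per_month Unit conversion (default 30.44 days).
#' @return Half-life, months.
#' @export
half_life <- function(k_rxn, c, seconds_per_month = SECONDS_PER_MONTH) {
  if (any(k_rxn <= 0) || any(c <= 0)) {
    abort_invalid("`k_rxn` and `c` must be > 0.")
  }
  log(2) / (k_rxn * c) / seconds_per_month
}

#' Screen compounds against lake flushing
#'
#' Compares each compound's singlet-oxygen reaction half-life in the
#' euphotic zone with the lake's hydraulic residence time:
#' `log10_ratio = log10(t_1/2 / tau)`. Classes: below 0 the reaction
#' outpaces flushing (`faster_than_flushing`), 0 to 1 `comparable`,
#' above 1 `slower`; the boundaries 0 and 1 fall to the slower class.
#'
#' @param compounds Tibble with `name` and `k_rxn` (M^-1 s^-1).
#' @param c Steady-state singlet-oxygen concentration, M.
#' @param tau_years Hydraulic residence time, years, > 0.
#' @return Tibble: `name`, `k_rxn`, `t_half_months`, `log10_ratio`,
#'   `fate_class`.
#' @export
screen_compounds <- function(compounds, c, tau_years) {
  stop_if_not_positive(tau_years, "tau_years")
  if (nrow(compounds) == 0) {
    return(tibble(name = character(), k_rxn = numeric(),
                  t_half_months = numeric(), log10_ratio = numeric(),
                  fate_class = character()))
  }
  t_half <- half_life(compounds$k_rxn, c)
  ratio <- log10(t_half / (tau_years * 12))
  tibble(
    name = compounds$name, k_rxn = compounds$k_rxn,
    t_half_months = t_half, log10_ratio = ratio,
    fate_class = dplyr::case_when(
      ratio < 0 ~ "faster_than_flushing",
      ratio < 1 ~ "comparable",
      TRUE ~ "slower"
    )
  )
}
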