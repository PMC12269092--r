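#' CDOM absorbance spectra and optical metrics
#'
#' An absorbance spectrum is a tibble with columns `wavelength_nm`
#' (strictly increasing) and `a_m` (Napierian absorption coefficient,
#' m^-1, non-negative). All optics functions take and return this layout;
#' the Napierian convention is used internally everywhere, with the
#' decadic convention appearing only at the SUVA254 boundary.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm), strictly
#'   increasing.
#' @param a_m Napierian absorption coefficients (m^-1), same length.
#' @return A tibble with columns `wavelength_nm` and `a_m`.
#' @examples
#' spec <- absorbance_spectrum(250:600, 2 * exp(-0.018 * (250:600 - 440)))
#' e2e3(spec)
#' @export
absorbance_spectrum <- function(wavelength_nm, a_m) {
  if (length(wavelength_nm) != length(a_m)) {
    abort_invalid("`wavelength_nm` and `a_m` must have the same length.")
  }
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0)) {
    abort_invalid("`wavelength_nm` must be strictly increasing with >= 2 points.")
  }
  if (any(!is.finite(a_m)) || any(a_m < 0)) {
    abort_invalid("`a_m` must be finite and >= 0.")
  }
  tibble(wavelength_nm = as.numeric(wavelength_nm), a_m = as.numeric(a_m))
}

#' Interpolate a Napierian absorption coefficient at a wavelength
#'
#' Linear interpolation between bracketing grid points; exact on grid
#' points.
#'
#' @param spec An absorbance spectrum (see [absorbance_spectrum()]).
#' @param lambda_nm Wavelength(s) in nm, inside the spectrum's range.
#' @return Absorption coefficient(s), m^-1.
#' @export
napierian_at <- function(spec, lambda_nm) {
  rng <- range(spec$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2])) {
    abort(sprintf("wavelength outside spectrum range [%g, %g] nm",
                  rng[1], rng[2]),
          class = "lakephoto_out_of_range")
  }
  stats::approx(spec$wavelength_nm, spec$a_m, xout = lambda_nm,
                method = "linear", ties = "ordered")$y
}

#' E2:E3 ratio
#'
#' Ratio of Napierian absorption coefficients at 250 and 365 nm, a proxy
#' inversely related to DOM molecular size and charge-transfer character.
#'
#' @inheritParams napierian_at
#' @return Dimensionless ratio a(250)/a(365).
#' @export
e2e3 <- function(spec) {
  a250 <- napierian_at(spec, 250)
  a365 <- napierian_at(spec, 365)
  if (a365 == 0) {
    abort("a(365 nm) is zero; E2:E3 undefined.",
          class = "lakephoto_undefined_metric")
  }
  a250 / a365
}

#' Specific UV absorbance at 254 nm
#'
#' Decadic absorbance per metre at 254 nm normalised to DOC:
#' (a(254)/ln 10) / DOC, in L mg-C^-1 m^-1. A DOM aromaticity proxy.
#'
#' @inheritParams napierian_at
#' @param doc Dissolved organic carbon, mg C/L, > 0.
#' @export
suva254 <- function(spec, doc) {
  stop_if_not_positive(doc, "doc")
  napierian_at(spec, 254) / log(10) / doc
}

#' Fit a CDOM spectral slope
#'
#' Ordinary least squares of ln a(lambda) on lambda over a wavelength
#' window; the slope is returned with positive sign for spectra that decay
#' with wavelength (the CDOM convention, nm^-1).
#'
#' @inheritParams napierian_at
#' @param lambda_lo,lambda_hi Window bounds, nm.
#' @return Spectral slope S (nm^-1).
#' @export
fit_spectral_slope <- function(spec, lambda_lo, lambda_hi) {
  keep <- spec$wavelength_nm >= lambda_lo & spec$wavelength_nm <= lambda_hi &
    spec$a_m > 0
  if (sum(keep) < 10L) {
    abort("need >= 10 grid points with a > 0 in the fitting window",
          class = "lakephoto_fit_failure")
  }
  fit <- lm(log(a_m) ~ wavelength_nm, data = spec[keep, ])
  -unname(coef(fit)[2])
}

#' Optical metric summary for one spectrum
#'
#' @inheritParams suva254
#' @param fi,hix,beta_alpha Optional fluorescence indices carried through
#'   as-is (not computed from spectra).
#' @return One-row tibble of a440, SUVA254, E2:E3 and the two standard
#'   spectral slopes.
#' @export
optical_metrics <- function(spec, doc, fi = NA_real_, hix = NA_real_,
                            beta_alpha = NA_real_) {
  tibble(
    a440 = napierian_at(spec, 440),
    suva254 = suva254(spec, doc),
    e2e3 = e2e3(spec),
    s290_400 = fit_spectral_slope(spec, 290, 400),
    s300_600 = fit_spectral_slope(spec, 300, 600),
    fi = fi, hix = hix, beta_alpha = beta_alpha
  )
}

#' Read / write the two-column absorbance CSV dialect
#'
#' @param path CSV path with header columns `wavelength_nm`, `a_m`.
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  absorbance_spectrum(df$wavelength_nm, df$a_m)
}

#' @rdname read_spectrum_csv
#' @param spec Spectrum to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  readr::write_csv(spec, path)
  invisible(path)
}
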