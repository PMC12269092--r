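#' Synthetic lake set
#'
#' Generates a set of lake specifications with the statistical structure
#' the rest of the pipeline assumes: drainage lakes dominate (as in the
#' Adirondack long-term monitoring pool, where seepage lakes are rare),
#' seepage lakes carry high dissolved iron and low singlet-oxygen quantum
#' yields (iron quenching of excited DOM states), and browning trends are
#' mostly positive with a median DOC slope near 0.057 mg C/L-yr.
#'
#' @param n Number of lakes (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param hydro_class Optional character vector (length 1 or `n`) forcing
#'   hydrologic classes instead of sampling them.
#' @return Tibble with one row per lake: `lake_id`, `hydro_class`,
#'   `till_class`, `tau_years`, `doc_baseline`, `doc_trend`,
#'   `color_per_doc`, `suva_trend`, `phi_true`, `fe_um`.
#' @examples
#' gen_lakes(5, seed = 1)
#' @export
gen_lakes <- function(n, seed, hydro_class = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort_invalid("`n` must be >= 1.")
  }
  n <- as.integer(n)
  classes <- c("headwater_drainage", "chain_drainage", "mounded_seepage")
  if (!is.null(hydro_class)) {
    hydro_class <- rep_len(match.arg(hydro_class, classes, several.ok = TRUE),
                           n)
  }
  withr::with_seed(sub_seed(seed, 1L), {
    if (is.null(hydro_class)) {
      hydro_class <- sample(classes, n, replace = TRUE,
                            prob = c(0.50, 0.445, 0.055))
    }
    seepage <- hydro_class == "mounded_seepage"
    phi <- ifelse(seepage,
                  pmin(pmax(rnorm(n, 0.0075, 0.001), 0.004), 0.012),
                  pmin(pmax(rnorm(n, 0.022, 0.005), 0.008), 0.04))
    fe <- ifelse(seepage,
                 pmax(rnorm(n, 15.6, 1.0), 10),
                 pmin(stats::rlnorm(n, log(1.9), 0.8), 13.1))
    tibble(
      lake_id = sprintf("L%02d", seq_len(n)),
      hydro_class = hydro_class,
      till_class = sample(c("thin", "medium", "thick", "none"), n,
                          replace = TRUE, prob = c(0.40, 0.30, 0.25, 0.05)),
      tau_years = stats::rlnorm(n, log(0.8), 0.9),
      doc_baseline = pmin(pmax(stats::rlnorm(n, log(4.5), 0.45), 1.5), 14),
      doc_trend = ifelse(runif(n) < 0.1, rnorm(n, 0, 0.003),
                         pmax(rnorm(n, 0.057, 0.025), 0.005)),
      color_per_doc = 1 / rnorm(n, 0.095, 0.01),
      suva_trend = rnorm(n, -0.02, 0.012),
      phi_true = phi,
      fe_um = fe
    )
  })
}

ar1_noise <- function(n, phi, sd_stationary) {
  if (sd_stationary == 0) return(numeric(n))
  innov_sd <- sd_stationary * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_stationary)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + rnorm(1, 0, innov_sd)
  x
}

#' Synthetic monthly water-chemistry record for one lake
#'
#' DOC is a linear trend plus one annual harmonic plus AR(1) noise,
#' floored at a small positive value; colour tracks DOC through the
#' lake's colour-to-DOC ratio, SUVA254 follows its own (usually negative)
#' trend, pH rises slowly and the summed sulfate + nitrate concentration
#' declines (recovery from acidification). Colour collection can stop
#' early and SUVA254 can start late, mirroring real monitoring records.
#'
#' @param lake One row of [gen_lakes()] output (or an equivalent list).
#' @param start Start date (`Date` or "YYYY-MM-DD").
#' @param months Record length in months (>= 24: the trend stage needs at
#'   least two seasonal cycles).
#' @param seed Integer seed.
#' @param noise_sd Stationary standard deviation of the AR(1) DOC noise,
#'   mg C/L.
#' @param ar_phi AR(1) coefficient of the noise.
#' @param seasonal_amp Amplitude of the annual DOC harmonic, mg C/L.
#' @param missing_frac Fraction of values masked missing completely at
#'   random (exercises gap handling downstream).
#' @param color_through,suva_from Fractions of the record over which
#'   colour is collected (from the start) and SUVA254 is collected (to
#'   the end).
#' @return Tibble: `lake_id`, `date`, `doc`, `color`, `suva254`, `ph`,
#'   `so4_no3`.
#' @export
gen_chemistry <- function(lake, start = "1992-06-01", months = 360, seed = 1,
                          noise_sd = 0.2, ar_phi = 0.5, seasonal_amp = 0.3,
                          missing_frac = 0.05, color_through = 0.8,
                          suva_from = 0.65) {
  if (!is.numeric(months) || months < 24) {
    abort_invalid("`months` must be >= 24 (two seasonal cycles).")
  }
  months <- as.integer(months)
  t_mon <- seq_len(months) - 1L
  dates <- seq(as.Date(start), by = "month", length.out = months)
  yrs <- t_mon / 12
  withr::with_seed(sub_seed(seed, 2L), {
    doc <- lake$doc_baseline + lake$doc_trend * yrs +
      seasonal_amp * sin(2 * pi * t_mon / 12) +
      ar1_noise(months, ar_phi, noise_sd)
    doc <- pmax(doc, 0.05)
    color <- lake$color_per_doc * doc +
      ar1_noise(months, ar_phi, noise_sd * lake$color_per_doc / 2)
    color <- pmax(color, 0)
    suva <- 3 + lake$suva_trend * yrs + ar1_noise(months, ar_phi, noise_sd / 4)
    suva <- pmax(suva, 0.1)
    ph <- 6 + 0.012 * yrs + ar1_noise(months, ar_phi, 0.08)
    so4 <- pmax(110 - 1.6 * yrs + ar1_noise(months, ar_phi, 4), 5)

    color[t_mon / months > color_through] <- NA_real_
    suva[t_mon / months < suva_from] <- NA_real_
    out <- tibble(lake_id = lake$lake_id, date = dates, doc = doc,
                  color = color, suva254 = suva, ph = ph, so4_no3 = so4)
    if (missing_frac > 0) {
      for (col in c("doc", "color", "suva254", "ph", "so4_no3")) {
        mask <- runif(months) < missing_frac
        out[[col]][mask] <- NA_real_
      }
    }
    out
  })
}

#' Synthetic regional driver series with planted coherence
#'
#' Builds each driver from the Fourier band-limited component of the DOC
#' series, phase-rotated by the requested offset, mixed with independent
#' white noise so that the planted wavelet coherence in the named band
#' approaches the requested magnitude (exact at magnitude 1 and 0). Under
#' the package's phase convention (see [wavelet_coherence()]) the
#' recovered mean phase of the (DOC, driver) pair equals the requested
#' `phase`.
#'
#' @param chem A [gen_chemistry()] record (DOC gaps are linearly
#'   interpolated before filtering).
#' @param couplings Tibble with columns `driver`, `band_lo`, `band_hi`
#'   (months), `magnitude` in \[0, 1\] and `phase` in \[-pi, pi\].
#' @param seed Integer seed.
#' @return Tibble: `date`, one column per driver named in `couplings`.
#' @export
gen_drivers <- function(chem, couplings, seed = 1) {
  n <- nrow(chem)
  if (any(couplings$band_lo < 2 | couplings$band_hi > n / 2)) {
    abort_invalid("coupling bands must lie within [2, months/2].")
  }
  if (any(couplings$magnitude < 0 | couplings$magnitude > 1)) {
    abort_invalid("`magnitude` must be in [0, 1].")
  }
  if (any(abs(couplings$phase) > pi)) {
    abort_invalid("`phase` must be in [-pi, pi].")
  }
  doc <- fill_gaps_linear(chem$doc)
  x <- as.numeric(scale(doc))
  xf <- fft(x)
  k <- seq_len(n) - 1
  freq_period <- n / pmin(k, n - k)
  freq_period[1] <- Inf
  withr::with_seed(sub_seed(seed, 3L), {
    out <- tibble(date = chem$date)
    for (drv in unique(couplings$driver)) {
      rows <- couplings[couplings$driver == drv, ]
      comp <- numeric(n)
      for (i in seq_len(nrow(rows))) {
        keep <- freq_period >= rows$band_lo[i] &
          freq_period <= rows$band_hi[i]
        filt <- rep(0 + 0i, n)
        idx <- which(keep)
        pos <- idx[idx <= floor(n / 2) + 1]
        neg <- idx[idx > floor(n / 2) + 1]
        filt[pos] <- xf[pos] * exp(-1i * rows$phase[i])
        filt[neg] <- xf[neg] * exp(1i * rows$phase[i])
        band <- Re(fft(filt, inverse = TRUE)) / n
        if (sd(band) > 0) band <- band / sd(band)
        comp <- comp + rows$magnitude[i] * band
      }
      m2 <- min(sum(rows$magnitude^2), 1)
      out[[drv]] <- comp + sqrt(1 - m2) * rnorm(n)
    }
    out
  })
}

fill_gaps_linear <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  ok <- !is.na(x)
  if (sum(ok) < 2) abort_invalid("series has fewer than 2 observed values")
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

#' Synthetic probe photolysis kinetics
#'
#' Inverse of the quantum-yield math: a furfuryl alcohol (FFA) trace
#' decays exponentially with k_obs = k_rxn,FFA * (phi_true * Ra / k_dD),
#' where Ra is the in-vial rate of light absorption and k_dD is the
#' deactivation rate constant of singlet oxygen by water; a
#' p-nitroanisole (PNA) actinometer trace decays at the rate implied by
#' the configured actinometer quantum yield and the reference light
#' field. Multiplicative lognormal noise with coefficient of variation
#' `noise_cv`.
#'
#' @param phi_true True apparent quantum yield (FFA traces), mol
#'   mol-photons^-1.
#' @param ra In-vial rate of light absorption, M s^-1 (FFA traces).
#' @param species `"FFA"` or `"PNA"`.
#' @param times Sampling times, s, increasing, length >= 4. The default
#'   emulates a six-hour irradiation sampled half-hourly, long enough to
#'   decay an FFA probe by one to two half-lives at typical lake-water
#'   quantum yields so the fitted rate is well conditioned.
#' @param noise_cv Coefficient of variation of the lognormal noise
#'   (>= 0).
#' @param seed Integer seed.
#' @param conc0 Initial probe concentration, M.
#' @param constants A [photo_constants()] list.
#' @param field Reference [light_field()] (PNA traces).
#' @param pyridine_M Pyridine concentration, M (PNA traces).
#' @param lamp_scale Lamp intensity scale relative to the reference field
#'   (PNA traces); [actinometry_scale()] recovers it.
#' @return Tibble: `time_s`, `conc_M`, `species`.
#' @export
gen_kinetics <- function(phi_true, ra = 2e-6, species = c("FFA", "PNA"),
                         times = seq(0, 21600, by = 1800), noise_cv = 0,
                         seed = 1, conc0 = 2e-5,
                         constants = photo_constants(),
                         field = light_field(), pyridine_M = 0.01,
                         lamp_scale = 1) {
  species <- match.arg(species)
  if (length(times) < 4L) abort_invalid("`times` must have >= 4 points.")
  if (any(diff(times) <= 0) || any(times < 0)) {
    abort_invalid("`times` must be non-negative and increasing.")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    abort_invalid("`noise_cv` must be >= 0.")
  }
  if (species == "FFA") {
    stop_if_not_positive(ra, "ra")
    k_obs <- constants$k_rxn_ffa * phi_true * ra / constants$k_d_delta
  } else {
    phi_pna <- constants$phi_pna_slope * pyridine_M +
      constants$phi_pna_intercept
    k_obs <- lamp_scale * phi_pna * pna_absorption_rate(field)
  }
  conc <- conc0 * exp(-k_obs * times)
  if (noise_cv > 0) {
    conc <- withr::with_seed(sub_seed(seed, 4L), {
      conc * exp(rnorm(length(times), 0, sqrt(log(1 + noise_cv^2))))
    })
  }
  tibble(time_s = as.numeric(times), conc_M = conc, species = species)
}

#' Synthetic exponential CDOM absorbance spectrum
#'
#' a(lambda) = a440 * exp(-S * (lambda - 440)).
#'
#' @param a440 Napierian absorption at 440 nm, m^-1, > 0.
#' @param s_slope Spectral slope S, nm^-1, > 0.
#' @param grid Wavelength grid, nm.
#' @return An [absorbance_spectrum()] tibble.
#' @export
gen_spectrum <- function(a440, s_slope, grid = 250:600) {
  stop_if_not_positive(a440, "a440")
  stop_if_not_positive(s_slope, "s_slope")
  absorbance_spectrum(grid, a440 * exp(-s_slope * (grid - 440)))
}

#' Synthetic compound kinetics table
#'
#' Bimolecular singlet-oxygen reaction rate constants for a screening
#' set of compounds, lognormally spread around a median of 1.8e6
#' M^-1 s^-1 and clipped to the span observed for environmentally
#' relevant contaminants (6.3e3 to 3.7e9 M^-1 s^-1).
#'
#' @param n Number of compounds (default 106).
#' @param seed Integer seed.
#' @param k_median Median rate constant, M^-1 s^-1.
#' @param k_range Clipping range, M^-1 s^-1.
#' @return Tibble: `name`, `k_rxn`.
#' @export
gen_compounds <- function(n = 106, seed = 1, k_median = 1.8e6,
                          k_range = c(6.3e3, 3.7e9)) {
  if (n < 0) abort_invalid("`n` must be >= 0.")
  withr::with_seed(sub_seed(seed, 7L), {
    k <- stats::rlnorm(n, log(k_median), 2.2)
    k <- pmin(pmax(k, k_range[1]), k_range[2])
    tibble(name = sprintf("compound_%03d", seq_len(n)), k_rxn = k)
  })
}

#' Smooth clear-sky-like daily-average solar spectrum
#'
#' Emulates the shape of clear-sky daily-average spectral photon
#' irradiance tables from atmospheric radiative-transfer output: a sharp
#' atmospheric UV-B cutoff below ~300 nm, a steady climb through the UV-A
#' and a photon flux that keeps rising into the visible (at 550 nm
#' roughly five-fold the 330 nm value). The shape is a monotone spline
#' through anchor points matching published mid-latitude clear-sky
#' spectra, scaled so the 550 nm value equals `z_max`. Units:
#' mol-photons cm^-2 s^-1 nm^-1.
#'
#' @param grid Wavelength grid, nm (default 1 nm from 290 to 550).
#' @param z_max Photon irradiance at 550 nm, mol-photons cm^-2 s^-1
#'   nm^-1.
#' @return Tibble: `wavelength_nm`, `z_daily`.
#' @export
gen_solar_spectrum <- function(grid = 290:550, z_max = 2e-9) {
  anchors_nm <- c(290, 300, 310, 320, 330, 350, 375, 400, 450, 500, 550)
  anchors_rel <- c(2e-4, 0.005, 0.06, 0.15, 0.25, 0.40, 0.50, 0.60,
                   0.80, 0.90, 1.0)
  shape <- stats::splinefun(anchors_nm, anchors_rel, method = "monoH.FC")
  tibble(wavelength_nm = as.numeric(grid),
         z_daily = z_max * pmax(shape(grid), 0))
}
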