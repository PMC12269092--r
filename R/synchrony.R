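#' Preprocess a monthly series for wavelet analysis
#'
#' Standard preparation before coherence analysis: shift to strictly
#' positive values if needed, Box-Cox transform with the
#' maximum-likelihood lambda, remove a linear trend, and standardize to
#' zero mean and unit variance. Gaps (NA) are linearly interpolated and
#' flagged; a series with more than `max_gap_frac` missing is refused.
#'
#' @param x Numeric vector, length >= 48 (four annual cycles).
#' @param max_gap_frac Maximum tolerated fraction of missing values.
#' @return Object of class `preprocessed_series`: list with `values`
#'   (zero mean, unit variance), `transform_lambda`, `detrend_order`
#'   (always 1), `interpolated` flag and `n`.
#' @export
preprocess_series <- function(x, max_gap_frac = 0.1) {
  if (!is.numeric(x)) abort_invalid("`x` must be numeric.")
  if (any(!is.finite(x) & !is.na(x))) {
    abort_invalid("`x` contains non-finite values.")
  }
  if (length(x) < 48) abort_invalid("need >= 48 points.")
  gap_frac <- mean(is.na(x))
  if (gap_frac > max_gap_frac) {
    abort_invalid(sprintf("%.0f%% of values missing (> %.0f%% tolerated)",
                          100 * gap_frac, 100 * max_gap_frac))
  }
  interpolated <- gap_frac > 0
  x <- fill_gaps_linear(x)

  # shift to strictly positive support for the power transform
  if (min(x) <= 0) x <- x - min(x) + 1e-6 * max(diff(range(x)), 1)
  lambda <- boxcox_mle(x)
  y <- boxcox_transform(x, lambda)
  t <- seq_along(y)
  y <- stats::residuals(lm(y ~ t))
  y <- (y - mean(y)) / sd(y)

  structure(list(values = as.numeric(y), transform_lambda = lambda,
                 detrend_order = 1L, interpolated = interpolated,
                 n = length(y)),
            class = "preprocessed_series")
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

# Profile log-likelihood of the Box-Cox parameter for an intercept-only
# model; maximised over [-2, 3].
boxcox_mle <- function(x) {
  n <- length(x)
  slx <- sum(log(x))
  ll <- function(lambda) {
    y <- boxcox_transform(x, lambda)
    v <- mean((y - mean(y))^2)
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (lambda - 1) * slx
  }
  optimize(ll, c(-2, 3), maximum = TRUE, tol = 1e-6)$maximum
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based transform with the standard Morlet mother wavelet
#' (dimensionless frequency `omega0 = 6`), a logarithmic scale grid and
#' the usual e-folding cone of influence. The scale-to-Fourier-period
#' factor is `4*pi / (omega0 + sqrt(2 + omega0^2))` (about 1.03 at
#' `omega0 = 6`, so scales and periods are nearly interchangeable).
#'
#' @param x Numeric vector or a [preprocess_series()] object.
#' @param dt Sampling interval (months for monthly data).
#' @param period_range Periods to resolve, in units of `dt`; must lie in
#'   `[2*dt, n*dt/2]`.
#' @param scales_per_octave Scale-grid density (default 24).
#' @param omega0 Morlet dimensionless frequency.
#' @return Object of class `lakephoto_cwt`: complex coefficient matrix
#'   (`scale` x `time`), `period`, `scale`, `coi` (maximum admissible
#'   period per time point), `dt`.
#' @export
cwt_morlet <- function(x, dt = 1, period_range = NULL,
                       scales_per_octave = 24, omega0 = 6) {
  if (inherits(x, "preprocessed_series")) x <- x$values
  n <- length(x)
  if (is.null(period_range)) period_range <- c(2 * dt, n * dt / 2)
  if (period_range[1] < 2 * dt - 1e-9 ||
      period_range[2] > n * dt / 2 + 1e-9) {
    abort_invalid("`period_range` must lie within [2*dt, n*dt/2].")
  }
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- period_range[1] / ff
  j_max <- ceiling(log2(period_range[2] / period_range[1]) *
                     scales_per_octave)
  scales <- s0 * 2^((0:j_max) / scales_per_octave)
  period <- scales * ff

  npad <- 2^ceiling(log2(n))
  xhat <- fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)

  coef <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  norm <- pi^(-1 / 4) * sqrt(2 * pi / dt)
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- norm * sqrt(s) * exp(-(s * omega - omega0)^2 / 2) *
      (omega > 0)
    coef[j, ] <- (fft(xhat * daughter, inverse = TRUE) / npad)[1:n]
  }

  t_edge <- pmin(seq_len(n) - 0.5, n - seq_len(n) + 0.5) * dt
  coi <- ff / sqrt(2) * t_edge

  structure(list(coef = coef, period = period, scale = scales, coi = coi,
                 dt = dt, n = n, omega0 = omega0),
            class = "lakephoto_cwt")
}

#' Standard time-scale bands for monthly series
#'
#' Short (3-6 months), intermediate (12-24 months) and long (36-72
#' months) bands.
#'
#' @return Tibble: `band`, `band_lo`, `band_hi` (months).
#' @export
coherence_bands <- function() {
  tibble(band = c("short", "intermediate", "long"),
         band_lo = c(3, 12, 36), band_hi = c(6, 24, 72))
}

as_site_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    x <- do.call(cbind, x)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

# Per-site unit-modulus cross-wavelet products, COI- and band-masked,
# averaged into one complex number.
cross_mean <- function(wx_list, wy_list, band) {
  acc <- 0 + 0i
  n_pix <- 0L
  for (i in seq_along(wx_list)) {
    wx <- wx_list[[i]]
    wy <- wy_list[[i]]
    in_band <- wx$period >= band[1] & wx$period <= band[2]
    if (!any(in_band)) next
    cx <- wx$coef[in_band, , drop = FALSE]
    cy <- wy$coef[in_band, , drop = FALSE]
    prod <- cx * Conj(cy)
    mod <- Mod(prod)
    keep <- outer(wx$period[in_band], wx$coi, `<=`) & mod > 0
    if (!any(keep)) next
    acc <- acc + sum(prod[keep] / mod[keep])
    n_pix <- n_pix + sum(keep)
  }
  list(mean = if (n_pix > 0) acc / n_pix else NA_complex_, n_pix = n_pix)
}

#' Band-aggregated wavelet coherence between two sets of series
#'
#' For every site pair, computes the normalized cross-wavelet product
#' `w_x * Conj(w_y) / (|w_x| |w_y|)` at each time-scale pixel outside the
#' cone of influence, then averages the unit-modulus products over time,
#' sites and the scales of the requested band. The modulus of that mean
#' is the coherence magnitude (0 to 1); its argument is the mean phase.
#'
#' Phase convention: `phase = Arg(w_x * Conj(w_y))`, so a positive phase
#' means `x` leads `y` (a quarter-cycle delay of `y` behind `x` gives
#' `+pi/2`).
#'
#' @param x,y Numeric vectors, time-by-site matrices, or lists of
#'   vectors; `x[, i]` is paired with `y[, i]`.
#' @param band Length-2 numeric band (months), or a band name from
#'   [coherence_bands()].
#' @param preprocess Apply [preprocess_series()] to every column first
#'   (the pipeline default). Set `FALSE` when the inputs are already
#'   prepared.
#' @param ... Passed to [cwt_morlet()].
#' @return One-row tibble: `band`, `band_lo`, `band_hi`, `magnitude`,
#'   `mean_phase`, `phase_class`, `n_pixels`, `n_sites`.
#' @export
wavelet_coherence <- function(x, y, band = "intermediate",
                              preprocess = TRUE, ...) {
  band_row <- resolve_band(band)
  x <- as_site_matrix(x)
  y <- as_site_matrix(y)
  if (!all(dim(x) == dim(y))) {
    abort_invalid("`x` and `y` must have identical dimensions.")
  }
  prep <- function(v) if (preprocess) preprocess_series(v)$values else v
  wx <- lapply(seq_len(ncol(x)), function(i) cwt_morlet(prep(x[, i]), ...))
  wy <- lapply(seq_len(ncol(y)), function(i) cwt_morlet(prep(y[, i]), ...))
  cm <- cross_mean(wx, wy, c(band_row$band_lo, band_row$band_hi))
  if (cm$n_pix == 0L) {
    abort_insufficient("no time-scale pixels left in band after masking")
  }
  phase <- Arg(cm$mean)
  tibble(band = band_row$band, band_lo = band_row$band_lo,
         band_hi = band_row$band_hi, magnitude = Mod(cm$mean),
         mean_phase = phase, phase_class = phase_classify(phase),
         n_pixels = cm$n_pix, n_sites = ncol(x))
}

resolve_band <- function(band) {
  if (is.character(band)) {
    bands <- coherence_bands()
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1) {
      abort_invalid(sprintf("unknown band '%s'", band))
    }
    return(row)
  }
  if (!is.numeric(band) || length(band) != 2 || band[1] >= band[2]) {
    abort_invalid("`band` must be a name or an increasing length-2 range.")
  }
  rng <- band
  tibble(band = "custom", band_lo = rng[1], band_hi = rng[2])
}

#' Classify a mean phase into the four synchrony classes
#'
#' Positive in-phase for \[-pi/4, pi/4\], lagged positive for
#' (-3pi/4, -pi/4), lagged negative for (pi/4, 3pi/4), negative
#' antiphase for \[3pi/4, pi\] and \[-pi, -3pi/4\]. Boundaries fall to
#' the in-phase / antiphase side.
#'
#' @param phase Numeric phase(s) in radians, within \[-pi, pi\].
#' @return Character vector of phase classes.
#' @export
phase_classify <- function(phase) {
  if (any(abs(phase) > pi + 1e-12)) {
    abort_invalid("`phase` must lie in [-pi, pi].")
  }
  dplyr::case_when(
    abs(phase) <= pi / 4 ~ "positive_in_phase",
    abs(phase) >= 3 * pi / 4 ~ "negative_antiphase",
    phase < 0 ~ "lagged_positive",
    TRUE ~ "lagged_negative"
  )
}

#' Surrogate significance of band-aggregated coherence
#'
#' Builds `n_surrogates` phase-randomized Fourier surrogates of the `y`
#' series (the same random phase rotation is applied to every site, so
#' the cross-site alignment of the surrogates is preserved and each
#' site's autocorrelation is retained), recomputes the band magnitude for
#' each, and returns `p = (1 + #\{surrogate >= observed\}) /
#' (n_surrogates + 1)`.
#'
#' @inheritParams wavelet_coherence
#' @param n_surrogates Number of surrogates (>= 99).
#' @param seed Integer seed.
#' @return One-row tibble: the observed [wavelet_coherence()] row plus
#'   `p_band` and `n_surrogates`.
#' @export
band_significance <- function(x, y, band = "intermediate",
                              n_surrogates = 199, seed = 1,
                              preprocess = TRUE, ...) {
  if (n_surrogates < 99) abort_invalid("`n_surrogates` must be >= 99.")
  band_row <- resolve_band(band)
  rng <- c(band_row$band_lo, band_row$band_hi)
  x <- as_site_matrix(x)
  y <- as_site_matrix(y)
  prep <- function(v) if (preprocess) preprocess_series(v)$values else v
  xp <- apply(x, 2, prep)
  yp <- apply(y, 2, prep)
  n <- nrow(xp)
  # only band scales are needed for the band magnitude
  wx <- lapply(seq_len(ncol(xp)), function(i)
    cwt_morlet(xp[, i], period_range = rng, ...))
  wy <- lapply(seq_len(ncol(yp)), function(i)
    cwt_morlet(yp[, i], period_range = rng, ...))
  obs <- cross_mean(wx, wy, rng)
  if (obs$n_pix == 0L) {
    abort_insufficient("no time-scale pixels left in band after masking")
  }
  obs_mag <- Mod(obs$mean)

  yf <- lapply(seq_len(ncol(yp)), function(i) fft(yp[, i]))
  half <- floor((n - 1) / 2)
  sur_mag <- withr::with_seed(sub_seed(seed, 6L), {
    vapply(seq_len(n_surrogates), function(b) {
      rot <- rep(0, n)
      ph <- runif(half, 0, 2 * pi)
      rot[2:(half + 1)] <- ph
      rot[n:(n - half + 1)] <- -ph
      wy_s <- lapply(yf, function(f) {
        ys <- Re(fft(f * exp(1i * rot), inverse = TRUE)) / n
        cwt_morlet(ys, period_range = rng, ...)
      })
      Mod(cross_mean(wx, wy_s, rng)$mean)
    }, numeric(1))
  })

  p <- (1 + sum(sur_mag >= obs_mag)) / (n_surrogates + 1)
  phase <- Arg(obs$mean)
  tibble(band = band_row$band, band_lo = rng[1], band_hi = rng[2],
         magnitude = obs_mag, mean_phase = phase,
         phase_class = phase_classify(phase), n_pixels = obs$n_pix,
         n_sites = ncol(x), p_band = p, n_surrogates = n_surrogates)
}

#' Coherence table for several drivers across standard bands
#'
#' Convenience wrapper running [band_significance()] for every driver
#' column against the response matrix over every band.
#'
#' @param response Time-by-site matrix (or vector) of the response
#'   series, e.g. DOC.
#' @param drivers Tibble/data frame of driver series (one column each; a
#'   `date` column is ignored).
#' @param bands Band tibble as from [coherence_bands()].
#' @param ... Passed to [band_significance()].
#' @return Tibble with one row per (driver, band).
#' @export
coherence_table <- function(response, drivers, bands = coherence_bands(),
                            ...) {
  drivers <- drivers[setdiff(names(drivers), "date")]
  response <- as_site_matrix(response)
  purrr::map_dfr(names(drivers), function(drv) {
    ym <- matrix(drivers[[drv]], nrow = nrow(response),
                 ncol = ncol(response))
    purrr::pmap_dfr(bands, function(band, band_lo, band_hi) {
      res <- band_significance(response, ym, band = c(band_lo, band_hi),
                               ...)
      res$band <- band
      dplyr::bind_cols(tibble(driver = drv), res)
    })
  })
}
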