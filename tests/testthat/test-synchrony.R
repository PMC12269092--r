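test_that("preprocessing yields zero mean, unit variance, no trend", {
  withr::with_seed(1, {
    x <- rnorm(120)
    pp <- preprocess_series(x)
    expect_equal(mean(pp$values), 0, tolerance = 1e-9)
    expect_equal(var(pp$values), 1, tolerance = 1e-9)

    y <- 5 * (1:120) + rnorm(120)
    ppy <- preprocess_series(y)
    slope <- unname(coef(lm(ppy$values ~ seq_len(120)))[2])
    expect_equal(slope, 0, tolerance = 1e-9)
  })
  expect_error(preprocess_series(c(rnorm(50), Inf)),
               class = "lakephoto_invalid_argument")
  expect_error(preprocess_series(rnorm(20)),
               class = "lakephoto_invalid_argument")
})

test_that("Box-Cox MLE finds a log-like transform for lognormal data", {
  lambdas <- vapply(1:50, function(s) {
    withr::with_seed(s, preprocess_series(rlnorm(360))$transform_lambda)
  }, numeric(1))
  expect_gte(mean(abs(lambdas) < 0.3), 0.9)
})

test_that("gap handling interpolates small gaps and refuses large ones", {
  withr::with_seed(2, {
    x <- rnorm(100) + 10
    x[c(10, 50)] <- NA
    pp <- preprocess_series(x)
    expect_true(pp$interpolated)
    x[1:30] <- NA
    expect_error(preprocess_series(x),
                 class = "lakephoto_invalid_argument")
  })
})

test_that("Morlet CWT localises frequencies and zeroes a zero series", {
  t <- 0:359
  w <- cwt_morlet(sin(2 * pi * t / 12))
  amp <- rowMeans(Mod(w$coef))
  peak <- w$period[which.max(amp)]
  grid_step <- w$period[2] / w$period[1]
  expect_lt(abs(log(peak / 12)), log(grid_step) * 1.5)

  wz <- cwt_morlet(rep(0, 128))
  expect_true(all(Mod(wz$coef) == 0))

  two <- sin(2 * pi * t / 12) + sin(2 * pi * t / 48)
  w2 <- cwt_morlet(two)
  amp2 <- rowMeans(Mod(w2$coef))
  near <- function(p) which.min(abs(w2$period - p))
  # both tones produce local maxima within a step or two of their period
  expect_gt(amp2[near(12)], amp2[near(20)])
  expect_gt(amp2[near(48)], amp2[near(20)])
  expect_gt(amp2[near(48)], amp2[near(90)])

  expect_error(cwt_morlet(rnorm(64), period_range = c(1, 32)),
               class = "lakephoto_invalid_argument")
})

test_that("coherence is exact for identical, inverted and lagged pairs", {
  t <- 0:359
  x <- sin(2 * pi * t / 12) + 0.3 * sin(2 * pi * t / 50)

  same <- wavelet_coherence(x, x, band = "intermediate",
                            preprocess = FALSE)
  expect_equal(same$magnitude, 1, tolerance = 1e-12)
  expect_equal(same$mean_phase, 0, tolerance = 1e-12)
  expect_equal(same$phase_class, "positive_in_phase")

  flip <- wavelet_coherence(x, -x, band = "intermediate",
                            preprocess = FALSE)
  expect_equal(flip$magnitude, 1, tolerance = 1e-12)
  expect_equal(abs(flip$mean_phase), pi, tolerance = 1e-12)
  expect_equal(flip$phase_class, "negative_antiphase")

  # quarter-cycle delay of y behind x at the 12-month scale: x leads,
  # phase +pi/2 under the package convention
  xs <- sin(2 * pi * t / 12)
  ys <- sin(2 * pi * (t - 3) / 12)
  lag <- wavelet_coherence(xs, ys, band = "intermediate",
                           preprocess = FALSE)
  expect_lt(abs(lag$mean_phase - pi / 2), 0.1)
  expect_match(lag$phase_class, "lagged")
})

test_that("phase classes map the quoted intervals and boundaries", {
  expect_equal(phase_classify(0.013), "positive_in_phase")
  expect_equal(phase_classify(1.91), "lagged_negative")
  expect_equal(phase_classify(3.06), "negative_antiphase")
  expect_equal(phase_classify(-1.31), "lagged_positive")
  # boundaries fall to the in-phase / antiphase side
  expect_equal(phase_classify(pi / 4), "positive_in_phase")
  expect_equal(phase_classify(-pi / 4), "positive_in_phase")
  expect_equal(phase_classify(3 * pi / 4), "negative_antiphase")
  expect_equal(phase_classify(-3 * pi / 4), "negative_antiphase")
  expect_error(phase_classify(4), class = "lakephoto_invalid_argument")
})

test_that("magnitude stays in [0, 1] and shrinks with uncorrelated sites", {
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(120)
      y <- rnorm(120)
      m <- wavelet_coherence(x, y, band = "intermediate",
                             preprocess = FALSE)$magnitude
      expect_gte(m, 0)
      expect_lte(m, 1)
    }
    t <- 0:119
    base <- sin(2 * pi * t / 16)
    coherent <- wavelet_coherence(base, base, band = c(12, 24),
                                  preprocess = FALSE)$magnitude
    diluted <- vapply(1:50, function(i) {
      x2 <- cbind(base, rnorm(120))
      y2 <- cbind(base, rnorm(120))
      wavelet_coherence(x2, y2, band = c(12, 24),
                        preprocess = FALSE)$magnitude
    }, numeric(1))
    expect_lt(mean(diluted), coherent)
  })
})

test_that("planted couplings are recovered with the requested phase class", {
  lake <- gen_lakes(1, seed = 4)
  chem <- gen_chemistry(lake, months = 360, seed = 4, missing_frac = 0)
  couplings <- tibble::tibble(
    driver = c("inphase", "anti"),
    band_lo = 12, band_hi = 24,
    magnitude = 1, phase = c(0, pi))
  drv <- gen_drivers(chem, couplings, seed = 4)
  doc <- preprocess_series(chem$doc)$values
  inph <- wavelet_coherence(doc, drv$inphase, band = "intermediate",
                            preprocess = FALSE)
  expect_equal(inph$phase_class, "positive_in_phase")
  expect_gt(inph$magnitude, 0.6)
  anti <- wavelet_coherence(doc, drv$anti, band = "intermediate",
                            preprocess = FALSE)
  expect_equal(anti$phase_class, "negative_antiphase")

  bad <- tibble::tibble(driver = "x", band_lo = 1, band_hi = 24,
                        magnitude = 1, phase = 0)
  expect_error(gen_drivers(chem, bad),
               class = "lakephoto_invalid_argument")
})

test_that("surrogate test is exact for a perfectly coherent pair", {
  t <- 0:239
  x <- sin(2 * pi * t / 16) + 0.1 * cos(2 * pi * t / 40)
  res <- band_significance(x, x, band = c(12, 24), n_surrogates = 999,
                           seed = 9, preprocess = FALSE)
  expect_equal(res$p_band, 1 / 1000)
  expect_error(band_significance(x, x, n_surrogates = 10),
               class = "lakephoto_invalid_argument")
})
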