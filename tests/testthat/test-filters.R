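test_that("moving-average detrend annihilates trends and keeps striae", {
  step <- 3
  n <- 1201
  ramp <- new_signature(5 + 0.02 * seq_len(n), step)
  out <- detrend_signature(ramp, window = 301)
  expect_lt(max(abs(out$values)), 1e-9)
  expect_identical(out$processing_state, "detrended")

  const <- new_signature(rep(4.2, n), step)
  expect_lt(max(abs(detrend_signature(const, 151)$values)), 1e-12)

  expect_error(detrend_signature(ramp, window = 300), "odd")
  expect_error(detrend_signature(ramp, window = n + 2), "odd|within")

  # short-period sinusoid: interior attenuation follows the closed-form
  # Dirichlet transfer function of the moving average, 1 - D_W(f)
  w <- 301
  period <- 25 # samples, << window
  x <- sin(2 * pi * seq_len(n) / period)
  sig <- new_signature(10 + 0.01 * seq_len(n) + x, step)
  out <- detrend_signature(sig, w)
  interior <- (w + 1):(n - w)
  f <- 1 / period
  dirichlet <- sin(pi * f * w) / (w * sin(pi * f))
  expected_gain <- 1 - dirichlet
  basis <- cbind(sin(2 * pi * seq_len(n) / period),
                 cos(2 * pi * seq_len(n) / period))
  amp <- sqrt(sum(coef(lm(out$values[interior] ~ basis[interior, ]))[-1]^2))
  expect_lt(abs(amp - abs(expected_gain)) / abs(expected_gain), 0.01)
})

test_that("the low-pass filter is zero-phase and meets its attenuation", {
  step <- 3
  n <- 1200
  cutoff <- 1 / 15
  dc <- new_signature(rep(2.5, n), step)
  out <- lowpass_signature(dc, cutoff)
  expect_lt(max(abs(out$values - 2.5)), 1e-6)

  # pure tone at 3x cutoff is crushed (spectral measurement away from the
  # signature ends, where any finite filter carries boundary leakage)
  t_um <- (seq_len(n) - 1) * step
  interior <- 200:(n - 200)
  tone <- new_signature(sin(2 * pi * 3 * cutoff * t_um), step)
  out <- lowpass_signature(tone, cutoff)
  expect_lt(sqrt(mean(out$values[interior]^2)) /
              sqrt(mean(tone$values[interior]^2)), 0.01)

  # tone at 2x cutoff: >= 40 dB with the default order
  tone2 <- new_signature(sin(2 * pi * 2 * cutoff * t_um), step)
  out2 <- lowpass_signature(tone2, cutoff)
  atten_db <- -20 * log10(sqrt(mean(out2$values[interior]^2)) /
                            sqrt(mean(tone2$values[interior]^2)))
  expect_gte(atten_db, 40)

  # impulse response is symmetric about the impulse (zero phase)
  imp <- numeric(801); imp[401] <- 1
  h <- lowpass_signature(new_signature(imp, step), cutoff)$values
  expect_lt(max(abs(h - rev(h))), 1e-9)

  expect_error(lowpass_signature(dc, cutoff = 1 / (2 * step)), "Nyquist")
})

test_that("band-pass filters pass the band, stop the stopband, zero phase", {
  step <- 3
  n <- 1600
  t_um <- (seq_len(n) - 1) * step
  low <- 1 / 100; high <- 1 / 20
  centre <- (low + high) / 2
  interior <- 300:(n - 300)
  rms <- function(v) sqrt(mean(v[interior]^2))

  for (kind in c("gaussian", "chebyshev2")) {
    tone_in <- new_signature(sin(2 * pi * centre * t_um), step)
    out_in <- bandpass_signature(tone_in, kind, low = low, high = high)
    expect_lt(abs(rms(out_in$values) / rms(tone_in$values) - 1), 0.05)

    tone_lo <- new_signature(sin(2 * pi * (low / 4) * t_um), step)
    out_lo <- bandpass_signature(tone_lo, kind, low = low, high = high)
    atten <- -20 * log10(rms(out_lo$values) / rms(tone_lo$values))
    expect_gte(atten, 20)

    z <- bandpass_signature(new_signature(rep(0, n), step), kind,
                            low = low, high = high)
    expect_lt(max(abs(z$values)), 1e-12)

    # zero phase: striae peaks do not move under filtering
    sig <- rand_sig(n, seed = 31, step = step)
    filt <- bandpass_signature(sig, kind, low = low, high = high)
    r <- normalized_xcorr(sig, new_signature(filt$values, step,
                                             processing_state = "detrended"),
                          max_lag = 50)
    expect_identical(r$best_lag, 0L)

    expect_error(bandpass_signature(sig, kind, low = 0.1, high = 0.05),
                 "band")
  }
})

test_that("filtering does not displace striae peaks", {
  # signature content entirely inside the passband: peaks must stay put
  v <- band_limited_noise(1200, 3, c(1 / 200, 1 / 30), 1, seed = 77)
  sig <- as_detrended(v)
  filt <- lowpass_signature(sig, cutoff = 1 / 15)
  p0 <- find_striae(sig)
  p1 <- find_striae(filt)
  # every prominent filtered peak sits within half a sample of an original one
  shifts <- vapply(p1$index, function(i) min(abs(p0$index - i)), numeric(1))
  expect_lt(stats::median(shifts), 0.5)
  r <- normalized_xcorr(sig,
                        new_signature(filt$values, sig$step,
                                      processing_state = "detrended"),
                        max_lag = 50)
  expect_identical(r$best_lag, 0L)
})
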