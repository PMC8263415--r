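test_that("fast correlation equals the direct double-loop definition", {
  for (trial in 1:20) {
    n1 <- 80 + (trial * 13) %% 60
    n2 <- 80 + (trial * 7) %% 60
    a <- rand_sig(n1, child_seed(40, trial, 1))
    b <- rand_sig(n2, child_seed(40, trial, 2))
    max_lag <- 20 + trial %% 10
    r <- normalized_xcorr(a, b, max_lag = max_lag)
    o <- brute_xcorr(a$values, b$values, max_lag)
    expect_identical(r$lags, o$lags)
    expect_lt(max(abs(r$xcorr - o$xcorr), na.rm = TRUE), 1e-12)
    expect_identical(is.na(r$xcorr), is.na(o$xcorr))

    # per-window Pearson variant against its own oracle
    rp <- normalized_xcorr(a, b, max_lag = max_lag, pearson_window = TRUE)
    op <- brute_xcorr(a$values, b$values, max_lag, pearson = TRUE)
    expect_lt(max(abs(rp$xcorr - op$xcorr), na.rm = TRUE), 1e-12)
  }
})

test_that("self-match, pure shift, and tie-breaking behave exactly", {
  s <- rand_sig(400, seed = 41)
  r <- normalized_xcorr(s, s)
  expect_identical(r$best_lag, 0L)
  expect_lt(abs(r$score - 1), 1e-9)

  # s2 = s1 delayed by 7 samples
  delayed <- as_detrended(c(rep(0, 7), s$values), origin = "delayed")
  r2 <- normalized_xcorr(s, delayed, max_lag = 30)
  expect_identical(r2$best_lag, 7L)
  expect_lt(abs(r2$score - 1), 1e-9)

  # ties resolve to the smallest |k|, then the negative lag
  flat <- as_detrended(rep(c(-1, 1), 50))
  rt <- normalized_xcorr(flat, flat, max_lag = 8)
  expect_identical(rt$best_lag, 0L)
})

test_that("correlation invariants hold across a randomized suite", {
  for (trial in 1:15) {
    a <- rand_sig(150 + trial, child_seed(42, trial, 1))
    b <- rand_sig(150 + (trial * 3) %% 40, child_seed(42, trial, 2))
    r <- normalized_xcorr(a, b, max_lag = 25)
    # boundedness (Cauchy-Schwarz)
    expect_true(all(abs(r$xcorr) <= 1 + 1e-12, na.rm = TRUE))

    # exact scale invariance under positive rescaling
    a4 <- as_detrended(4 * a$values)
    bh <- as_detrended(0.5 * b$values)
    r_scaled <- normalized_xcorr(a4, bh, max_lag = 25)
    expect_identical(r_scaled$xcorr, r$xcorr)
    expect_identical(r_scaled$best_lag, r$best_lag)
    a_arb <- as_detrended(0.0371 * a$values)
    r_arb <- normalized_xcorr(a_arb, b, max_lag = 25)
    expect_lt(max(abs(r_arb$xcorr - r$xcorr), na.rm = TRUE), 1e-12)

    # symmetry on full overlap (equal lengths)
    c2 <- as_detrended(b$values[seq_along(a$values) %% length(b$values) + 1])
    rab <- normalized_xcorr(a, c2, max_lag = 25)
    rba <- normalized_xcorr(c2, a, max_lag = 25)
    expect_identical(rba$best_lag, -rab$best_lag)
    expect_lt(abs(rab$score - rba$score), 1e-12)

    # shift equivariance: sliding s2's window by m moves best_lag by exactly
    # -m and leaves the score untouched (full-overlap construction)
    long <- band_limited_noise(260, 3, c(1 / 200, 1 / 10), 1,
                               child_seed(42, trial, 3))
    d <- 4; m <- 5
    a2 <- as_detrended(long[1:200])
    s2 <- as_detrended(long[(1 + d):(200 + d)])
    s2m <- as_detrended(long[(1 + d + m):(200 + d + m)])
    r1 <- normalized_xcorr(a2, s2, max_lag = 25)
    r2 <- normalized_xcorr(a2, s2m, max_lag = 25)
    expect_identical(r1$best_lag, -as.integer(d))
    expect_identical(r2$best_lag, r1$best_lag - as.integer(m))
    expect_lt(abs(r1$score - 1), 1e-9)
    expect_lt(abs(r2$score - r1$score), 1e-9)
  }
})

test_that("overlap and energy guards are enforced", {
  a <- rand_sig(100, seed = 43)
  r <- normalized_xcorr(a, a, max_lag = 40, min_overlap = 0.8)
  # lags with overlap below 80 samples are excluded
  expect_true(all(is.na(r$xcorr[abs(r$lags) > 20])))
  expect_true(all(!is.na(r$xcorr[abs(r$lags) <= 20])))

  expect_error(normalized_xcorr(a, a, max_lag = 100), "max_lag")
  expect_error(normalized_xcorr(a, a, min_overlap = 0), "min_overlap")
  raw <- new_signature(a$values, a$step) # still raw
  expect_error(normalized_xcorr(raw, a), "detrended")

  # an all-zero window is excluded with a warning
  z <- as_detrended(rep(0, 100))
  expect_warning(expect_error(normalized_xcorr(a, z), "no admissible lag"),
                 "zero-energy")
})

test_that("alignment and averaging recover shifts and suppress noise", {
  base <- band_limited_noise(700, 3, c(1 / 200, 1 / 10), 1, seed = 44)
  starts <- c(101, 96, 108, 99, 104)
  L <- 500
  sigs <- lapply(starts, function(s0) {
    as_detrended(base[s0:(s0 + L - 1)], origin = paste0("s", s0))
  })
  set <- signature_set(sigs, "shifted")
  avg <- align_and_average(set, max_lag = 30)
  expect_identical(attr(avg, "shifts"), as.integer(starts[1] - starts))
  # the average equals the common profile on the covered support (anchor
  # coordinates where at least ceil(n/2) signatures overlap)
  support <- attr(avg, "support")
  ref_start <- starts[1] + support[1] - 1
  expect_identical(length(avg$values), as.integer(diff(support) + 1))
  expect_lt(max(abs(avg$values -
                      base[ref_start:(ref_start + length(avg$values) - 1)])),
            1e-12)

  # five identical signatures average to themselves
  same <- signature_set(rep(list(sigs[[1]]), 5), "same")
  expect_equal(align_and_average(same)$values, sigs[[1]]$values,
               tolerance = 1e-12)

  # single-signature set passes through unchanged
  one <- signature_set(sigs[1], "one")
  expect_identical(align_and_average(one)$values, sigs[[1]]$values)

  # i.i.d. noise shrinks like 1/sqrt(5)
  sigma <- 0.2
  noisy <- lapply(1:5, function(i) {
    as_detrended(base[101:600] +
                   with_seed(child_seed(45, i), rnorm(500, 0, sigma)))
  })
  avg_n <- align_and_average(signature_set(noisy, "noisy"), max_lag = 30)
  resid <- avg_n$values - base[101:600][seq_along(avg_n$values)]
  target <- sigma / sqrt(5)
  expect_lt(abs(sd(resid) - target) / target, 0.20)
})

test_that("mark comparison is reversal-aware and refuses mismatched chains", {
  base <- rand_sig(500, seed = 46)
  setA <- signature_set(rep(list(base), 3), "A")
  expect_lt(abs(compare_marks(setA, setA)$score - 1), 1e-9)

  # a mirrored counterpart is found by the reversal search
  mirrored <- signature_set(list(as_detrended(rev(base$values))), "B")
  res <- compare_marks(setA, mirrored, allow_reverse = TRUE)
  expect_true(res$reversed)
  expect_lt(abs(res$score - 1), 1e-9)
  res_no <- compare_marks(setA, mirrored, allow_reverse = FALSE)
  expect_lt(res_no$score, 0.9)

  # different pre-processing chains are refused
  s_raw <- new_signature(base$values, 3)
  setC <- signature_set(list(lowpass_signature(detrend_signature(s_raw, 301),
                                               1 / 15)), "C")
  setD <- signature_set(list(lowpass_signature(detrend_signature(s_raw, 151),
                                               1 / 15)), "D")
  expect_error(compare_marks(setC, setD), "pre-processed differently")
})
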