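test_that("blade generation is deterministic and band-controlled", {
  b1 <- generate_blade(seed = 1, length_um = 1500)
  b2 <- generate_blade(seed = 1, length_um = 1500)
  expect_identical(b1, b2)
  expect_error(generate_blade(seed = 1, length_um = 100), ">= 64")
  expect_error(generate_blade(seed = 1, length_um = 1500,
                              band = c(0.01, 0.4)), "Nyquist")

  # variance lands near the configured amplitude
  expect_lt(abs(sd(b1$edge_signature) - 1), 1e-9)

  # a periodic class component appears in the spectrum iff its amplitude > 0
  # (period chosen on an FFT bin of the 1536-um profile: no leakage)
  period <- 64
  with_class <- generate_blade(seed = 2, length_um = 1536,
                               class_component = list(amplitude = 2,
                                                      period = period))
  without <- generate_blade(seed = 2, length_um = 1536,
                            class_component = list(amplitude = 0,
                                                   period = period))
  plain <- generate_blade(seed = 2, length_um = 1536)
  expect_identical(without$edge_signature, plain$edge_signature)
  spec_amp <- function(v, f_target, step = 3) {
    n <- length(v)
    f <- abs(striasig:::fft_freqs(n, step))
    bin <- which.min(abs(f - f_target))
    2 * Mod(fft(v))[bin] / n
  }
  expect_gt(spec_amp(with_class$edge_signature, 1 / period), 1.5)
  expect_lt(spec_amp(without$edge_signature, 1 / period), 0.5)
})

test_that("edge profiles from different seeds are uncorrelated", {
  # Monte-Carlo check under one master seed: the peak normalized
  # cross-correlation of two independent blades stays below 0.5
  worst <- 0
  for (trial in 1:200) {
    a <- rand_sig(256, child_seed(20, trial, 1))
    b <- rand_sig(256, child_seed(20, trial, 2))
    r <- normalized_xcorr(a, b)
    worst <- max(worst, abs(r$score))
  }
  expect_lt(worst, 0.5)
})

test_that("a noiseless imprint replicates the edge segment along every row", {
  qm <- quiet_mark(rows = 16)
  g <- qm$grid
  seg <- edge_window(qm$blade, ncols = ncol(g$heights))
  for (r in seq_len(nrow(g$heights))) {
    expect_identical(unname(g$heights[r, ]), seg)
  }
  expect_true(all(g$valid_mask))
  expect_identical(g$meta$truth$blade_id, qm$blade$blade_id)

  # section window outside the blade is refused
  expect_error(
    imprint_mark(qm$blade, quiet_mark_config(section_offset = 2000,
                                             section_length = 1536)),
    "outside"
  )
})

test_that("a plane fit recovers injected tilt", {
  flat <- generate_blade(seed = 4, length_um = 2500, amplitude_sd = 0)
  g <- imprint_mark(flat, quiet_mark_config(rows = 32, tilt_x = 0.01,
                                            tilt_y = 0.02))
  df <- expand.grid(y = (seq_len(nrow(g$heights)) - 1) * g$pitch_y,
                    x = (seq_len(ncol(g$heights)) - 1) * g$pitch_x)
  df$z <- as.vector(g$heights)
  fit <- coef(lm(z ~ x + y, data = df))
  expect_lt(abs(fit[["x"]] - 0.01), 1e-6)
  expect_lt(abs(fit[["y"]] - 0.02), 1e-6)
})

test_that("KM/KNM manifests enumerate pairs correctly and consistently", {
  tiny <- quiet_mark_config(rows = 8, section_length = 300)
  counts <- function(n_b, m_b, seed) {
    ds <- make_km_knm_dataset(n_b, m_b, tiny, seed = seed,
                              angle_jitter_deg = 0)
    tab <- table(ds$manifest$label)
    # exhaustive consistency: KM pairs share a blade, KNM pairs never do
    blade_of <- vapply(ds$grids, function(g) g$meta$blade, character(1))
    same <- blade_of[ds$manifest$mark_a] == blade_of[ds$manifest$mark_b]
    expect_identical(unname(same), ds$manifest$label == "KM")
    c(KM = unname(tab["KM"]), KNM = unname(tab["KNM"]),
      total = nrow(ds$manifest))
  }
  expect_identical(counts(4, 2, 1), c(KM = 4L, KNM = 24L, total = 28L))
  expect_identical(counts(2, 2, 2), c(KM = 2L, KNM = 4L, total = 6L))
  # brute-force enumeration oracle for an asymmetric design
  expect_identical(counts(5, 3, 3),
                   c(KM = as.integer(5 * choose(3, 2)),
                     KNM = as.integer(choose(15, 2) - 15),
                     total = as.integer(choose(15, 2))))
  expect_error(make_km_knm_dataset(1, 2, tiny, seed = 1), "n_blades")
})

test_that("dataset regeneration under a fixed seed is identical", {
  tiny <- mark_sim_config(rows = 16, section_length = 300)
  d1 <- make_km_knm_dataset(2, 2, tiny, seed = 5)
  d2 <- make_km_knm_dataset(2, 2, tiny, seed = 5)
  expect_identical(d1, d2)
  d3 <- make_km_knm_dataset(2, 2, tiny, seed = 6)
  expect_false(identical(d1$grids[[1]]$heights, d3$grids[[1]]$heights))
})
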