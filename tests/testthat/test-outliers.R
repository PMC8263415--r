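test_that("a single spike is flagged exactly, by both flagging methods", {
  qm <- quiet_mark(rows = 32)
  g <- qm$grid
  g$heights[17, 200] <- g$heights[17, 200] + 50

  ls <- remove_outliers(g, "local_sigma", k = 3)
  expect_identical(which(!ls$valid_mask), which(row(g$heights) == 17 &
                                                  col(g$heights) == 200))
  st <- remove_outliers(g, "slope_threshold")
  expect_identical(which(!st$valid_mask), which(row(g$heights) == 17 &
                                                  col(g$heights) == 200))
  # all other points bit-identical
  keep <- ls$valid_mask
  expect_identical(ls$heights[keep], g$heights[keep])
})

test_that("clean grids pass through every method unchanged", {
  b <- generate_blade(seed = 9, length_um = 2500)
  g <- imprint_mark(b, quiet_mark_config(rows = 48, noise_sd = 0.05,
                                         rng_seed = 4))
  for (m in c("slope_threshold", "local_sigma", "nn_substitute")) {
    out <- remove_outliers(g, m)
    expect_identical(out$heights, g$heights)
    expect_identical(out$valid_mask, g$valid_mask)
  }
})

test_that("injected spikes are found with few false flags", {
  b <- generate_blade(seed = 10, length_um = 2500)
  g <- imprint_mark(b, quiet_mark_config(rows = 96, noise_sd = 0.05,
                                         spike_rate = 0.01,
                                         spike_amplitude = 20, rng_seed = 5))
  truth <- g$meta$truth$spike_idx
  out <- remove_outliers(g, "slope_threshold")
  flagged <- which(!out$valid_mask)
  hit <- mean(truth %in% flagged)
  false_rate <- length(setdiff(flagged, truth)) /
    (length(g$heights) - length(truth))
  expect_gte(hit, 0.95)
  expect_lte(false_rate, 0.005)
})

test_that("flagging is idempotent at fixed parameters", {
  b <- generate_blade(seed = 11, length_um = 2500)
  g <- imprint_mark(b, quiet_mark_config(rows = 64, noise_sd = 0.05,
                                         spike_rate = 0.005,
                                         spike_amplitude = 20, rng_seed = 6))
  for (m in c("slope_threshold", "local_sigma")) {
    once <- remove_outliers(g, m)
    twice <- remove_outliers(once, m)
    expect_identical(twice$heights, once$heights)
    expect_identical(twice$valid_mask, once$valid_mask)
  }
})

test_that("nearest-neighbour substitution fills invalid points", {
  qm <- quiet_mark(rows = 32, dropout_rate = 0.02, rng_seed = 7)
  g <- qm$grid
  expect_gt(sum(!g$valid_mask), 0)
  out <- remove_outliers(g, "nn_substitute", neighbors = 10)
  expect_true(all(out$valid_mask))
  # untouched pixels are bit-identical
  expect_identical(out$heights[g$valid_mask], g$heights[g$valid_mask])

  # substituted value equals the mean of the 10 nearest valid pixels
  bad <- which(!g$valid_mask, arr.ind = TRUE)[1, , drop = FALSE]
  ok <- which(g$valid_mask, arr.ind = TRUE)
  d2 <- (ok[, 1] - bad[1])^2 * g$pitch_y^2 + (ok[, 2] - bad[2])^2 * g$pitch_x^2
  nn <- ok[order(d2)[1:10], , drop = FALSE]
  expect_equal(out$heights[bad], mean(g$heights[nn]), tolerance = 1e-12)

  expect_error(remove_outliers(g, "nn_substitute", neighbors = 0), ">= 1")
  expect_error(remove_outliers(g, "local_sigma", window = 2), "odd")
})
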