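test_that("reference construction records designs and handles degeneracy", {
  expect_warning(
    ref <- build_reference(rep(0.9, 4), c(0.2, 0.25, 0.3, 0.22)),
    "zero-variance"
  )
  expect_identical(ref$km_ci, c(0.9, 0.9))
  expect_identical(ref$km_mean, 0.9)
  expect_identical(ref$km_sd, 0)

  km <- c(0.95, 0.97, 0.96, 0.99)
  knm <- seq(0.1, 0.33, by = 0.01)
  ref <- build_reference(km, knm)
  expect_identical(ref$n_km, 4L)
  expect_identical(ref$n_knm, 24L)
  expect_identical(ref$ci_method, "t")
  expect_identical(ref$interval, "scores")
  # the interval contains its sample mean
  expect_true(ref$km_ci[1] <= ref$km_mean && ref$km_mean <= ref$km_ci[2])
  expect_true(ref$knm_ci[1] <= ref$knm_mean && ref$knm_mean <= ref$knm_ci[2])
  # both interval scopes against their textbook formulas
  expect_equal(ref$km_ci,
               mean(km) + c(-1, 1) * qt(0.975, 3) * sd(km) * sqrt(1 + 1 / 4),
               tolerance = 1e-12)
  ref_m <- build_reference(km, knm, interval = "mean")
  expect_equal(ref_m$km_ci,
               mean(km) + c(-1, 1) * qt(0.975, 3) * sd(km) / 2,
               tolerance = 1e-12)
  # the score interval always contains the mean interval
  expect_lt(ref$km_ci[1], ref_m$km_ci[1])
  expect_gt(ref$km_ci[2], ref_m$km_ci[2])

  expect_error(build_reference(0.9, knm), ">= 2")
  expect_error(build_reference(c(2, 0.9), knm), "lie in")
  expect_error(build_reference(km, knm, ci_method = "bootstrap"), "seed")
})

test_that("t and bootstrap intervals agree on Gaussian scores", {
  x <- with_seed(60, rnorm(24, 0.3, 0.05))
  y <- with_seed(61, rnorm(24, 0.9, 0.02))
  rt <- build_reference(y, x, ci_method = "t", interval = "mean")
  rb <- build_reference(y, x, ci_method = "bootstrap", interval = "mean",
                        boot_reps = 1e5, seed = 62)
  hw_t <- diff(rt$knm_ci) / 2
  hw_b <- diff(rb$knm_ci) / 2
  expect_lt(abs(hw_t - hw_b), 0.1 * hw_b)
})

test_that("the CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(4, 16, 64), function(n) {
    mean(vapply(1:200, function(i) {
      x <- with_seed(child_seed(63, n, i), rnorm(n, 0.5, 0.1))
      r <- suppressWarnings(build_reference(x, x, ci_method = "normal",
                                            interval = "mean"))
      diff(r$km_ci)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(widths[1] / widths[2] - 2), 0.4)
  expect_lt(abs(widths[2] / widths[3] - 2), 0.25)
})

test_that("the Fisher-z option respects the score boundary", {
  km <- c(0.995, 0.999, 0.997, 0.998)
  knm <- c(0.2, 0.3, 0.25, 0.28, 0.22, 0.31)
  rz <- build_reference(km, knm, fisher_z = TRUE)
  expect_lte(rz$km_ci[2], 1)
  expect_gte(rz$km_ci[1], tanh(mean(atanh(km)) - 10)) # sane lower bound
})

test_that("the CI decision rule classifies by the verdict table", {
  ref <- suppressWarnings(build_reference(c(0.9, 0.95, 0.92, 0.93),
                                          c(0.2, 0.3, 0.25, 0.28)))
  expect_identical(classify_score(0.92, ref)$label, "supports_identification")
  expect_identical(classify_score(0.26, ref)$label, "supports_exclusion")
  expect_identical(classify_score(0.6, ref)$label, "inconclusive")
  expect_error(classify_score(1.2, ref), "lie in")

  # overlapping CIs never throw; membership in both is inconclusive
  overlap <- build_reference(c(0.4, 0.5, 0.45, 0.55), c(0.35, 0.5, 0.42, 0.52))
  v <- classify_score(0.45, overlap)
  expect_true(v$in_km_ci && v$in_knm_ci)
  expect_identical(v$label, "inconclusive")

  # monotonicity: a higher score never moves the verdict from
  # identification toward exclusion
  scores <- seq(-1, 1, by = 0.01)
  labels <- vapply(scores, function(s) classify_score(s, ref)$label,
                   character(1))
  id_at <- which(labels == "supports_identification")
  ex_at <- which(labels == "supports_exclusion")
  if (length(id_at) && length(ex_at)) expect_lt(max(ex_at), min(id_at))
})
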