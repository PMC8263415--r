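#' Build KM/KNM reference score distributions
#'
#' Summarises known-match and known-non-match similarity scores into the
#' reference used to classify a questioned comparison: per-group mean, SD and
#' a two-sided 95% confidence interval for the mean, by Student-t (default),
#' normal, or bootstrap construction. A `fisher_z` option performs the CI
#' arithmetic on `atanh(score)` and back-transforms, which respects the
#' `[-1, 1]` boundary for scores near 1. A zero-variance sample yields a point
#' CI with a warning.
#'
#' @param km_scores,knm_scores Numeric score samples in `[-1, 1]`, each of
#'   length >= 2.
#' @param ci_method `"t"`, `"normal"`, or `"bootstrap"`.
#' @param interval Interval scope: `"scores"` (default) covers where
#'   individual scores of the group are expected to fall (a t prediction
#'   interval, `mean +/- t * sd * sqrt(1 + 1/n)`; empirical quantiles under
#'   the bootstrap), which is the scope the classification rule needs —
#'   whether a questioned score is consistent with the known-match scores;
#'   `"mean"` is the classical confidence interval for the group mean
#'   (`mean +/- t * sd / sqrt(n)`), which shrinks with n and describes the
#'   mean's precision, not the score spread.
#' @param conf Confidence level; default 0.95.
#' @param fisher_z Construct the CI on the Fisher-z scale; default `FALSE`.
#' @param boot_reps Bootstrap replicates; default 2000.
#' @param seed Seed for the bootstrap (required for `ci_method =
#'   "bootstrap"`).
#' @return A `ref_distributions` object with fields `km_scores`,
#'   `knm_scores`, `km_mean`, `km_sd`, `km_ci`, `knm_mean`, `knm_sd`,
#'   `knm_ci`, `n_km`, `n_knm`, `ci_method`.
#' @export
build_reference <- function(km_scores, knm_scores,
                            ci_method = c("t", "normal", "bootstrap"),
                            interval = c("scores", "mean"),
                            conf = 0.95, fisher_z = FALSE,
                            boot_reps = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  interval <- match.arg(interval)
  km_scores <- as.numeric(km_scores)
  knm_scores <- as.numeric(knm_scores)
  if (length(km_scores) < 2 || length(knm_scores) < 2) {
    stop("need >= 2 scores in each group for CI construction", call. = FALSE)
  }
  if (any(abs(c(km_scores, knm_scores)) > 1 + 1e-9)) {
    stop("scores must lie in [-1, 1]", call. = FALSE)
  }
  if (ci_method == "bootstrap" && is.null(seed)) {
    stop("bootstrap CI requires a seed", call. = FALSE)
  }
  structure(
    list(
      km_scores = km_scores, knm_scores = knm_scores,
      km_mean = mean(km_scores), km_sd = sd(km_scores),
      knm_mean = mean(knm_scores), knm_sd = sd(knm_scores),
      km_ci = group_ci(km_scores, ci_method, interval, conf, fisher_z,
                       boot_reps,
                       if (is.null(seed)) NULL else child_seed(seed, 1)),
      knm_ci = group_ci(knm_scores, ci_method, interval, conf, fisher_z,
                        boot_reps,
                        if (is.null(seed)) NULL else child_seed(seed, 2)),
      n_km = length(km_scores), n_knm = length(knm_scores),
      conf = conf,
      ci_method = ci_method,
      interval = interval,
      fisher_z = fisher_z
    ),
    class = "ref_distributions"
  )
}

group_ci <- function(x, method, interval, conf, fisher_z, boot_reps, seed) {
  n <- length(x)
  if (sd(x) == 0) {
    warning("zero-variance score sample: point confidence interval",
            call. = FALSE)
    return(c(x[1], x[1]))
  }
  tf <- if (fisher_z) function(v) atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))
        else identity
  bt <- if (fisher_z) tanh else identity
  z <- tf(x)
  alpha <- 1 - conf
  # scale factor: precision of the mean, or spread of a new single score
  sf <- if (interval == "mean") 1 / sqrt(n) else sqrt(1 + 1 / n)
  ci <- switch(method,
    t = mean(z) + c(-1, 1) * qt(1 - alpha / 2, n - 1) * sd(z) * sf,
    normal = mean(z) + c(-1, 1) * qnorm(1 - alpha / 2) * sd(z) * sf,
    bootstrap = {
      if (interval == "mean") {
        means <- with_seed(seed, {
          vapply(seq_len(boot_reps),
                 function(i) mean(z[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
        })
        unname(quantile(means, c(alpha / 2, 1 - alpha / 2), type = 7))
      } else {
        unname(quantile(z, c(alpha / 2, 1 - alpha / 2), type = 7))
      }
    }
  )
  bt(ci)
}

#' @export
print.ref_distributions <- function(x, ...) {
  cat(sprintf(
    "<ref_distributions> (%s %s-interval, %.0f%%)\n  KM : n = %d, mean %.4f, sd %.4f, CI [%.4f, %.4f]\n  KNM: n = %d, mean %.4f, sd %.4f, CI [%.4f, %.4f]\n",
    x$ci_method, x$interval %||% "mean", 100 * x$conf,
    x$n_km, x$km_mean, x$km_sd, x$km_ci[1], x$km_ci[2],
    x$n_knm, x$knm_mean, x$knm_sd, x$knm_ci[1], x$knm_ci[2]
  ))
  invisible(x)
}

#' @export
#' @rdname build_reference
#' @param x A `ref_distributions`.
#' @param ... Unused.
tidy.ref_distributions <- function(x, ...) {
  tibble::tibble(
    group = c("KM", "KNM"),
    n = c(x$n_km, x$n_knm),
    mean = c(x$km_mean, x$knm_mean),
    sd = c(x$km_sd, x$knm_sd),
    ci_lower = c(x$km_ci[1], x$knm_ci[1]),
    ci_upper = c(x$km_ci[2], x$knm_ci[2])
  )
}

#' @export
#' @rdname build_reference
glance.ref_distributions <- function(x, ...) {
  tibble::tibble(
    km_mean = x$km_mean, knm_mean = x$knm_mean,
    separation = x$km_mean - x$knm_mean,
    ci_disjoint = x$km_ci[1] > x$knm_ci[2] || x$knm_ci[1] > x$km_ci[2],
    n_km = x$n_km, n_knm = x$n_knm,
    ci_method = x$ci_method,
    interval = x$interval
  )
}

#' Classify a similarity score against a KM/KNM reference
#'
#' The confidence-interval decision rule: a score inside the known-match CI
#' only supports identification, inside the known-non-match CI only supports
#' exclusion, and anything else (neither, or both when the CIs overlap) is
#' inconclusive. The rule never throws on overlapping CIs.
#'
#' @param score Similarity score in `[-1, 1]`.
#' @param ref A [build_reference()] object.
#' @return A one-row tibble of class `match_verdict`: `score`, `in_km_ci`,
#'   `in_knm_ci`, `label` (`"supports_identification"`,
#'   `"supports_exclusion"`, `"inconclusive"`), `reference`.
#' @export
classify_score <- function(score, ref) {
  stopifnot(inherits(ref, "ref_distributions"))
  if (!is.numeric(score) || abs(score) > 1 + 1e-9) {
    stop("score must lie in [-1, 1]", call. = FALSE)
  }
  in_km <- score >= ref$km_ci[1] && score <= ref$km_ci[2]
  in_knm <- score >= ref$knm_ci[1] && score <= ref$knm_ci[2]
  label <- if (in_km && !in_knm) "supports_identification"
           else if (in_knm && !in_km) "supports_exclusion"
           else "inconclusive"
  out <- tibble::tibble(
    score = score,
    in_km_ci = in_km,
    in_knm_ci = in_knm,
    label = label,
    reference = sprintf("%s-CI(%0.2f) KM n=%d / KNM n=%d",
                        ref$ci_method, ref$conf, ref$n_km, ref$n_knm)
  )
  class(out) <- c("match_verdict", class(out))
  out
}
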