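#' Pre-process a mark surface into a comparison-ready signature set
#'
#' The default chain mirrors standard practice for striated-mark data:
#' local-sigma outlier flagging, nearest-neighbour substitution of invalid
#' points, orientation correction (estimated when not supplied), extraction of
#' the `n` least-disturbed cross-sections, moving-average detrending and
#' zero-phase low-pass noise reduction. A band-pass variant replaces the
#' detrend + low-pass pair.
#'
#' @param grid A [surface_grid].
#' @param angle Striation angle (degrees); `NULL` (default) estimates it with
#'   [estimate_striation_orientation()]. A supplied value always wins.
#' @param n Number of signatures; default 5.
#' @param window Detrend window (samples); default 301.
#' @param cutoff Low-pass cutoff (cycles/um); default 1/15.
#' @param filter `"detrend_lowpass"` (default), `"gaussian"` or
#'   `"chebyshev2"` (band-pass variants, using `band`).
#' @param band Length-2 band (cycles/um) for the band-pass variants; default
#'   `c(1/300, 1/15)`.
#' @param sigma_k,sigma_window Local-sigma outlier parameters; defaults 6, 7.
#' @param nn Neighbour count for invalid-point substitution; default 10.
#' @return A [signature_set()] of detrended/filtered signatures; attribute
#'   `"angle_used"` records the correction applied.
#' @export
preprocess_mark <- function(grid, angle = NULL, n = 5, window = 301,
                            cutoff = 1 / 15,
                            filter = c("detrend_lowpass", "gaussian",
                                       "chebyshev2"),
                            band = c(1 / 300, 1 / 15),
                            sigma_k = 6, sigma_window = 7, nn = 10) {
  filter <- match.arg(filter)
  g <- remove_outliers(grid, "local_sigma", k = sigma_k,
                       window = sigma_window)
  g <- remove_outliers(g, "nn_substitute", neighbors = nn)
  if (is.null(angle)) {
    angle <- estimate_striation_orientation(g)$angle_deg
  }
  set <- extract_signatures(g, angle = angle, n = n, trial_window = window)
  sigs <- lapply(set$signatures, function(s) {
    if (filter == "detrend_lowpass") {
      lowpass_signature(detrend_signature(s, window = window),
                        cutoff = cutoff)
    } else {
      bandpass_signature(s, kind = filter, low = band[1], high = band[2])
    }
  })
  out <- signature_set(sigs, set$mark_id, set$extraction_lines,
                       set$disturbance_scores)
  attr(out, "angle_used") <- angle
  out
}

#' Run a known-match / known-non-match reference experiment
#'
#' Pre-processes every mark in the dataset, compares every manifest pair with
#' [compare_marks()], tabulates the scores with their KM/KNM labels, and
#' builds the reference distributions. With the classic 4-blade x 2-mark
#' design this performs exactly 28 comparisons (4 KM + 24 KNM). A pair whose
#' comparison fails is recorded as failed and excluded from the reference.
#'
#' @param grids Named list of [surface_grid] objects (e.g. from
#'   [make_km_knm_dataset()]).
#' @param manifest Tibble with `pair_id`, `mark_a`, `mark_b`, `label`
#'   (`"KM"`/`"KNM"`).
#' @param ... Pre-processing options passed to [preprocess_mark()].
#' @param allow_reverse,max_lag,min_overlap Comparison options for
#'   [compare_marks()].
#' @param cms Also count consecutive matching striae per pair; default `TRUE`.
#' @param ci_method,interval,conf,seed Reference construction options for
#'   [build_reference()].
#' @return A list of class `km_knm_experiment`: `scores` (tibble: `pair_id`,
#'   `mark_a`, `mark_b`, `label`, `score`, `best_lag`, `reversed`,
#'   `overlap`, `cms_max_run`, `failed`), `reference`
#'   ([build_reference()]), and `sets` (the per-mark signature sets).
#' @export
km_knm_experiment <- function(grids, manifest, ...,
                              allow_reverse = TRUE, max_lag = NULL,
                              min_overlap = 0.5, cms = TRUE,
                              ci_method = "t", interval = "scores",
                              conf = 0.95, seed = NULL) {
  stopifnot(is.list(grids),
            all(c("pair_id", "mark_a", "mark_b", "label") %in% names(manifest)))
  marks <- unique(c(manifest$mark_a, manifest$mark_b))
  missing <- setdiff(marks, names(grids))
  if (length(missing)) {
    stop("manifest references unknown marks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(grids[marks], function(g) preprocess_mark(g, ...))

  rows <- purrr::pmap(manifest, function(pair_id, mark_a, mark_b, label, ...) {
    res <- tryCatch(
      compare_marks(sets[[mark_a]], sets[[mark_b]],
                    allow_reverse = allow_reverse, max_lag = max_lag,
                    min_overlap = min_overlap),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(
        pair_id = pair_id, mark_a = mark_a, mark_b = mark_b, label = label,
        score = NA_real_, best_lag = NA_integer_, reversed = NA,
        overlap = NA_integer_, cms_max_run = NA_integer_, failed = TRUE,
        failure = conditionMessage(res)
      ))
    }
    run <- if (cms) {
      cr <- tryCatch(
        count_cms(res$avg_a, res$avg_b, aligned_lag = res$best_lag),
        error = function(e) NULL
      )
      if (is.null(cr)) NA_integer_ else cr$max_run
    } else {
      NA_integer_
    }
    tibble::tibble(
      pair_id = pair_id, mark_a = mark_a, mark_b = mark_b, label = label,
      score = res$score, best_lag = as.integer(res$best_lag),
      reversed = isTRUE(res$reversed),
      overlap = as.integer(res$overlap_at_best),
      cms_max_run = run, failed = FALSE, failure = NA_character_
    )
  })
  scores <- dplyr::bind_rows(rows)
  if (any(scores$failed)) {
    warning(sum(scores$failed), " pair(s) failed comparison and were excluded",
            call. = FALSE)
  }
  oks <- dplyr::filter(scores, !.data$failed)
  ref <- build_reference(
    oks$score[oks$label == "KM"], oks$score[oks$label == "KNM"],
    ci_method = ci_method, interval = interval, conf = conf, seed = seed
  )
  structure(
    list(scores = scores, reference = ref, sets = sets),
    class = "km_knm_experiment"
  )
}

#' @export
print.km_knm_experiment <- function(x, ...) {
  cat(sprintf(
    "<km_knm_experiment> %d comparisons (%d KM, %d KNM, %d failed)\n",
    nrow(x$scores), sum(x$scores$label == "KM"), sum(x$scores$label == "KNM"),
    sum(x$scores$failed)
  ))
  print(x$reference)
  invisible(x)
}

#' @export
#' @rdname km_knm_experiment
#' @param x A `km_knm_experiment`.
#' @param ... Unused.
tidy.km_knm_experiment <- function(x, ...) x$scores

#' @export
#' @rdname km_knm_experiment
glance.km_knm_experiment <- function(x, ...) glance(x$reference)
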