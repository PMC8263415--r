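#' Extract cross-section signatures from a mark
#'
#' After orientation correction every grid row is a cross-section
#' perpendicular to the striae. This picks the `n` least-disturbed rows —
#' scored by residual variance after a trial moving-average detrend plus the
#' invalid fraction of the adjacent rows — subject to a minimum mutual spacing
#' so the profiles are not near-duplicates. Rows whose maximal contiguous
#' valid run is too short are inadmissible, so no extracted profile ever
#' crosses an invalid pixel; the selected rows are then cropped to their
#' common fully-valid column window. Ties in score go to the smallest row
#' index.
#'
#' @param grid A [surface_grid].
#' @param angle Striation angle (degrees) to correct before extraction, e.g.
#'   from [estimate_striation_orientation()]; 0 skips resampling.
#' @param n Number of signatures to extract; default 5.
#' @param min_spacing Minimum row spacing between chosen lines; default 10.
#' @param trial_window Odd moving-average window for the disturbance score;
#'   default 301, clipped to the available run length.
#' @param min_run_frac Minimum admissible valid-run length as a fraction of
#'   the grid width; default 0.5.
#' @return A [signature_set()] of `n` raw signatures with 0-based
#'   `extraction_lines` and `disturbance_scores`.
#' @export
extract_signatures <- function(grid, angle = 0, n = 5, min_spacing = 10,
                               trial_window = 301, min_run_frac = 0.5) {
  stopifnot(inherits(grid, "surface_grid"), n >= 1)
  g <- rotate_grid(grid, angle)
  h <- g$heights
  ok <- g$valid_mask
  ny <- nrow(h); nx <- ncol(h)
  min_len <- max(16, floor(min_run_frac * nx))

  runs <- lapply(seq_len(ny), function(r) longest_true_run(ok[r, ]))
  inv_frac <- 1 - rowMeans(ok)
  score <- rep(Inf, ny)
  for (r in seq_len(ny)) {
    rn <- runs[[r]]
    if (rn$len < min_len) next
    vals <- h[r, rn$start:rn$end]
    w <- min(trial_window, rn$len)
    if (w %% 2 == 0) w <- w - 1
    resid <- vals - moving_average(vals, max(3, w))
    adj <- inv_frac[intersect(c(r - 1, r + 1), seq_len(ny))]
    score[r] <- stats::var(resid) + mean(adj)
  }

  ord <- order(score, seq_len(ny))
  picked <- integer(0)
  for (r in ord) {
    if (!is.finite(score[r])) break
    if (all(abs(r - picked) >= min_spacing)) picked <- c(picked, r)
    if (length(picked) == n) break
  }
  if (length(picked) < n) {
    stop(sprintf("only %d admissible extraction lines (need %d)",
                 length(picked), n), call. = FALSE)
  }
  picked <- sort(picked)
  c1 <- max(vapply(runs[picked], function(x) x$start, numeric(1)))
  c2 <- min(vapply(runs[picked], function(x) x$end, numeric(1)))
  if (c2 - c1 + 1 < min_len) {
    stop("selected lines share too narrow a valid column window", call. = FALSE)
  }
  mark_id <- g$meta$mark_id %||% "mark"
  sigs <- lapply(picked, function(r) {
    new_signature(
      h[r, c1:c2], step = g$pitch_x,
      origin = sprintf("%s:row%d", mark_id, r - 1),
      processing_state = "raw"
    )
  })
  signature_set(sigs, mark_id,
                extraction_lines = picked - 1L,
                disturbance_scores = score[picked])
}

longest_true_run <- function(v) {
  r <- rle(v)
  if (!any(r$values)) return(list(start = 0, end = -1, len = 0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  list(start = starts[i], end = ends[i], len = r$lengths[i])
}

#' Mark signature by averaging along the striae
#'
#' The averaging alternative to line extraction: after orientation correction
#' every column of the grid is averaged over its valid pixels, collapsing the
#' whole data set into a single profile. Columns with no valid pixel are
#' filled by linear interpolation from their neighbours.
#'
#' @param grid A [surface_grid].
#' @param angle Striation angle (degrees) to correct first; 0 skips
#'   resampling.
#' @return A raw [new_signature()] with step `pitch_x`.
#' @export
mean_profile_along_striations <- function(grid, angle = 0) {
  stopifnot(inherits(grid, "surface_grid"))
  g <- rotate_grid(grid, angle)
  h <- g$heights
  ok <- g$valid_mask
  cnt <- colSums(ok)
  if (all(cnt == 0)) stop("all-invalid grid", call. = FALSE)
  hz <- h; hz[!ok] <- 0
  prof <- colSums(hz) / pmax(cnt, 1)
  empty <- cnt == 0
  if (any(empty)) {
    idx <- seq_along(prof)
    prof[empty] <- stats::approx(idx[!empty], prof[!empty], xout = idx[empty],
                                 rule = 2)$y
  }
  new_signature(
    prof, step = g$pitch_x,
    origin = sprintf("%s:colmean", g$meta$mark_id %||% "mark"),
    processing_state = "raw"
  )
}
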