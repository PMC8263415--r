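#' Normalized cross-correlation of two signatures
#'
#' The similarity statistic at the core of computational striated-mark
#' comparison: for each integer lag `k`,
#' \deqn{xcorr\{k\} = \frac{\sum_i S_1[i]\, S_2[i+k]}
#'   {\sqrt{\sum_i S_1[i]^2 \cdot \sum_i S_2[i+k]^2}}}
#' with all three sums taken over the overlapping index range at that lag (the
#' denominator's \eqn{S_2} sum over the same shifted window as the numerator),
#' so every value lies in `[-1, 1]` by Cauchy-Schwarz. Lags whose overlap
#' falls below `min_overlap * min(N1, N2)` samples are excluded; a zero-energy
#' overlap (an all-zero segment) is excluded with a warning. The best lag
#' maximises the statistic, ties resolved to the smallest `|k|` and then to
#' the negative lag. Cross-products are computed by FFT, window energies by
#' cumulative sums.
#'
#' Signatures must already be mean-free (detrended or filtered); no additional
#' mean subtraction is applied inside the statistic. The optional
#' `pearson_window` variant instead centres each overlap window on its own
#' mean (a per-window Pearson correlation).
#'
#' @param s1,s2 Detrended or filtered [new_signature()] objects with equal
#'   step. A positive best lag means `s2` is delayed relative to `s1`.
#' @param max_lag Largest absolute lag searched (samples); default a quarter
#'   of the shorter signature. Must be below `min(N1, N2)`.
#' @param min_overlap Minimum admissible overlap as a fraction in `(0, 1]` of
#'   the shorter signature; default 0.5.
#' @param pearson_window If `TRUE`, centre each overlap window on its mean.
#' @return A `correlation_result`: `lags`, `xcorr` (NA where excluded),
#'   `best_lag`, `score`, `overlap_at_best`, `reversed`.
#' @export
normalized_xcorr <- function(s1, s2, max_lag = NULL, min_overlap = 0.5,
                             pearson_window = FALSE) {
  stopifnot(inherits(s1, "signature"), inherits(s2, "signature"))
  if (!is_detrended(s1) || !is_detrended(s2)) {
    stop("signatures must be detrended (or filtered) before correlation",
         call. = FALSE)
  }
  if (abs(s1$step - s2$step) > 1e-9) {
    stop("signatures must share the same step", call. = FALSE)
  }
  if (!(min_overlap > 0 && min_overlap <= 1)) {
    stop("min_overlap must lie in (0, 1]", call. = FALSE)
  }
  a <- s1$values; b <- s2$values
  n1 <- length(a); n2 <- length(b)
  nmin <- min(n1, n2)
  if (is.null(max_lag)) max_lag <- floor(nmin / 4)
  if (max_lag >= nmin) stop("max_lag must be < min(N1, N2)", call. = FALSE)
  max_lag <- as.integer(max_lag)

  lags <- seq.int(-max_lag, max_lag)
  lo <- pmax(1, 1 - lags)
  hi <- pmin(n1, n2 - lags)
  m <- hi - lo + 1
  admissible <- m >= ceiling(min_overlap * nmin)

  cross <- fft_crosscorr(a, b, max_lag)
  ca1 <- c(0, cumsum(a)); ca2 <- c(0, cumsum(a^2))
  cb1 <- c(0, cumsum(b)); cb2 <- c(0, cumsum(b^2))
  e1 <- ca2[hi + 1] - ca2[lo]
  e2 <- cb2[hi + lags + 1] - cb2[lo + lags]

  if (pearson_window) {
    mu1 <- (ca1[hi + 1] - ca1[lo]) / m
    mu2 <- (cb1[hi + lags + 1] - cb1[lo + lags]) / m
    cross <- cross - m * mu1 * mu2
    e1 <- e1 - m * mu1^2
    e2 <- e2 - m * mu2^2
  }

  den <- sqrt(pmax(e1, 0) * pmax(e2, 0))
  zero_energy <- admissible & den <= 0
  if (any(zero_energy)) {
    warning(sum(zero_energy),
            " lag(s) excluded: zero-energy overlap window", call. = FALSE)
  }
  xc <- ifelse(admissible & den > 0, cross / den, NA_real_)
  if (!any(!is.na(xc))) stop("no admissible lag", call. = FALSE)

  # ties (to within floating-point noise) resolve to the smallest |k|,
  # then to the negative lag
  top <- max(xc, na.rm = TRUE)
  cand <- which(!is.na(xc) & xc >= top - 1e-12)
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  structure(
    list(
      lags = lags,
      xcorr = xc,
      best_lag = as.integer(lags[best]),
      score = xc[best],
      overlap_at_best = m[best],
      reversed = FALSE,
      n1 = n1, n2 = n2,
      step = s1$step,
      min_overlap = min_overlap
    ),
    class = "correlation_result"
  )
}

# linear cross-correlation sums c[k] = sum_i a[i] * b[i + k], |k| <= max_lag
fft_crosscorr <- function(a, b, max_lag) {
  n1 <- length(a); n2 <- length(b)
  L <- stats::nextn(n1 + n2, 2)
  fa <- fft(c(a, numeric(L - n1)))
  fb <- fft(c(b, numeric(L - n2)))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / L
  k <- seq.int(-max_lag, max_lag)
  cc[ifelse(k >= 0, k + 1, L + k + 1)]
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> score %.4f at lag %d (%d-sample overlap)%s\n",
    x$score, x$best_lag, x$overlap_at_best,
    if (isTRUE(x$reversed)) ", second signature reversed" else ""
  ))
  invisible(x)
}

#' @export
#' @rdname normalized_xcorr
#' @param x A `correlation_result`.
#' @param ... Unused.
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(lag = x$lags, xcorr = x$xcorr)
}

#' @export
#' @rdname normalized_xcorr
glance.correlation_result <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    best_lag = x$best_lag,
    overlap_at_best = x$overlap_at_best,
    reversed = isTRUE(x$reversed),
    n1 = x$n1,
    n2 = x$n2
  )
}

#' Align a signature set by cross-correlation and average it
#'
#' Each signature is shifted by its best lag against the anchor (the first
#' signature by default, or the highest-energy one), and the pointwise mean is
#' taken over every position covered by at least half of the signatures
#' (`ceiling(n/2)`). Averaging suppresses disturbances that differ between
#' extraction lines while preserving the shared striae profile. A
#' single-signature set is returned unchanged.
#'
#' @param set A [signature_set()]; all members share step and processing
#'   state.
#' @param anchor `"first"` or `"max_energy"`.
#' @param max_lag,min_overlap Passed to [normalized_xcorr()] for the pairwise
#'   alignments.
#' @return A `signature` (the aligned average); attribute `"shifts"` records
#'   the per-signature lags relative to the anchor.
#' @export
align_and_average <- function(set, anchor = c("first", "max_energy"),
                              max_lag = NULL, min_overlap = 0.5) {
  stopifnot(inherits(set, "signature_set"))
  anchor <- match.arg(anchor)
  sigs <- set$signatures
  n <- length(sigs)
  if (n == 1) {
    out <- sigs[[1]]
    attr(out, "shifts") <- 0L
    return(out)
  }
  ai <- if (anchor == "first") 1L else {
    which.max(vapply(sigs, function(s) sum(s$values^2), numeric(1)))
  }
  ref <- sigs[[ai]]
  shifts <- vapply(seq_len(n), function(i) {
    if (i == ai) return(0L)
    r <- normalized_xcorr(ref, sigs[[i]], max_lag = max_lag,
                          min_overlap = min_overlap)
    as.integer(r$best_lag)
  }, integer(1))

  # member i sample j sits at anchor coordinate j - shift_i
  starts <- 1L - shifts
  ends <- vapply(sigs, function(s) length(s$values), integer(1)) - shifts
  c0 <- min(starts); c1 <- max(ends)
  len <- c1 - c0 + 1
  acc <- numeric(len)
  cnt <- integer(len)
  for (i in seq_len(n)) {
    pos <- (starts[i]:ends[i]) - c0 + 1
    acc[pos] <- acc[pos] + sigs[[i]]$values
    cnt[pos] <- cnt[pos] + 1L
  }
  keep <- cnt >= ceiling(n / 2)
  vals <- acc[keep] / cnt[keep]
  support <- range((c0:c1)[keep]) # anchor-sample coordinates of the average
  out <- new_signature(
    vals, ref$step,
    origin = sprintf("%s:avg%d", set$mark_id, n),
    processing_state = ref$processing_state,
    processing = c(ref$processing, list(n_averaged = n))
  )
  attr(out, "shifts") <- shifts
  attr(out, "support") <- support
  out
}

#' Compare two marks by their averaged signatures
#'
#' The end of the comparison chain: each mark's signature set is aligned and
#' averaged, and the two averages are scored by [normalized_xcorr()]. Because
#' casts of opposite blade sides mirror the profile, the second mark is by
#' default also evaluated reversed and the better of the two orientations is
#' returned with `reversed` flagged. Sets pre-processed with different chains
#' (different detrend window, cutoff, or filter kind) are refused.
#'
#' @param a,b [signature_set()] objects, identically pre-processed.
#' @param allow_reverse Also try `b` reversed; default `TRUE`.
#' @param max_lag,min_overlap,pearson_window Passed to [normalized_xcorr()].
#' @return A `correlation_result` with additional fields `mark_a`, `mark_b`,
#'   and the averaged signatures `avg_a`, `avg_b` (as compared, i.e. reversed
#'   if `reversed` is `TRUE`).
#' @export
compare_marks <- function(a, b, allow_reverse = TRUE, max_lag = NULL,
                          min_overlap = 0.5, pearson_window = FALSE) {
  stopifnot(inherits(a, "signature_set"), inherits(b, "signature_set"))
  if (!identical(set_processing_tag(a), set_processing_tag(b))) {
    stop("signature sets were pre-processed differently; refusing to compare",
         call. = FALSE)
  }
  avg_a <- align_and_average(a, max_lag = max_lag, min_overlap = min_overlap)
  avg_b <- align_and_average(b, max_lag = max_lag, min_overlap = min_overlap)
  fwd <- normalized_xcorr(avg_a, avg_b, max_lag = max_lag,
                          min_overlap = min_overlap,
                          pearson_window = pearson_window)
  res <- fwd
  used_b <- avg_b
  if (allow_reverse) {
    rev_b <- new_signature(rev(avg_b$values), avg_b$step,
                           origin = paste0(avg_b$origin, ":rev"),
                           processing_state = avg_b$processing_state,
                           processing = avg_b$processing)
    bwd <- normalized_xcorr(avg_a, rev_b, max_lag = max_lag,
                            min_overlap = min_overlap,
                            pearson_window = pearson_window)
    if (bwd$score > fwd$score) {
      res <- bwd
      res$reversed <- TRUE
      used_b <- rev_b
    }
  }
  res$mark_a <- a$mark_id
  res$mark_b <- b$mark_id
  res$avg_a <- avg_a
  res$avg_b <- used_b
  res
}
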