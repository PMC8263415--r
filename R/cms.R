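#' Detect striae in a signature
#'
#' Striae are taken as local maxima of the detrended profile whose topographic
#' prominence (height above the higher of the two saddles separating the peak
#' from taller terrain) exceeds a threshold. Prominence, rather than raw
#' height, is what makes a groove edge count as a stria on a profile that
#' still carries gentle residual waviness.
#'
#' @param sig A [new_signature()].
#' @param prominence Minimum prominence (um); default `0.5 * sd(values)`.
#' @return Tibble with `index` (1-based sample), `position_um`, `height_um`,
#'   `prominence_um`.
#' @export
find_striae <- function(sig, prominence = NULL) {
  stopifnot(inherits(sig, "signature"))
  v <- sig$values
  if (is.null(prominence)) prominence <- 0.5 * sd(v)
  n <- length(v)
  is_peak <- which(diff(sign(diff(v))) < 0) + 1
  if (length(is_peak) == 0) {
    return(tibble::tibble(index = integer(0), position_um = numeric(0),
                          height_um = numeric(0), prominence_um = numeric(0)))
  }
  prom <- vapply(is_peak, function(p) peak_prominence(v, p), numeric(1))
  keep <- prom >= prominence
  tibble::tibble(
    index = is_peak[keep],
    position_um = (is_peak[keep] - 1) * sig$step,
    height_um = v[is_peak[keep]],
    prominence_um = prom[keep]
  )
}

# standard topographic prominence: on each side, walk to the first strictly
# higher sample (or the end) and record the minimum on the way; the reference
# level is the higher of the two minima
peak_prominence <- function(v, p) {
  h <- v[p]
  left <- v[seq_len(p - 1)]
  right <- if (p < length(v)) v[(p + 1):length(v)] else numeric(0)
  higher_l <- which(left > h)
  min_l <- if (length(higher_l)) min(left[(max(higher_l)):(p - 1)]) else
    if (length(left)) min(left) else h
  higher_r <- which(right > h)
  min_r <- if (length(higher_r)) min(right[1:(min(higher_r))]) else
    if (length(right)) min(right) else h
  h - max(min_l, min_r)
}

#' Count consecutive matching striae (CMS)
#'
#' Biasotti-style counting on two aligned signatures: striae are detected in
#' each profile, the lag from a prior cross-correlation alignment is applied
#' to the second profile's positions, and striae are paired greedily in
#' positional order when they fall within `tol` of each other. The headline
#' statistic `max_run` is defined directly as the longest `L` such that `L`
#' consecutive striae of one profile each lie within `tol` of `L` consecutive
#' striae of the other (computed by dynamic programming over the tolerance
#' matrix) — runs are therefore not hostage to an unlucky early greedy pairing.
#'
#' @param s1,s2 Detrended/filtered [new_signature()] objects, same step.
#' @param aligned_lag Integer lag (samples) aligning `s2` to `s1`, typically
#'   `best_lag` from [normalized_xcorr()]; a stria at `s2` sample `j` is
#'   placed at position `(j - 1 - aligned_lag) * step`.
#' @param prominence Minimum stria prominence (um); default
#'   `0.5 * sd` of each signature.
#' @param tol Matching tolerance (um); default 2 samples (`2 * step`).
#' @return A `cms_result`: `striae_a`, `striae_b` (position tibbles),
#'   `matches` (tibble of paired indices), `runs` (all run lengths in the
#'   greedy matching), `max_run`.
#' @export
count_cms <- function(s1, s2, aligned_lag = 0, prominence = NULL, tol = NULL) {
  stopifnot(inherits(s1, "signature"), inherits(s2, "signature"))
  if (abs(s1$step - s2$step) > 1e-9) {
    stop("signatures must share the same step", call. = FALSE)
  }
  if (is.null(tol)) tol <- 2 * s1$step
  pa <- find_striae(s1, prominence)
  pb <- find_striae(s2, prominence)
  if (nrow(pa) == 0 && nrow(pb) == 0) {
    stop("no striae detected in either signature", call. = FALSE)
  }
  pos_a <- pa$position_um
  pos_b <- pb$position_um - aligned_lag * s2$step

  matches <- greedy_order_match(pos_a, pos_b, tol)
  max_dp <- cms_max_run(pos_a, pos_b, tol)
  runs <- match_runs(matches)
  structure(
    list(
      striae_a = pa, striae_b = pb,
      positions_b_aligned = pos_b,
      matches = matches,
      runs = runs,
      max_run = max_dp,
      tol = tol,
      aligned_lag = aligned_lag
    ),
    class = "cms_result"
  )
}

# one-to-one, order-preserving greedy pairing by two advancing pointers
greedy_order_match <- function(pos_a, pos_b, tol) {
  i <- 1L; j <- 1L
  ia <- integer(0); ib <- integer(0)
  while (i <= length(pos_a) && j <= length(pos_b)) {
    d <- pos_a[i] - pos_b[j]
    if (abs(d) <= tol) {
      ia <- c(ia, i); ib <- c(ib, j)
      i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(
    index_a = ia, index_b = ib,
    position_a = pos_a[ia], position_b = pos_b[ib]
  )
}

# longest L with |pos_a[i+t] - pos_b[j+t]| <= tol for t = 0..L-1
cms_max_run <- function(pos_a, pos_b, tol) {
  na <- length(pos_a); nb <- length(pos_b)
  if (na == 0 || nb == 0) return(0L)
  M <- abs(outer(pos_a, pos_b, `-`)) <= tol
  R <- matrix(0L, na, nb)
  best <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (M[i, j]) {
        R[i, j] <- 1L + if (i > 1 && j > 1) R[i - 1, j - 1] else 0L
        if (R[i, j] > best) best <- R[i, j]
      }
    }
  }
  best
}

match_runs <- function(matches) {
  if (nrow(matches) == 0) return(integer(0))
  da <- diff(matches$index_a)
  db <- diff(matches$index_b)
  brk <- which(da != 1 | db != 1)
  lens <- diff(c(0, brk, nrow(matches)))
  as.integer(lens)
}

#' @export
print.cms_result <- function(x, ...) {
  cat(sprintf(
    "<cms_result> %d vs %d striae, %d matched, max consecutive run %d (tol %.3g um)\n",
    nrow(x$striae_a), nrow(x$striae_b), nrow(x$matches), x$max_run, x$tol
  ))
  invisible(x)
}

#' @export
#' @rdname count_cms
#' @param x A `cms_result`.
#' @param ... Unused.
glance.cms_result <- function(x, ...) {
  tibble::tibble(
    n_striae_a = nrow(x$striae_a),
    n_striae_b = nrow(x$striae_b),
    n_matched = nrow(x$matches),
    max_run = x$max_run,
    tol_um = x$tol
  )
}
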