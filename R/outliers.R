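#' Remove outlier pixels from a surface grid
#'
#' Implements the three classical pre-processing treatments for unreliable
#' surface-topography points:
#'
#' * `"slope_threshold"` — a pixel is flagged when the slope to *both* of its
#'   neighbours along an axis (x or y) exceeds `threshold` (um/um): isolated
#'   spikes trip both sides, their clean neighbours only one. Flagged pixels
#'   become invalid.
#' * `"local_sigma"` — a pixel is flagged when it deviates from the local mean
#'   (over a `window` x `window` neighbourhood of valid pixels) by more than
#'   `k` local standard deviations. Flagged pixels become invalid.
#' * `"nn_substitute"` — every *invalid* pixel (dropout or previously flagged)
#'   is replaced by the mean of its `neighbors` nearest valid pixels and marked
#'   valid again.
#'
#' All unflagged pixels are bit-identical to the input. The first two methods
#' are idempotent at fixed parameters (statistics are computed over valid
#' pixels only, and a removed spike cannot re-trip its neighbours).
#'
#' @param grid A [surface_grid].
#' @param method One of `"slope_threshold"`, `"local_sigma"`,
#'   `"nn_substitute"`.
#' @param threshold Slope threshold (um/um) for `"slope_threshold"`; default
#'   5x the larger of the two per-axis median absolute adjacent slopes (the
#'   along-striae axis of a striated surface has near-zero slopes and would
#'   otherwise collapse the scale).
#' @param k Deviation multiple for `"local_sigma"`; default 6.
#' @param window Odd neighbourhood size (pixels) for `"local_sigma"`;
#'   default 7, must be >= 3.
#' @param neighbors Number of nearest valid neighbours for
#'   `"nn_substitute"`; default 10, must be >= 1.
#' @return A [surface_grid]; `meta$outlier_flagged` records how many pixels
#'   changed validity.
#' @export
remove_outliers <- function(grid,
                            method = c("slope_threshold", "local_sigma",
                                       "nn_substitute"),
                            threshold = NULL, k = 6, window = 7,
                            neighbors = 10) {
  stopifnot(inherits(grid, "surface_grid"))
  method <- match.arg(method)
  out <- switch(method,
    slope_threshold = flag_slope(grid, threshold),
    local_sigma = flag_local_sigma(grid, k, window),
    nn_substitute = substitute_invalid(grid, neighbors)
  )
  out
}

flag_slope <- function(grid, threshold) {
  h <- grid$heights
  ok <- grid$valid_mask
  ny <- nrow(h); nx <- ncol(h)
  dx <- grid$pitch_x; dy <- grid$pitch_y
  hv <- h; hv[!ok] <- NA_real_

  if (is.null(threshold)) {
    # slope scale of the measured topography: on a striated surface the
    # along-striae slopes are near zero, so take the larger per-axis median
    sx <- abs(hv[, -1] - hv[, -nx]) / dx
    sy <- abs(hv[-1, ] - hv[-ny, ]) / dy
    threshold <- 5 * max(median(sx, na.rm = TRUE), median(sy, na.rm = TRUE))
  }
  pad_na <- function(m, side) {
    # NA-pad a gap-difference matrix back to full grid size
    if (side == "left") cbind(NA_real_, m)
    else if (side == "right") cbind(m, NA_real_)
    else if (side == "top") rbind(NA_real_, m)
    else rbind(m, NA_real_)
  }
  spikey <- function(d_in, d_out, pitch) {
    # a spike rises then falls: both slopes exceed the threshold with
    # opposite signs; a steep monotone stretch (same signs) is left alone
    out <- abs(d_in) / pitch > threshold & abs(d_out) / pitch > threshold &
      sign(d_in) != sign(d_out)
    out & !is.na(out)
  }
  gx <- hv[, -1, drop = FALSE] - hv[, -nx, drop = FALSE]
  gy <- hv[-1, , drop = FALSE] - hv[-ny, , drop = FALSE]
  flag <- spikey(pad_na(gx, "left"), pad_na(gx, "right"), dx) |
    spikey(pad_na(gy, "top"), pad_na(gy, "bottom"), dy)
  flag <- flag & ok
  apply_flags(grid, flag, "slope_threshold")
}

# summed-area local sums over a centered window with edge clipping
local_box_sum <- function(m, half) {
  ny <- nrow(m); nx <- ncol(m)
  sat <- apply(m, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  sat <- rbind(0, cbind(0, sat)) # (ny+1) x (nx+1), sat[i+1, j+1] = sum <= (i, j)
  r1 <- pmax(seq_len(ny) - half, 1); r2 <- pmin(seq_len(ny) + half, ny)
  c1 <- pmax(seq_len(nx) - half, 1); c2 <- pmin(seq_len(nx) + half, nx)
  R2 <- matrix(r2 + 1, ny, nx); R1 <- matrix(r1, ny, nx)
  C2 <- matrix(rep(c2 + 1, each = ny), ny, nx)
  C1 <- matrix(rep(c1, each = ny), ny, nx)
  ix <- function(r, c) (c - 1) * (ny + 1) + r
  sat[ix(R2, C2)] - sat[ix(R1, C2)] - sat[ix(R2, C1)] + sat[ix(R1, C1)]
}

flag_local_sigma <- function(grid, k, window) {
  if (window %% 2 != 1 || window < 3) {
    stop("local_sigma window must be odd and >= 3", call. = FALSE)
  }
  h <- grid$heights
  ok <- grid$valid_mask
  half <- (window - 1) / 2
  hz <- h; hz[!ok] <- 0
  n <- local_box_sum(ok * 1, half)
  s1 <- local_box_sum(hz, half)
  s2 <- local_box_sum(hz^2, half)
  mu <- s1 / pmax(n, 1)
  varr <- (s2 - s1^2 / pmax(n, 1)) / pmax(n - 1, 1)
  sdd <- sqrt(pmax(varr, 0))
  flag <- ok & n >= 5 & abs(h - mu) > k * sdd & sdd > 0
  flag[is.na(flag)] <- FALSE
  apply_flags(grid, flag, "local_sigma")
}

apply_flags <- function(grid, flag, method) {
  h <- grid$heights
  mask <- grid$valid_mask
  h[flag] <- NA_real_
  mask[flag] <- FALSE
  meta <- grid$meta
  meta$outlier_flagged <- sum(flag)
  meta$outlier_method <- method
  surface_grid(h, grid$pitch_x, grid$pitch_y, valid_mask = mask, meta = meta)
}

substitute_invalid <- function(grid, neighbors) {
  if (neighbors < 1) stop("neighbor count must be >= 1", call. = FALSE)
  h <- grid$heights
  ok <- grid$valid_mask
  ny <- nrow(h); nx <- ncol(h)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) == 0) return(grid)
  dxs <- grid$pitch_x; dys <- grid$pitch_y
  for (b in seq_len(nrow(bad))) {
    r0 <- bad[b, 1]; c0 <- bad[b, 2]
    # expand square rings until enough valid neighbours, then keep k nearest
    rad <- 1
    repeat {
      rr <- max(1, r0 - rad):min(ny, r0 + rad)
      cc <- max(1, c0 - rad):min(nx, c0 + rad)
      sub_ok <- ok[rr, cc, drop = FALSE]
      if (sum(sub_ok) >= neighbors || (length(rr) == ny && length(cc) == nx)) {
        idx <- which(sub_ok, arr.ind = TRUE)
        if (nrow(idx) == 0) break
        d2 <- ((rr[idx[, 1]] - r0) * dys)^2 + ((cc[idx[, 2]] - c0) * dxs)^2
        keep <- order(d2)[seq_len(min(neighbors, nrow(idx)))]
        vals <- h[cbind(rr[idx[keep, 1]], cc[idx[keep, 2]])]
        h[r0, c0] <- mean(vals)
        break
      }
      rad <- rad * 2
    }
  }
  mask <- !is.na(h)
  if (!all(mask)) {
    # pathological all-invalid grid: nothing to substitute from
    if (!any(ok)) stop("cannot substitute: grid has no valid pixels",
                       call. = FALSE)
  }
  meta <- grid$meta
  meta$outlier_flagged <- sum(!ok & mask)
  meta$outlier_method <- "nn_substitute"
  surface_grid(h, grid$pitch_x, grid$pitch_y, valid_mask = mask, meta = meta)
}
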