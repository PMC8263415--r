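#' Estimate the striation direction of a mark
#'
#' Finds the angle at which averaging the surface along the striae preserves
#' the most profile detail. For each candidate angle the valid pixels are
#' projected onto the axis perpendicular to the hypothesised striae, binned at
#' the pixel pitch, and the binned mean profile is high-passed (moving-average
#' subtraction) before its variance is taken as the directional energy; the
#' energy is maximised by a 1-degree grid search refined at 0.1 degrees. On an
#' isotropic surface the energy landscape is flat and the estimate is flagged
#' as low confidence.
#'
#' @param grid A [surface_grid] with >= 70% valid pixels.
#' @param search Half-width of the angle search (degrees); default 45.
#' @param detrend_window Moving-average window (samples, odd) applied to each
#'   candidate profile before scoring; default 51.
#' @param conf_threshold Confidence below which `low_confidence` is set;
#'   default 0.3.
#' @return A list: `angle_deg` (in (-90, 90]), `confidence` in `[0, 1]`,
#'   `low_confidence` flag, and the searched `angles`/`energy` curves.
#' @export
estimate_striation_orientation <- function(grid, search = 45,
                                           detrend_window = 51,
                                           conf_threshold = 0.3) {
  stopifnot(inherits(grid, "surface_grid"))
  if (mean(grid$valid_mask) < 0.7) {
    stop("insufficient valid data (< 70%) for orientation estimation",
         call. = FALSE)
  }
  h <- grid$heights
  ok <- grid$valid_mask & !is.na(h)
  ny <- nrow(h); nx <- ncol(h)
  x_um <- rep((seq_len(nx) - 1) * grid$pitch_x, each = ny)[ok]
  y_um <- rep((seq_len(ny) - 1) * grid$pitch_y, times = nx)[ok]
  z <- h[ok]

  # directional signal energy at one candidate angle: between-bin variance of
  # the high-passed projected profile, minus the sampling-noise floor the bin
  # means would show for an isotropic surface (within-bin variance / count)
  energy_at <- function(a_deg) {
    a <- a_deg * pi / 180
    u <- x_um * cos(a) + y_um * sin(a)
    bin <- round(u / grid$pitch_x)
    bin <- bin - min(bin) + 1
    sums <- as.vector(rowsum(z, bin))
    sq <- as.vector(rowsum(z^2, bin))
    cnts <- as.vector(rowsum(rep(1, length(z)), bin))
    # bins with a single pixel carry no information and inflate the
    # between-bin variance; drop them and weight the rest by pixel count
    multi <- !is.na(sums) & cnts >= 2
    prof <- sums[multi] / cnts[multi]
    w <- cnts[multi]
    if (length(prof) < detrend_window) return(c(signal = 0, floor = Inf))
    resid <- prof - moving_average(prof, detrend_window)
    between <- sum(w * resid^2) / sum(w)
    wvar <- (sq[multi] - sums[multi]^2 / cnts[multi]) / (cnts[multi] - 1)
    floor <- sum(wvar) / sum(w)
    c(signal = max(0, between - floor), floor = floor)
  }

  coarse <- seq(-search, search, by = 1)
  e1 <- vapply(coarse, energy_at, numeric(2))
  best <- coarse[which.max(e1["signal", ])]
  fine <- seq(best - 1, best + 1, by = 0.1)
  e2 <- vapply(fine, energy_at, numeric(2))
  ib <- which.max(e2["signal", ])
  angle <- fine[ib]
  if (angle <= -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180

  # confidence: directional signal at the best angle above the across-angle
  # fluctuation baseline, relative to the sampling-noise floor — near 1 for a
  # striated surface, near 0 for an isotropic one
  s_max <- e2["signal", ib]
  s_base <- median(e1["signal", ])
  confidence <- if (!is.finite(s_max) || s_max <= 0) 0 else {
    max(0, min(1, (s_max - s_base) / (s_max + e2["floor", ib])))
  }
  list(
    angle_deg = angle,
    confidence = confidence,
    low_confidence = confidence < conf_threshold,
    angles = c(coarse, fine),
    energy = c(e1["signal", ], e2["signal", ])
  )
}

#' Orientation-correct a surface grid
#'
#' Resamples the grid with bilinear interpolation so that the striae run along
#' the column axis (striation angle 0): a pixel of the corrected grid samples
#' the original surface at the location obtained by rotating its centred
#' coordinates by `angle_deg`. Target pixels falling outside the original
#' grid, or whose interpolation stencil touches an invalid pixel, become
#' invalid. `angle_deg = 0` returns the input unchanged (no resampling).
#'
#' @param grid A [surface_grid].
#' @param angle_deg Striation angle to correct for (degrees CCW from the
#'   column axis), typically from [estimate_striation_orientation()].
#' @return A [surface_grid] of the same dimensions.
#' @export
rotate_grid <- function(grid, angle_deg) {
  stopifnot(inherits(grid, "surface_grid"))
  if (angle_deg == 0) return(grid)
  a <- angle_deg * pi / 180
  h <- grid$heights
  ny <- nrow(h); nx <- ncol(h)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  # target pixel (x', y') samples the source at centred rotation by +a,
  # so that the source's perpendicular coordinate becomes the x' axis
  xp <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx) - cx
  yp <- matrix(rep(seq_len(ny) - 1, times = nx), ny, nx) - cy
  sx <- cx + xp * cos(a) - yp * sin(a) * (grid$pitch_y / grid$pitch_x)
  sy <- cy + xp * sin(a) * (grid$pitch_x / grid$pitch_y) + yp * cos(a)

  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 0 & (x0 + 1) <= (nx - 1) & y0 >= 0 & (y0 + 1) <= (ny - 1)

  hv <- h
  hv[!grid$valid_mask] <- NA_real_
  at <- function(r, c) {
    idx <- pmin(pmax(r, 0), ny - 1) + ny * pmin(pmax(c, 0), nx - 1) + 1
    hv[idx]
  }
  v00 <- at(y0, x0); v01 <- at(y0, x0 + 1)
  v10 <- at(y0 + 1, x0); v11 <- at(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- NA_real_
  out <- matrix(out, ny, nx)
  mask <- !is.na(out)
  meta <- grid$meta
  meta$striation_angle_deg <- 0
  meta$rotation_applied_deg <- angle_deg
  surface_grid(out, grid$pitch_x, grid$pitch_y, valid_mask = mask, meta = meta)
}
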