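#' Construct a surface grid
#'
#' A `surface_grid` is the package's container for a regular-grid height map of
#' a striated mark: a numeric matrix of elevations in micrometres, the sampling
#' pitch in micrometres per pixel, a per-pixel validity mask (measured vs
#' dropout), and free-text provenance metadata. Row index is the y coordinate,
#' column index the x coordinate; indices are 0-based in all coordinate
#' metadata. Invalid pixels hold `NA` in `heights` and `FALSE` in the mask, and
#' are excluded from every numeric reduction in the package.
#'
#' @param heights Numeric matrix of elevations (um). `NA` marks dropouts.
#' @param pitch_x,pitch_y Sampling interval (um/px), strictly positive.
#' @param valid_mask Logical matrix, same dimension as `heights`. Defaults to
#'   `!is.na(heights)`.
#' @param meta Named list of provenance fields. Recognised entries include
#'   `mark_id`, `source` (`"case"`, `"test"` or `"synthetic"`), `blade`,
#'   `side`, `section`, and `striation_angle_deg` (known or estimated striae
#'   direction, degrees CCW from the column axis; 0 means striae run along
#'   columns so each row is a cross-section).
#' @return An object of class `surface_grid`.
#' @export
#' @examples
#' g <- surface_grid(matrix(0, 3, 3), pitch_x = 3, pitch_y = 3)
#' validate_grid(g)
surface_grid <- function(heights, pitch_x, pitch_y = pitch_x,
                         valid_mask = NULL, meta = list()) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (is.null(valid_mask)) valid_mask <- !is.na(heights)
  valid_mask <- as.matrix(valid_mask)
  if (!identical(dim(heights), dim(valid_mask))) {
    stop("heights and valid_mask must have identical dimensions", call. = FALSE)
  }
  if (!is.numeric(pitch_x) || !is.numeric(pitch_y) ||
      pitch_x <= 0 || pitch_y <= 0) {
    stop("pitch_x and pitch_y must be > 0", call. = FALSE)
  }
  heights[!valid_mask] <- NA_real_
  structure(
    list(
      heights = heights,
      pitch_x = as.numeric(pitch_x),
      pitch_y = as.numeric(pitch_y),
      valid_mask = valid_mask,
      meta = meta
    ),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<surface_grid> %d rows x %d cols, pitch %.3g x %.3g um/px\n",
    d[1], d[2], x$pitch_x, x$pitch_y
  ))
  cat(sprintf(
    "  valid: %.1f%%  height range: [%.3g, %.3g] um\n",
    100 * mean(x$valid_mask),
    suppressWarnings(min(x$heights, na.rm = TRUE)),
    suppressWarnings(max(x$heights, na.rm = TRUE))
  ))
  if (!is.null(x$meta$mark_id)) cat("  mark_id:", x$meta$mark_id, "\n")
  invisible(x)
}

# sidecar serialization: flat "key = value" lines, full double precision
.meta_numeric_keys <- c("pitch_x", "pitch_y", "striation_angle_deg")

write_sidecar <- function(path, fields) {
  lines <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    paste0(k, " = ", v)
  }, character(1))
  writeLines(lines, path)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  for (k in intersect(names(out), .meta_numeric_keys)) {
    out[[k]] <- as.numeric(out[[k]])
  }
  out
}

#' Read a surface grid from a grid-csv file
#'
#' Reads a comma-delimited height map (row index = y, column index = x, values
#' in um, token `NA` for unmeasured pixels) together with its key-value
#' metadata sidecar `<path>.meta`. Non-numeric or missing cells become invalid
#' pixels. Ragged rows are a format error.
#'
#' @param path Path to the grid-csv file.
#' @param pitch_x,pitch_y Fallback pitch (um/px) when the sidecar is absent or
#'   does not state one. An error is raised if no pitch is available at all.
#' @return A [surface_grid].
#' @export
read_surface <- function(path, pitch_x = NULL, pitch_y = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty grid file: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1) {
    stop("malformed grid (ragged rows) in ", path, call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  heights <- matrix(vals, nrow = length(lines), ncol = ncols[1], byrow = TRUE)

  meta <- list()
  sidecar <- paste0(path, ".meta")
  if (file.exists(sidecar)) meta <- read_sidecar(sidecar)
  px <- meta$pitch_x %||% pitch_x
  py <- meta$pitch_y %||% pitch_y %||% px
  if (is.null(px)) {
    stop("no pitch in sidecar and no default supplied for ", path,
         call. = FALSE)
  }
  meta$pitch_x <- NULL
  meta$pitch_y <- NULL
  surface_grid(heights, pitch_x = px, pitch_y = py, meta = meta)
}

#' Write a surface grid to a grid-csv file
#'
#' Writes the heights as comma-delimited rows (token `NA` for invalid pixels)
#' plus a `<path>.meta` key-value sidecar carrying the pitch and all scalar
#' metadata. Finite heights round-trip bit-compatibly through [read_surface()].
#'
#' @param grid A [surface_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(grid, path) {
  stopifnot(inherits(grid, "surface_grid"))
  h <- grid$heights
  txt <- matrix(sprintf("%.17g", h), nrow = nrow(h))
  txt[!grid$valid_mask | is.na(h)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  fields <- c(
    list(pitch_x = grid$pitch_x, pitch_y = grid$pitch_y, units = "um"),
    Filter(function(v) is.character(v) || is.numeric(v), grid$meta)
  )
  write_sidecar(paste0(path, ".meta"), fields)
  invisible(path)
}

#' Diagnostic report for a surface grid
#'
#' Summarises dimensions, invalid-pixel fraction and height range, and flags
#' grids whose invalid fraction exceeds a ceiling. Purely reporting: the input
#' is never modified.
#'
#' @param grid A [surface_grid].
#' @param max_invalid Ceiling on the invalid-pixel fraction above which the
#'   grid is flagged (default 0.3).
#' @return A one-row tibble with columns `n_rows`, `n_cols`, `pitch_x`,
#'   `pitch_y`, `invalid_fraction`, `height_min`, `height_max`, `flagged`.
#' @export
validate_grid <- function(grid, max_invalid = 0.3) {
  stopifnot(inherits(grid, "surface_grid"))
  inv <- 1 - mean(grid$valid_mask)
  finite <- grid$heights[grid$valid_mask]
  tibble::tibble(
    n_rows = nrow(grid$heights),
    n_cols = ncol(grid$heights),
    pitch_x = grid$pitch_x,
    pitch_y = grid$pitch_y,
    invalid_fraction = inv,
    height_min = if (length(finite)) min(finite) else NA_real_,
    height_max = if (length(finite)) max(finite) else NA_real_,
    flagged = inv > max_invalid
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
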