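#' Mark simulation configuration
#'
#' Parameters of one simulated strike: which stretch of the blade edge is
#' imprinted, how the mark lies on the scanner grid, and the disturbances a
#' real scan carries. All fields are recorded in the output grid's metadata as
#' ground truth. Defaults are the package's reference simulation conditions.
#'
#' @param section_offset Start of the imprinted edge window (um along the edge).
#' @param section_length Length of the imprinted window (um); sets grid width.
#' @param rows Number of grid rows (extent along the striae).
#' @param pitch Grid sampling interval (um/px) in both axes; default 3.
#' @param striation_angle_deg Striae direction, degrees CCW from the column
#'   axis; 0 means each grid row is an exact cross-section of the edge.
#' @param tilt_x,tilt_y Plane slope of the specimen vs the scanner reference
#'   plane (um per um).
#' @param form_amplitude,form_wavelength Smooth low-frequency bow (um, um).
#' @param noise_sd Measurement noise SD (um).
#' @param spike_rate,spike_amplitude Rate in `[0,1]` and magnitude (um) of
#'   isolated outlier pixels (scanner artefacts).
#' @param dropout_rate Rate in `[0,1]` of unmeasured pixels.
#' @param wear_sd SD (um) of a band-limited perturbation applied to the edge
#'   signature once per mark, modelling tool change between strikes.
#' @param rng_seed Integer seed for this mark's random draws.
#' @return A list of class `mark_sim_config`.
#' @export
mark_sim_config <- function(section_offset = 402, section_length = 1536,
                            rows = 128, pitch = 3,
                            striation_angle_deg = 0,
                            tilt_x = 0.01, tilt_y = 0.005,
                            form_amplitude = 2, form_wavelength = 2000,
                            noise_sd = 0.05,
                            spike_rate = 0.001, spike_amplitude = 20,
                            dropout_rate = 0.01,
                            wear_sd = 0.1,
                            rng_seed = 1) {
  cfg <- as.list(environment())
  rates <- c(cfg$spike_rate, cfg$dropout_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("spike_rate and dropout_rate must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(cfg$pitch > 0, cfg$section_length > 0, cfg$rows >= 1)
  class(cfg) <- "mark_sim_config"
  cfg
}

#' A disturbance-free variant of [mark_sim_config()]
#'
#' All noise, tilt, form, spike, dropout and wear terms set to zero; useful for
#' identity checks (a noiseless mark reproduces the edge segment exactly).
#'
#' @param ... Overrides passed on to [mark_sim_config()].
#' @return A `mark_sim_config`.
#' @export
quiet_mark_config <- function(...) {
  args <- modifyList(
    list(tilt_x = 0, tilt_y = 0, form_amplitude = 0, noise_sd = 0,
         spike_rate = 0, dropout_rate = 0, wear_sd = 0),
    list(...)
  )
  do.call(mark_sim_config, args)
}

#' Imprint a blade into a synthetic mark surface
#'
#' Realises the geometry of a blade strike: the edge profile is replicated
#' along the cut direction, so the height at grid position (x, y) is the edge
#' signature evaluated at the coordinate perpendicular to the striae, plus
#' specimen tilt, low-frequency form, measurement noise, spike artefacts, and
#' dropouts. The full configuration and realised disturbance bookkeeping are
#' embedded as ground-truth metadata.
#'
#' @param blade A [generate_blade()] profile.
#' @param cfg A [mark_sim_config()].
#' @param mark_id Identifier for the mark (default derived from blade + seed).
#' @return A [surface_grid] with `meta$truth` carrying the ground truth
#'   (realised spike/dropout indices and counts, wear seed, angle).
#' @export
#' @examples
#' b <- generate_blade(seed = 1, length_um = 2500)
#' g <- imprint_mark(b, quiet_mark_config(rows = 16))
#' all(g$heights[1, ] == g$heights[16, ])
imprint_mark <- function(blade, cfg, mark_id = NULL) {
  stopifnot(inherits(blade, "blade_profile"), inherits(cfg, "mark_sim_config"))
  p <- cfg$pitch
  nx <- floor(cfg$section_length / p)
  ny <- cfg$rows
  a <- cfg$striation_angle_deg * pi / 180

  edge <- blade$edge_signature
  wear_seed <- child_seed(cfg$rng_seed, 11)
  if (cfg$wear_sd > 0) {
    edge <- edge + band_limited_noise(length(edge), blade$step, blade$band,
                                      cfg$wear_sd, wear_seed)
  }

  x_um <- (seq_len(nx) - 1) * p
  y_um <- (seq_len(ny) - 1) * p
  # edge coordinate perpendicular to the striae for every pixel
  u <- cfg$section_offset +
    outer(y_um * sin(a), x_um * cos(a), `+`) # ny x nx
  edge_max <- (length(edge) - 1) * blade$step
  if (min(u) < 0 || max(u) > edge_max) {
    stop(sprintf(
      "section window [%.1f, %.1f] um outside blade profile [0, %.1f] um",
      min(u), max(u), edge_max
    ), call. = FALSE)
  }
  heights <- matrix(interp_linear(edge, blade$step, as.vector(u)), ny, nx)

  heights <- heights +
    outer(y_um * cfg$tilt_y, x_um * cfg$tilt_x, `+`)
  if (cfg$form_amplitude > 0) {
    th <- 30 * pi / 180 # fixed oblique form direction: genuinely 2D bow
    d <- outer(y_um * sin(th), x_um * cos(th), `+`)
    heights <- heights + cfg$form_amplitude * sin(2 * pi * d / cfg$form_wavelength)
  }

  npx <- nx * ny
  truth <- list(
    blade_id = blade$blade_id,
    striation_angle_deg = cfg$striation_angle_deg,
    wear_seed = wear_seed,
    cfg = cfg
  )
  if (cfg$noise_sd > 0) {
    heights <- heights +
      matrix(with_seed(child_seed(cfg$rng_seed, 12), rnorm(npx, 0, cfg$noise_sd)),
             ny, nx)
  }
  if (cfg$spike_rate > 0) {
    spikes <- with_seed(child_seed(cfg$rng_seed, 13), {
      idx <- which(runif(npx) < cfg$spike_rate)
      sign <- sample(c(-1, 1), length(idx), replace = TRUE)
      list(idx = idx, sign = sign)
    })
    heights[spikes$idx] <- heights[spikes$idx] +
      spikes$sign * cfg$spike_amplitude
    truth$spike_idx <- spikes$idx
  } else {
    truth$spike_idx <- integer(0)
  }
  mask <- matrix(TRUE, ny, nx)
  if (cfg$dropout_rate > 0) {
    drop_idx <- with_seed(child_seed(cfg$rng_seed, 14),
                          which(runif(npx) < cfg$dropout_rate))
    mask[drop_idx] <- FALSE
    truth$dropout_idx <- drop_idx
  } else {
    truth$dropout_idx <- integer(0)
  }

  surface_grid(
    heights, pitch_x = p, pitch_y = p, valid_mask = mask,
    meta = list(
      mark_id = mark_id %||% paste0(blade$blade_id, "-m", cfg$rng_seed),
      source = "synthetic",
      blade = blade$blade_id,
      striation_angle_deg = cfg$striation_angle_deg,
      truth = truth
    )
  )
}

# linear interpolation of a regularly sampled profile at arbitrary coordinates
interp_linear <- function(values, step, at) {
  pos <- at / step
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- pmin(pmax(i0, 0), length(values) - 1)
  i1 <- pmin(i0 + 1, length(values) - 1)
  values[i0 + 1] * (1 - frac) + values[i1 + 1] * frac
}

#' Generate a known-match / known-non-match dataset
#'
#' Emulates the reference experiment used to calibrate mark comparison: several
#' blades each strike several marks, and every unordered pair of marks is
#' labelled KM (same blade) or KNM (different blades). With 4 blades and 2
#' marks each this yields the classic 4 KM + 24 KNM design. Marks of the same
#' blade imprint the same edge section, so only disturbances and wear separate
#' them.
#'
#' @param n_blades Number of distinct blades (>= 2).
#' @param marks_per_blade Marks struck per blade (>= 2).
#' @param cfg_template A [mark_sim_config()] used for every mark; each mark
#'   receives its own derived `rng_seed` and an angle jitter.
#' @param seed Master seed; all blades and marks derive from it.
#' @param angle_jitter_deg Half-width (degrees) of the uniform per-mark
#'   striation-angle jitter around the template angle; default 3.
#' @param blade_length_um Edge length simulated per blade; default sized to
#'   cover the template's section window at any jittered angle.
#' @return A list with `grids` (named list of [surface_grid]), `manifest`
#'   (tibble: `pair_id`, `mark_a`, `mark_b`, `label`), and `blades`.
#' @export
#' @examples
#' ds <- make_km_knm_dataset(2, 2, quiet_mark_config(rows = 8), seed = 1)
#' table(ds$manifest$label)
make_km_knm_dataset <- function(n_blades = 4, marks_per_blade = 2,
                                cfg_template = mark_sim_config(), seed = 1,
                                angle_jitter_deg = 3,
                                blade_length_um = NULL) {
  stopifnot(n_blades >= 2, marks_per_blade >= 2)
  if (is.null(blade_length_um)) {
    blade_length_um <- cfg_template$section_offset + cfg_template$section_length +
      cfg_template$rows * cfg_template$pitch + 200
  }
  blades <- lapply(seq_len(n_blades), function(b) {
    generate_blade(
      seed = child_seed(seed, 1, b), length_um = blade_length_um,
      step = cfg_template$pitch, blade_id = sprintf("b%02d", b)
    )
  })
  grids <- list()
  for (b in seq_len(n_blades)) {
    for (m in seq_len(marks_per_blade)) {
      cfg <- cfg_template
      cfg$rng_seed <- child_seed(seed, 2, b, m)
      if (angle_jitter_deg > 0) {
        cfg$striation_angle_deg <- cfg_template$striation_angle_deg +
          with_seed(child_seed(seed, 3, b, m),
                    runif(1, -angle_jitter_deg, angle_jitter_deg))
      }
      id <- sprintf("b%02dm%02d", b, m)
      grids[[id]] <- imprint_mark(blades[[b]], cfg, mark_id = id)
    }
  }
  ids <- names(grids)
  blade_of <- vapply(grids, function(g) g$meta$blade, character(1))
  pairs <- utils::combn(ids, 2)
  manifest <- tibble::tibble(
    pair_id = sprintf("p%03d", seq_len(ncol(pairs))),
    mark_a = pairs[1, ],
    mark_b = pairs[2, ],
    label = unname(ifelse(blade_of[pairs[1, ]] == blade_of[pairs[2, ]],
                          "KM", "KNM"))
  )
  list(grids = grids, manifest = manifest, blades = blades)
}
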