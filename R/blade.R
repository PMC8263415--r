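#' Band-limited Gaussian noise profile
#'
#' White Gaussian noise hard-limited in the frequency domain to `band`
#' (cycles/um) and rescaled to a target standard deviation. The building block
#' for simulated blade-edge signatures and wear perturbations.
#'
#' @param n Number of samples.
#' @param step Sampling interval (um).
#' @param band Length-2 numeric, passband in cycles/um; must lie below the
#'   Nyquist frequency `1/(2*step)`.
#' @param sd_target Standard deviation of the output (um).
#' @param seed Integer seed (deterministic output).
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, step, band, sd_target, seed) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  nyq <- 1 / (2 * step)
  if (band[2] > nyq + 1e-12) {
    stop("band upper edge ", band[2], " exceeds Nyquist ", nyq, call. = FALSE)
  }
  w <- with_seed(seed, rnorm(n))
  f <- fft_freqs(n, step)
  keep <- abs(f) >= band[1] & abs(f) <= band[2]
  spec <- fft(w)
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  x * (sd_target / s)
}

# two-sided FFT bin frequencies in cycles/um
fft_freqs <- function(n, step) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * step)
}

#' Simulate a blade-edge profile
#'
#' Generates the micro-irregularity profile of a blade's cutting edge: the
#' individual characteristics (burrs, dents, wear scratches) modelled as
#' band-limited Gaussian noise, plus an optional periodic class component
#' representing manufacturing grinding structure. Every mark struck with the
#' same blade shares this profile, which is what makes known matches match.
#'
#' @param seed Integer seed; the profile is a pure function of its arguments.
#' @param length_um Length of simulated edge (um). Must give >= 64 samples.
#' @param step Sampling interval (um/px); default 3.
#' @param band Passband of the individual component (cycles/um); default
#'   `c(1/200, 1/10)`, i.e. striae widths of roughly 10-60 um.
#' @param amplitude_sd Standard deviation of the individual component (um).
#' @param class_component Optional `list(amplitude =, period =)` (um) adding a
#'   sinusoidal grinding structure; `NULL` or amplitude 0 disables it.
#' @param blade_id Identifier stamped into marks struck with this blade.
#' @return An object of class `blade_profile` with fields `edge_signature`,
#'   `step`, `band`, `class_component`, `blade_id`, `rng_seed`.
#' @export
#' @examples
#' b <- generate_blade(seed = 1, length_um = 1500)
#' length(b$edge_signature)
generate_blade <- function(seed, length_um, step = 3,
                           band = c(1 / 200, 1 / 10), amplitude_sd = 1,
                           class_component = NULL, blade_id = NULL) {
  n <- floor(length_um / step)
  if (n < 64) stop("blade profile needs >= 64 samples", call. = FALSE)
  edge <- if (amplitude_sd > 0) {
    band_limited_noise(n, step, band, amplitude_sd, child_seed(seed, 101))
  } else {
    numeric(n)
  }
  if (!is.null(class_component) && class_component$amplitude > 0) {
    u <- (seq_len(n) - 1) * step
    edge <- edge + class_component$amplitude *
      sin(2 * pi * u / class_component$period)
  }
  structure(
    list(
      edge_signature = edge,
      step = step,
      band = band,
      amplitude_sd = amplitude_sd,
      class_component = class_component,
      blade_id = blade_id %||% paste0("blade-", seed),
      rng_seed = seed
    ),
    class = "blade_profile"
  )
}

#' @export
print.blade_profile <- function(x, ...) {
  cat(sprintf(
    "<blade_profile> '%s': %d samples @ %.3g um, band [%.4g, %.4g] c/um\n",
    x$blade_id, length(x$edge_signature), x$step, x$band[1], x$band[2]
  ))
  invisible(x)
}
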