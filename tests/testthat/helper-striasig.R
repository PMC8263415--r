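# shared helpers: independent oracles and small fixture builders

# deliberate O(N * K) double-loop evaluation of the normalized
# cross-correlation definition; kept naive so it stays independent of the
# FFT/cumsum implementation it checks
brute_xcorr <- function(a, b, max_lag, min_overlap = 0.5, pearson = FALSE) {
  n1 <- length(a); n2 <- length(b)
  nmin <- min(n1, n2)
  ks <- seq.int(-max_lag, max_lag)
  out <- rep(NA_real_, length(ks))
  for (q in seq_along(ks)) {
    k <- ks[q]
    num <- 0; e1 <- 0; e2 <- 0; m <- 0; s1 <- 0; s2 <- 0
    for (i in seq_len(n1)) {
      j <- i + k
      if (j >= 1 && j <= n2) {
        num <- num + a[i] * b[j]
        e1 <- e1 + a[i]^2
        e2 <- e2 + b[j]^2
        s1 <- s1 + a[i]
        s2 <- s2 + b[j]
        m <- m + 1
      }
    }
    if (m < ceiling(min_overlap * nmin)) next
    if (pearson) {
      num <- num - s1 * s2 / m
      e1 <- e1 - s1^2 / m
      e2 <- e2 - s2^2 / m
    }
    if (e1 <= 0 || e2 <= 0) next
    out[q] <- num / sqrt(e1 * e2)
  }
  list(lags = ks, xcorr = out)
}

# brute-force longest consecutive tolerance-matching run over peak positions
brute_max_run <- function(pa, pb, tol) {
  best <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      t <- 0
      while (i + t <= length(pa) && j + t <= length(pb) &&
             abs(pa[i + t] - pb[j + t]) <= tol) {
        t <- t + 1
      }
      best <- max(best, t)
    }
  }
  best
}

# mean-free band-limited test signature, already marked detrended
rand_sig <- function(n, seed, step = 3, sd_target = 1) {
  v <- band_limited_noise(n, step, c(1 / 200, 1 / 10), sd_target, seed)
  new_signature(v - mean(v), step, origin = paste0("rand", seed),
                processing_state = "detrended")
}

as_detrended <- function(values, step = 3, origin = "test") {
  new_signature(values, step, origin = origin, processing_state = "detrended")
}

# comb profile with Gaussian teeth at the given positions (um)
comb_signature <- function(positions_um, length_um, step = 3, width = 6,
                           amp = 1) {
  x <- seq(0, length_um, by = step)
  v <- rowSums(vapply(positions_um,
                      function(p) amp * exp(-0.5 * ((x - p) / width)^2),
                      numeric(length(x))))
  as_detrended(v, step)
}

# small quiet mark used in several extraction tests
quiet_mark <- function(rows = 64, seed = 1, length_um = 2500, ...) {
  b <- generate_blade(seed = seed, length_um = length_um)
  list(blade = b, grid = imprint_mark(b, quiet_mark_config(rows = rows, ...)))
}

edge_window <- function(blade, cfg_offset = 402, ncols) {
  i0 <- cfg_offset / blade$step + 1
  blade$edge_signature[i0:(i0 + ncols - 1)]
}
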