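#' Construct a signature
#'
#' A `signature` is a 1D height profile taken across a striated mark,
#' perpendicular to the striation direction — the quantity that normalized
#' cross-correlation compares. It carries its sampling step (um), a provenance
#' tag, a processing state (`"raw"`, `"detrended"` or `"filtered"`), and the
#' processing parameters applied so far (used to refuse comparisons between
#' incompatibly pre-processed signatures).
#'
#' @param values Numeric vector of elevations (um), length >= 2, no NAs.
#' @param step Sampling interval along the profile (um), > 0.
#' @param origin Character tag: mark identifier plus extraction-line index.
#' @param processing_state One of `"raw"`, `"detrended"`, `"filtered"`.
#' @param processing Named list of applied processing parameters.
#' @return An object of class `signature`.
#' @export
new_signature <- function(values, step, origin = "unknown",
                          processing_state = "raw", processing = list()) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("signature needs >= 2 samples", call. = FALSE)
  if (anyNA(values)) stop("signature values must not contain NA", call. = FALSE)
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  processing_state <- match.arg(processing_state,
                                c("raw", "detrended", "filtered"))
  structure(
    list(
      values = values,
      step = as.numeric(step),
      origin = origin,
      processing_state = processing_state,
      processing = processing
    ),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf(
    "<signature> %d samples @ %.3g um (%s, %s), sd %.3g um\n",
    length(x$values), x$step, x$origin, x$processing_state, sd(x$values)
  ))
  invisible(x)
}

#' @export
#' @rdname new_signature
#' @param x A `signature`.
#' @param ... Unused.
tidy.signature <- function(x, ...) {
  tibble::tibble(
    position_um = (seq_along(x$values) - 1) * x$step,
    height_um = x$values
  )
}

is_detrended <- function(sig) {
  sig$processing_state %in% c("detrended", "filtered")
}

#' Set of extracted signatures from one mark
#'
#' Bundles the profiles extracted from a single mark together with the grid
#' rows they were taken from and each line's disturbance score. All member
#' signatures share step and processing state.
#'
#' @param signatures List of [new_signature()] objects.
#' @param mark_id Mark identifier.
#' @param extraction_lines Integer vector of 0-based grid row indices.
#' @param disturbance_scores Numeric per-line quality scores (lower = cleaner).
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(signatures, mark_id,
                          extraction_lines = rep(NA_integer_, length(signatures)),
                          disturbance_scores = rep(NA_real_, length(signatures))) {
  stopifnot(length(signatures) >= 1)
  steps <- vapply(signatures, function(s) s$step, numeric(1))
  states <- vapply(signatures, function(s) s$processing_state, character(1))
  if (length(unique(steps)) != 1 || length(unique(states)) != 1) {
    stop("all signatures in a set must share step and processing_state",
         call. = FALSE)
  }
  structure(
    list(
      signatures = signatures,
      mark_id = mark_id,
      extraction_lines = extraction_lines,
      disturbance_scores = disturbance_scores
    ),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "<signature_set> mark '%s': %d signatures (%s), rows %s\n",
    x$mark_id, length(x$signatures), x$signatures[[1]]$processing_state,
    paste(x$extraction_lines, collapse = ", ")
  ))
  invisible(x)
}

#' @export
#' @rdname signature_set
#' @param x A `signature_set`.
#' @param ... Unused.
tidy.signature_set <- function(x, ...) {
  purrr::map2_dfr(x$signatures, seq_along(x$signatures), function(s, i) {
    dplyr::mutate(tidy(s), line = i, .before = 1)
  })
}

set_step <- function(set) set$signatures[[1]]$step
set_state <- function(set) set$signatures[[1]]$processing_state

# processing fingerprint used to refuse cross-comparisons between marks
# pre-processed with different chains
set_processing_tag <- function(set) {
  p <- set$signatures[[1]]$processing
  paste(
    set_state(set),
    paste(names(p), vapply(p, function(v) paste(format(v), collapse = ";"),
                           character(1)),
          sep = "=", collapse = ","),
    sep = "|"
  )
}
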