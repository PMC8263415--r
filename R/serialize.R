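#' Write / read a signature set as JSON
#'
#' A documented plain-text interchange format for extracted signature sets:
#' mark identifier, step, processing state and parameters, 0-based extraction
#' lines, disturbance scores, and per-signature value arrays at full double
#' precision.
#'
#' @param set A [signature_set()].
#' @param path Output path.
#' @return `path` (write) or a `signature_set` (read), invisibly for write.
#' @export
write_signature_set <- function(set, path) {
  stopifnot(inherits(set, "signature_set"))
  obj <- list(
    format = "striasig-signature-set-v1",
    mark_id = set$mark_id,
    step_um = set_step(set),
    processing_state = set_state(set),
    processing = set$signatures[[1]]$processing,
    extraction_lines = set$extraction_lines,
    disturbance_scores = set$disturbance_scores,
    signatures = lapply(set$signatures, function(s) {
      list(origin = s$origin, values_um = s$values)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_signature_set
#' @export
read_signature_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "striasig-signature-set-v1")) {
    stop("not a striasig signature-set file: ", path, call. = FALSE)
  }
  sigs <- lapply(obj$signatures, function(s) {
    new_signature(unlist(s$values_um), obj$step_um, origin = s$origin,
                  processing_state = obj$processing_state,
                  processing = as.list(obj$processing))
  })
  signature_set(sigs, obj$mark_id,
                extraction_lines = as.integer(obj$extraction_lines),
                disturbance_scores = as.numeric(obj$disturbance_scores))
}

#' Write / read reference distributions as JSON
#'
#' Serialises the raw KM/KNM score samples together with the CI construction
#' settings, so the reference can be rebuilt exactly on read.
#'
#' @param ref A [build_reference()] object.
#' @param path File path.
#' @return `path` (write) or a `ref_distributions` (read).
#' @export
write_reference_json <- function(ref, path) {
  stopifnot(inherits(ref, "ref_distributions"))
  obj <- list(
    format = "striasig-reference-v1",
    km_scores = ref$km_scores, knm_scores = ref$knm_scores,
    ci_method = ref$ci_method, interval = ref$interval, conf = ref$conf,
    fisher_z = ref$fisher_z,
    summary = tidy(ref)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "striasig-reference-v1")) {
    stop("not a striasig reference file: ", path, call. = FALSE)
  }
  build_reference(obj$km_scores, obj$knm_scores, ci_method = obj$ci_method,
                  interval = obj$interval %||% "scores",
                  conf = obj$conf, fisher_z = isTRUE(obj$fisher_z))
}
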