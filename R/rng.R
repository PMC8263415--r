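#' Derive a child seed from a master seed
#'
#' One master seed fans out into independent per-object seeds through a small
#' integer hash, so that every simulated object (blade, mark, noise field) has
#' its own reproducible stream while the whole experiment is driven by a single
#' integer. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... One or more integer indices (e.g. blade index, mark index,
#'   component tag) identifying the consumer.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, 2, 3)
child_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, is.numeric(master))
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(master) %% m
  for (k in idx) {
    # 64-bit-safe modular polynomial hash in doubles (products < 2^53)
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
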