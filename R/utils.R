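# Shared internal helpers.

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Package-level cache (e.g. Slepian taper families keyed by geometry).
.respox_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .respox_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .respox_cache)
  }
  get(key, envir = .respox_cache, inherits = FALSE)
}
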