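#' @include AllClasses.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component seed from a global seed
#'
#' Expands one global seed into reproducible, component-specific streams by
#' stable string hashing, so that e.g. protocol generation, recording noise
#' and the smoother each get independent seeds that are fully determined by
#' the global seed.
#'
#' @param seed integer global seed.
#' @param component character label of the consuming component.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, component) {
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483646 + 1)
}
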