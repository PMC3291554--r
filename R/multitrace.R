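#' @include smoother.R
NULL

#' Joint fit of several recordings with shared parameters
#'
#' Each recording contributes its own group of hidden dynamic states to the
#' extended state, while one common parameter vector (and scale factor)
#' governs all groups; the per-observation importance weight is the product
#' of the per-trace observation densities.  With a single recording this
#' reduces exactly to \code{\link{runFixedLagSmoother}}.  Useful when single
#' traces are sparsely informative (e.g. long silent stretches): the traces'
#' informative epochs complement each other.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param recordings list of \code{\link{Recording}} objects on identical
#'   sample grids.
#' @param free free parameter names.
#' @param config a \code{\link{SmootherConfig}}.
#' @param priorBox optional prior-bounds override (see
#'   \code{\link{runFixedLagSmoother}}).
#' @param fixed named overrides for non-estimated parameters.
#' @return a \code{\link{FitResult}} whose smoothed-state columns are
#'   grouped per trace (\code{trace1.v}, ...).
#' @export
fitMultiTrace <- function(model, recordings, free, config, priorBox = NULL,
                          fixed = NULL) {
  if (!length(recordings)) stop("need at least one recording")
  n0 <- nrow(recordings[[1]]@y)
  dt0 <- recordings[[1]]@sampleInterval
  for (rec in recordings) {
    if (nrow(rec@y) != n0 || abs(rec@sampleInterval - dt0) > 1e-9)
      stop("recordings must share the same sample grid (length and interval)")
  }
  .runSmoother(model, recordings, free, config, priorBox, fixed)
}
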