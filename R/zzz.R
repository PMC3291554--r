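#' @useDynLib sossm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile median aggregate dnorm setNames
#' @importFrom utils write.csv capture.output
NULL
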