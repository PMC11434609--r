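#' @useDynLib sleepHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new is validObject
#' @importFrom stats cor sd rnorm rgamma setNames cov kmeans prcomp median
#' @importFrom utils head read.table
NULL
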