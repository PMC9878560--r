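#' @useDynLib polypseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.onLoad <- function(libname, pkgname) {
  # autoplot dispatch only matters once ggplot2 is around
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    registerS3method("autoplot", "polyp_fit", autoplot.polyp_fit,
                     envir = asNamespace("ggplot2"))
  }
  invisible(NULL)
}
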