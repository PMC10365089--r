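.onLoad <- function(libname, pkgname) {
  # bit-identical training requires a deterministic BLAS
  invisible(blas_single_thread())
}
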