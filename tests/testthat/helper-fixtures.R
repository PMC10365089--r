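# Shared fixtures, generated in code at test time.

# a small on-disk dataset reused by training/evaluation tests
tiny_manifest <- local({
  cache <- NULL
  function(seed = 11, n_phantom = 4, n_patient = 8, doses = c(20, 30, 60),
           size = 64) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "csdct-fixture")
    man <- build_manifest(dir, n_phantom = n_phantom, n_patient = n_patient,
                          doses = doses, seed = seed, size = size)
    cache <<- man
    man
  }
})

flat_image <- function(value = 0, n = 32) {
  ct_image(matrix(value, n, n), id = "flat")
}

random_image <- function(seed, n = 64, lo = -100, hi = 100) {
  withr::with_seed(seed, matrix(runif(n * n, lo, hi), n))
}
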