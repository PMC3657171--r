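# Shared small fixtures, built once per test run.

small_phantom <- local({
  cache <- NULL
  function(seed = 5L, noise_sd = 2, ...) {
    key <- paste(seed, noise_sd, ...)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      ph <- make_phantom(phantom_spec(seed = seed, noise_sd = noise_sd,
                                      ...))
      attr(ph, "key") <- key
      cache <<- ph
    }
    cache
  }
})

# A tiny grid image with reproducible content.
tiny_image <- function(d = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  voxel_image(array(stats::rnorm(prod(d)), d), spacing)
}

expect_scalar_equal <- function(x, y, tol = 1e-9) {
  testthat::expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
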