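test_that("the excess-variance law is zero at reference and follows 1/sqrt(dose) far below it", {
  m <- noise_model(reference_mAs = 175, k = 100)
  expect_identical(mas_to_sigma(m, 175), 0)
  expect_identical(mas_to_sigma(m, 200), 0)
  # with the reference term negligible the law reduces to k / sqrt(dose)
  m_inf <- noise_model(reference_mAs = 1e12, k = 100)
  expect_equal(mas_to_sigma(m_inf, 25), 20, tolerance = 1e-6)
})

test_that("sigma is strictly decreasing and continuous over the 5-95 mAs ladder", {
  m <- noise_model()
  ladder <- dose_ladder(seq(5, 95, by = 5), m)
  expect_identical(nrow(ladder), 19L)
  expect_true(all(diff(ladder$sigma) < 0))
  # continuity: a fine grid has no jumps larger than its local slope implies
  fine <- mas_to_sigma(m, seq(5, 175, by = 0.01))
  expect_lt(max(abs(diff(fine))), 0.5)
  expect_error(mas_to_sigma(m, 0), "positive")
  expect_error(mas_to_sigma(m, -3), "positive")
})

test_that("add_lowdose_noise is seeded, additive, zero-mean, and exact at sigma zero", {
  img <- generate_phantom_slice(4, 64)
  d <- dose_level(30)
  a <- add_lowdose_noise(img, d, seed = 9)
  b <- add_lowdose_noise(img, d, seed = 9)
  expect_identical(a$pixels, b$pixels)
  expect_identical(dim(a), dim(img))
  expect_identical(a$dose_mAs, 30)
  clean <- dose_level(175)
  expect_identical(add_lowdose_noise(img, clean, seed = 1)$pixels, img$pixels)
  # mean preserved within 3 standard errors on a large field
  big <- ct_image(matrix(0, 256, 256), id = "zero")
  d20 <- dose_level(20)
  noisy <- add_lowdose_noise(big, d20, seed = 2)
  se <- d20$sigma / sqrt(length(big$pixels))
  expect_lt(abs(mean(noisy$pixels)), 3 * se)
})

test_that("estimate_noise_sigma recovers the generating sigma and ignores mean shifts", {
  x <- ct_image(matrix(rep(0, 512 * 512), 512), id = "x")
  d <- dose_level(30)  # sigma ~ 31.6 HU
  noisy <- add_lowdose_noise(x, d, seed = 3)
  est <- estimate_noise_sigma(noisy, x)
  expect_lt(abs(est - d$sigma), 1)
  expect_identical(estimate_noise_sigma(x, x), 0)
  shifted <- x
  shifted$pixels <- x$pixels + 7
  expect_equal(estimate_noise_sigma(shifted, x), 0)
  expect_error(estimate_noise_sigma(x, flat_image(0, 16)), "geometry")
})

test_that("noise round trip holds within 5% across the ladder at 256x256", {
  base <- ct_image(matrix(0, 256, 256), id = "base")
  for (mAs in c(10, 20, 60, 90)) {
    d <- dose_level(mAs)
    est <- estimate_noise_sigma(add_lowdose_noise(base, d, seed = mAs), base)
    expect_lt(abs(est - d$sigma) / d$sigma, 0.05)
  }
})
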