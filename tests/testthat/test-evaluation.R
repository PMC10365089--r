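test_that("psnr matches closed forms, including the exact-match sentinel", {
  x <- random_image(1, 32)
  expect_identical(psnr(x, x, 255), Inf)
  expect_equal(psnr(x, x + 10, 255), 10 * log10(255^2 / 100),
               tolerance = 1e-9)
  # doubling a constant difference costs exactly 20 log10(2) dB
  expect_equal(psnr(x, x + 10, 255) - psnr(x, x + 20, 255), 20 * log10(2),
               tolerance = 1e-9)
  expect_identical(psnr(x, x + 5, 100), psnr(x + 5, x, 100))
  expect_error(psnr(x, matrix(0, 8, 8), 255), "geometry")
  expect_error(psnr(x, x, -1), "positive")
})

test_that("ssim is 1 on identical images, symmetric, and window-guarded", {
  x <- random_image(2, 32)
  expect_equal(ssim(x, x, 200), 1, tolerance = 1e-12)
  y <- x + random_image(3, 32, -20, 20)
  expect_identical(ssim(x, y, 200), ssim(y, x, 200))
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8), 1), "window")
})

test_that("ssim decreases monotonically with additive noise amplitude", {
  base <- generate_patient_slice(5, 64)
  vals <- vapply(c(5, 10, 20, 40), function(s) {
    noisy <- base$pixels + withr::with_seed(s, matrix(rnorm(64^2, 0, s), 64))
    ssim(base$pixels, noisy, 2048)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("metric aggregates equal the mean of retained per-image values", {
  refs <- lapply(1:4, function(s) generate_patient_slice(s, 64))
  tests <- lapply(seq_along(refs), function(i) {
    out <- refs[[i]]
    out$pixels <- out$pixels + withr::with_seed(i, matrix(rnorm(64^2, 0, 15),
                                                          64))
    out
  })
  mr <- metric_result(refs, tests, 2048)
  expect_identical(mr$n_images, 4L)
  expect_identical(mr$psnr, mean(mr$per_image$psnr))
  expect_identical(mr$ssim, mean(mr$per_image$ssim))
  expect_identical(tidy(mr), mr$per_image)
  expect_identical(glance(mr)$psnr, mr$psnr)
})

test_that("the comparison harness keeps arms comparable and deltas antisymmetric", {
  man <- tiny_manifest()
  # clipping to the plausible HU range projects every pixel toward its true
  # value (all clean values lie inside the clip window), so this arm must
  # strictly beat the identity arm
  clip <- function(img) {
    out <- img
    out$pixels <- pmin(pmax(img$pixels, -1100), 1100)
    out
  }
  rep <- run_comparison(list(identity = "identity", clip = clip),
                        man, doses = c(20, 60), seed = 4)
  expect_identical(nrow(rep), 4L)          # |doses| x |arms|
  expect_identical(sort(unique(rep$arm)), c("clip", "identity"))
  per <- attr(rep, "per_image")
  expect_true(all(is.finite(per$psnr)))
  at20 <- rep[rep$dose_mAs == 20, ]
  expect_gt(at20$psnr[at20$arm == "clip"], at20$psnr[at20$arm == "identity"])
  # deltas are antisymmetric
  d <- comparison_deltas(rep)
  ab <- d[d$arm_a == "clip" & d$arm_b == "identity", ]
  ba <- d[d$arm_a == "identity" & d$arm_b == "clip", ]
  expect_equal(ab$d_psnr, -ba$d_psnr, tolerance = 1e-12)
})

test_that("identity-arm PSNR equals the noisy-input PSNR by construction", {
  man <- tiny_manifest()
  model <- attr(man, "noise_model")
  rep <- run_comparison(list(identity = "identity"), man, doses = 30,
                        seed = 9)
  cleans <- csdct:::load_manifest_images(man, "test")$patient_standard
  d30 <- dose_level(30, model)
  manual <- mean(vapply(seq_along(cleans), function(i) {
    noisy <- add_lowdose_noise(cleans[[i]], d30,
                               csdct:::derive_seed(9, 1000 + i))
    psnr(cleans[[i]], noisy, 2048)
  }, numeric(1)))
  expect_equal(rep$psnr, manual, tolerance = 1e-12)
})
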