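test_that("network builders enforce role/spec contracts", {
  expect_error(build_denoiser(network_spec("simulator"), 1), "role")
  expect_error(build_simulator(network_spec("denoiser"), 1), "role")
  expect_error(build_discriminator(network_spec("denoiser"), 1), "role")
  expect_error(network_spec("simulator", init = "zero-residual"),
               "denoiser only")
})

test_that("denoiser preserves geometry, is seeded, and supports identity init", {
  spec <- network_spec("denoiser", depth = 4, width = 6)
  a <- build_denoiser(spec, 3)
  b <- build_denoiser(spec, 3)
  x <- random_image(1, 40)
  ya <- denoise(a, x)
  expect_identical(dim(ya), dim(x))
  expect_identical(ya, denoise(b, x))
  expect_false(identical(ya, denoise(build_denoiser(spec, 4), x)))
  idn <- build_denoiser(network_spec("denoiser", depth = 4, width = 6,
                                     init = "zero-residual"), 3)
  expect_identical(denoise(idn, x), x)
  # odd sizes work: the chain is fully convolutional
  x2 <- random_image(2, 33)
  expect_identical(dim(denoise(a, x2)), c(33L, 33L))
})

test_that("simulator preserves geometry, is seeded, and perturbs at init", {
  spec <- network_spec("simulator", depth = 2, width = 4)
  sim <- build_simulator(spec, 5)
  img <- generate_phantom_slice(1, 64)
  y1 <- simulate_lowdose(sim, img, seed = 2)
  y2 <- simulate_lowdose(sim, img, seed = 2)
  expect_identical(y1$pixels, y2$pixels)
  expect_identical(dim(y1), dim(img))
  # freshly initialized simulator applies a nonzero perturbation
  expect_gt(sd(y1$pixels - img$pixels), 0)
  # u-shape divisibility contract
  expect_error(simulate_lowdose(sim, random_image(1, 33), seed = 1),
               "divisible")
})

test_that("discriminator outputs lie strictly inside (0, 1) and are seeded", {
  spec <- network_spec("discriminator", depth = 3, width = 4)
  d <- build_discriminator(spec, 7)
  for (s in 1:3) {
    p <- csdct:::forward_discriminator(d, random_image(s, 32) * 100)$prob
    expect_true(all(p > 0 & p < 1))
  }
  d2 <- build_discriminator(spec, 7)
  x <- random_image(4, 32)
  expect_identical(csdct:::forward_discriminator(d, x)$prob,
                   csdct:::forward_discriminator(d2, x)$prob)
})

test_that("parameter counts match the closed-form layer algebra", {
  for (spec in list(network_spec("denoiser", depth = 5, width = 8),
                    network_spec("denoiser", depth = 3, width = 4),
                    network_spec("simulator", depth = 2, width = 8),
                    network_spec("simulator", depth = 3, width = 4),
                    network_spec("discriminator", depth = 3, width = 8))) {
    net <- switch(spec$role,
                  denoiser = build_denoiser(spec, 1),
                  simulator = build_simulator(spec, 1),
                  discriminator = build_discriminator(spec, 1))
    expect_identical(param_count(net), param_count(spec))
  }
  # hand count for the smallest denoiser: depth 3, width 4
  # conv1: 9*1*4+4 = 40; conv2: 9*4*4+4 = 148; conv3: 9*4*1+1 = 37
  expect_identical(param_count(network_spec("denoiser", depth = 3,
                                            width = 4)), 40L + 148L + 37L)
})

test_that("the denoiser is translation-compatible away from its receptive field", {
  spec <- network_spec("denoiser", depth = 4, width = 6)
  net <- build_denoiser(spec, 9)
  x <- random_image(6, 48)
  full <- denoise(net, x)
  r <- spec$receptive_field  # margin beyond the receptive-field radius
  inner <- denoise(net, x[11:38, 11:38])
  expect_equal(full[(10 + r):(38 - r), (10 + r):(38 - r)],
               inner[r:(28 - r), r:(28 - r)], tolerance = 1e-10)
})

test_that("checkpoints restore forward outputs bit-exactly", {
  sim <- build_simulator(network_spec("simulator", depth = 2, width = 4), 2)
  den <- build_denoiser(network_spec("denoiser", depth = 4, width = 4), 2)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(list(sim = sim, den = den), f)
  back <- load_checkpoint(f)
  img <- generate_patient_slice(3, 64)
  expect_identical(simulate_lowdose(back$sim, img, seed = 1)$pixels,
                   simulate_lowdose(sim, img, seed = 1)$pixels)
  expect_identical(denoise(back$den, img)$pixels, denoise(den, img)$pixels)
})

test_that("a discriminator trained on separated toy sets ranks real above fake", {
  ns <- asNamespace("csdct")
  spec <- network_spec("discriminator", depth = 3, width = 8)
  plan <- tiny_profile(seed = 1)
  state <- ns$init_state(plan)
  withr::with_seed(31, {
    reals <- lapply(1:16, function(i) matrix(rnorm(32 * 32, 0, 0.2), 32))
    fakes <- lapply(1:16, function(i) matrix(0, 32, 32))
    for (step in 1:60) {
      idx <- sample.int(16, 4)
      st <- ns$disc_step(state, reals[idx], fakes[idx], weight = 1)
      state <- st$state
    }
  })
  score <- function(x) mean(ns$forward_discriminator(state$discriminator,
                                                     x)$prob)
  m_real <- mean(vapply(reals, score, numeric(1)))
  m_fake <- mean(vapply(fakes, score, numeric(1)))
  expect_gt(m_real - m_fake, 0.5)
})
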