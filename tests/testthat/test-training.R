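plan_smoke <- function(seed = 1, ...) {
  tiny_profile(seed = seed, stage1_steps = 5, stage2_steps = 3,
               batch_size = 2, ...)
}

test_that("training plans validate their schedule invariants", {
  expect_error(training_plan(stage1_steps = 0), "stage1_steps")
  expect_error(tiny_profile(s2d_d2s_ratio = c(1, 0)), "both cycles")
  expect_error(tiny_profile(lambda = c(1, 1, 1)), "4-vector")
  expect_error(tiny_profile(lambda = c(-1, 1, 1, 1)), "4-vector")
  expect_error(training_plan(
    patch_size = 34,
    simulator_spec = network_spec("simulator", depth = 3)), "divisible")
})

test_that("pretrain requires data and returns a seeded, reproducible state", {
  expect_error(pretrain(plan_smoke(), list()), "nonempty")
  man <- tiny_manifest()
  pairs <- csdct:::load_manifest_images(man, "train")$phantom_pairs
  s1 <- pretrain(plan_smoke(3), pairs)
  s2 <- pretrain(plan_smoke(3), pairs)
  expect_identical(s1$denoiser, s2$denoiser)
  expect_identical(s1$simulator, s2$simulator)
  expect_identical(s1$discriminator, s2$discriminator)
  expect_identical(s1$stage, "pretrain")
  expect_identical(nrow(s1$pretrain_history), 5L)
})

test_that("cyclic steps demand a pretrained state and proper batch composition", {
  man <- tiny_manifest()
  data <- csdct:::load_manifest_images(man, "train")
  plan <- plan_smoke(2)
  state <- pretrain(plan, data$phantom_pairs)
  raw <- csdct:::init_state(plan)
  lows <- lapply(data$phantom_pairs[1:2], `[[`, "low")
  phantom_std <- data$phantom_pairs[[1]]$standard
  patient_std <- data$patient_standard[[1]]
  expect_error(s2d_step(raw, list(phantom_std, patient_std), lows),
               "past pretraining")
  # clean batch must contain every configured domain
  expect_error(s2d_step(state, list(phantom_std, phantom_std), lows),
               "missing required domain")
  ok <- s2d_step(state, list(phantom_std, patient_std), lows)
  expect_s3_class(ok$state, "csd_state")
  expect_equal(ok$report$total,
               sum(plan$lambda * c(ok$report$gan_s2d, ok$report$gan_d2s,
                                   ok$report$l1_s2d, ok$report$l1_d2s)),
               tolerance = 1e-9)
  # mixed D2S demands simulated patient inputs
  expect_error(d2s_step(state, data$phantom_pairs[1:2], list()),
               "sim_low_batch")
})

test_that("each zero loss weight freezes exactly its gradient path", {
  man <- tiny_manifest()
  data <- csdct:::load_manifest_images(man, "train")
  mk_state <- function(lambda) {
    plan <- plan_smoke(4, lambda = lambda)
    pretrain(plan, data$phantom_pairs)
  }
  clean <- list(data$phantom_pairs[[1]]$standard, data$patient_standard[[1]])
  lows <- lapply(data$phantom_pairs[1:2], `[[`, "low")
  sims <- list(list(low = generate_patient_slice(50, 64)$pixels,
                    standard = generate_patient_slice(50, 64)$pixels))

  # lambda3 = 0: the denoiser is untouched by an S2D step
  st <- mk_state(c(1, 1, 0, 10))
  out <- s2d_step(st, clean, lows)
  expect_identical(out$state$denoiser, st$denoiser)
  expect_false(identical(out$state$simulator, st$simulator))

  # lambda1 = 0: discriminator and simulator are untouched by S2D
  st <- mk_state(c(0, 1, 10, 10))
  out <- s2d_step(st, clean, lows)
  expect_identical(out$state$discriminator, st$discriminator)
  expect_identical(out$state$simulator, st$simulator)
  expect_false(identical(out$state$denoiser, st$denoiser))

  # lambda2 = lambda4 = 0: a D2S step is a no-op on all weights
  st <- mk_state(c(1, 0, 10, 0))
  out <- d2s_step(st, data$phantom_pairs[1:2], sims)
  expect_identical(out$state$denoiser, st$denoiser)
  expect_identical(out$state$simulator, st$simulator)
  expect_identical(out$state$discriminator, st$discriminator)
})

test_that("the noisy-only ablation restricts D2S inputs to original noisy scans", {
  man <- tiny_manifest()
  data <- csdct:::load_manifest_images(man, "train")
  plan <- plan_smoke(5, d2s_inputs = "noisy-only")
  state <- pretrain(plan, data$phantom_pairs)
  # no simulated inputs needed or used in the ablation mode
  out <- d2s_step(state, data$phantom_pairs[1:2], list())
  expect_s3_class(out$state, "csd_state")
  expect_gt(out$report$l1_d2s, 0)
})

test_that("train_csd is deterministic and keeps exact history bookkeeping", {
  man <- tiny_manifest()
  plan <- plan_smoke(6, s2d_d2s_ratio = c(2, 1))
  f1 <- train_csd(plan, man)
  f2 <- train_csd(plan, man)
  expect_identical(f1$state$denoiser, f2$state$denoiser)
  expect_identical(f1$state$simulator, f2$state$simulator)
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), plan$stage2_steps * 3L)
  expect_identical(unique(f1$history$cycle), c("s2d", "d2s"))
  expect_true(all(is.finite(f1$history$total)))
})

test_that("a resumed run reproduces the uninterrupted run bit-exactly", {
  man <- tiny_manifest()
  ckdir <- file.path(tempdir(), "ck-resume")
  unlink(ckdir, recursive = TRUE)
  plan <- plan_smoke(7, stage2_steps = 6, checkpoint_every = 2)
  full <- train_csd(plan, man, checkpoint_dir = ckdir)
  mid <- file.path(ckdir, "ckpt_000002.rds")
  expect_true(file.exists(mid))
  resumed <- resume_csd(mid, man)
  expect_identical(resumed$state$denoiser, full$state$denoiser)
  expect_identical(resumed$state$simulator, full$state$simulator)
  expect_identical(resumed$state$discriminator, full$state$discriminator)
  expect_identical(resumed$history, full$history)
})

test_that("training emits a reproducible JSON-lines log", {
  man <- tiny_manifest()
  log <- tempfile(fileext = ".jsonl")
  plan <- plan_smoke(8)
  fit <- train_csd(plan, man, log_file = log)
  lines <- readLines(log)
  expect_identical(length(lines), nrow(fit$history))
  row <- jsonlite::fromJSON(lines[1])
  expect_identical(row$cycle, "s2d")
  expect_true(all(c("step", "total", "gan_s2d") %in% names(row)))
})
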