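test_that("phantom slices are seeded, piecewise constant, and multi-modal in HU", {
  a <- generate_phantom_slice(21, 64)
  b <- generate_phantom_slice(21, 64)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$domain_tag, "phantom")
  # air / soft tissue / bone modes all present
  expect_gt(sum(a$pixels == -1000), 100)
  expect_gt(sum(a$pixels == 40), 100)
  expect_gt(sum(a$pixels == 1000), 50)
  # piecewise-constant interior: central soft-tissue disc has ~zero variance
  n <- 64
  ctr <- a$pixels[(n / 2 - 3):(n / 2 + 3), (n / 2 - 3):(n / 2 + 3)]
  per_level <- tapply(as.vector(ctr), as.vector(ctr), var)
  expect_true(all(is.na(per_level) | per_level < 5))
  expect_error(generate_phantom_slice(1, size = 16), ">= 32")
})

test_that("patient slices carry intra-tissue texture that phantoms lack", {
  a <- generate_patient_slice(21, 64)
  b <- generate_patient_slice(21, 64)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$domain_tag, "patient")
  stats <- vapply(1:20, function(s) {
    c(texture_stat(generate_phantom_slice(s, 64)),
      texture_stat(generate_patient_slice(s, 64)))
  }, numeric(2))
  expect_true(all(stats[2, ] > stats[1, ]))
})

test_that("the texture statistic separates the domains perfectly over 50 seeds", {
  ph <- vapply(1:50, function(s) texture_stat(generate_phantom_slice(s, 48)),
               numeric(1))
  pt <- vapply(1:50, function(s) texture_stat(generate_patient_slice(s, 48)),
               numeric(1))
  expect_lt(max(ph), min(pt))
})

test_that("patient texture concentrates power at mid frequencies relative to phantoms", {
  # median mid-frequency power over soft-tissue tiles: the typical
  # phantom tile is exactly constant (zero power) while every patient tile
  # carries texture; tiles touching inserts/boundaries are a minority and
  # the median ignores them
  n_tile <- 12L
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_tile) - 1) / (n_tile - 1))
  fr <- pmin(outer(0:(n_tile - 1), 0:(n_tile - 1), function(i, j) {
    sqrt(pmin(i, n_tile - i)^2 + pmin(j, n_tile - j)^2)
  }), n_tile / 2)
  mid <- fr >= n_tile / 8 & fr < n_tile / 4
  spec_of <- function(img) {
    powers <- c()
    for (i in seq(7L, 64L - n_tile - 3L, by = 3L)) {
      for (j in seq(7L, 64L - n_tile - 3L, by = 3L)) {
        tile <- img$pixels[i:(i + n_tile - 1L), j:(j + n_tile - 1L)]
        if (all(tile > -200 & tile < 200)) {
          px <- tile - mean(tile)
          f <- Mod(stats::fft(px * outer(h, h)))^2
          powers <- c(powers, mean(f[mid]))
        }
      }
    }
    stats::median(powers)
  }
  ratio <- vapply(1:20, function(s) {
    spec_of(generate_patient_slice(s, 64)) /
      spec_of(generate_phantom_slice(s, 64))
  }, numeric(1))
  expect_gt(mean(ratio), 5)
})

test_that("dose ladders honor counts, derived seeds, and the reference-dose guard", {
  base <- generate_phantom_slice(1, 64)
  ladder <- generate_dose_ladder(base, seq(5, 95, by = 5), seed = 7)
  expect_length(ladder, 19L)
  sds <- vapply(ladder, function(p) {
    estimate_noise_sigma(p$low, p$standard)
  }, numeric(1))
  # measured noise increases monotonically as dose falls along the ladder
  expect_true(all(diff(sds) < 0))
  reps <- generate_dose_ladder(base, 20, seed = 1, n_per_dose = 138)
  expect_length(reps, 138L)
  expect_gt(length(unique(vapply(reps, function(p) p$low$pixels[1, 1],
                                 numeric(1)))), 100)
  expect_error(generate_dose_ladder(base, 175, seed = 1), "reference")
  zero <- ct_image(matrix(0, 32, 32), id = "z", domain_tag = "phantom")
  p <- generate_dose_ladder(zero, list(dose_level(20)), seed = 1)[[1]]
  expect_identical(dim(p$low), dim(p$standard))
})

test_that("manifests split by unit with floor rounding and disjoint pair ids", {
  tf <- split_units(sprintf("pt%03d", 1:388), 0.8, seed = 3)
  expect_identical(sum(tf$split == "train"), 310L)
  expect_identical(sum(tf$split == "test"), 78L)
  man <- tiny_manifest()
  man2 <- build_manifest(file.path(tempdir(), "csdct-fixture2"),
                         n_phantom = 4, n_patient = 8,
                         doses = c(20, 30, 60), seed = 11, size = 64)
  expect_identical(man$id, man2$id)
  expect_identical(man$split, man2$split)
  train_ids <- unique(man$pair_id[man$split == "train"])
  test_ids <- unique(man$pair_id[man$split == "test"])
  expect_length(intersect(train_ids, test_ids), 0L)
  expect_error(build_manifest(tempdir(), train_fraction = 1.2), "\\(0, 1\\)")
})

test_that("generated images survive the container round trip bit-exactly", {
  for (img in list(generate_phantom_slice(2, 64),
                   generate_patient_slice(2, 64))) {
    f <- tempfile(fileext = ".cthu")
    write_ct(img, f)
    back <- read_ct(f)
    expect_identical(back$pixels, img$pixels)
    expect_identical(back$domain_tag, img$domain_tag)
    expect_identical(back$id, img$id)
    expect_identical(back$spacing, img$spacing)
  }
})
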