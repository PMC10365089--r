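test_that("gan_loss matches its closed forms and clamps degenerate probabilities", {
  expect_equal(gan_loss(rep(0.5, 8), rep(0.5, 8)), -2 * log(2),
               tolerance = 1e-12)
  # symmetry: constant p on both branches gives log p + log(1 - p)
  for (p in c(0.1, 0.3, 0.7)) {
    expect_equal(gan_loss(rep(p, 4), rep(p, 4)),
                 gan_loss(rep(1 - p, 4), rep(1 - p, 4)), tolerance = 1e-12)
  }
  # maximized near d_real -> 1, d_fake -> 0, approaching 0 from below
  grid <- seq(0.05, 0.95, by = 0.05)
  vals <- outer(grid, grid, Vectorize(function(a, b) gan_loss(a, b)))
  best <- which(vals == max(vals), arr.ind = TRUE)
  expect_identical(grid[best[1]], 0.95)
  expect_identical(grid[best[2]], 0.05)
  expect_lt(max(vals), 0)
  # exact 0/1 probabilities stay finite via the epsilon clamp
  expect_true(is.finite(gan_loss(c(1, 1), c(0, 0))))
  expect_true(is.finite(gan_loss(c(0, 0), c(1, 1))))
  expect_error(gan_loss(1.2, 0.5), "probabilities")
})

test_that("gan_loss is invariant to batch permutation", {
  withr::with_seed(5, {
    pr <- runif(20)
    pf <- runif(20)
    expect_identical(gan_loss(pr, pf), gan_loss(rev(pr), sample(pf)))
  })
})

test_that("l1_loss equals a brute-force elementwise oracle on random pairs", {
  brute <- function(a, b) {
    tot <- 0
    n <- 0
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(ncol(a))) {
        tot <- tot + abs(a[i, j] - b[i, j])
        n <- n + 1
      }
    }
    tot / n
  }
  withr::with_seed(8, {
    for (r in 1:100) {
      a <- matrix(rnorm(64, sd = 50), 8)
      b <- matrix(rnorm(64, sd = 50), 8)
      expect_equal(l1_loss(a, b), brute(a, b), tolerance = 1e-6)
    }
  })
  x <- random_image(1, 16)
  expect_identical(l1_loss(x, x), 0)
  expect_equal(l1_loss(x + 3, x), 3, tolerance = 1e-12)
  expect_error(l1_loss(x, matrix(0, 4, 4)), "shape")
})

test_that("l1_loss is a metric: symmetric, nonnegative, triangle inequality", {
  withr::with_seed(9, {
    for (r in 1:25) {
      a <- matrix(rnorm(36), 6)
      b <- matrix(rnorm(36), 6)
      c <- matrix(rnorm(36), 6)
      expect_identical(l1_loss(a, b), l1_loss(b, a))
      expect_gte(l1_loss(a, b), 0)
      expect_lte(l1_loss(a, c), l1_loss(a, b) + l1_loss(b, c) + 1e-12)
    }
  })
})

test_that("the weighted total objective is exact and validates its weights", {
  expect_identical(total_objective(c(1, 2, 3, 4), c(1, 1, 1, 1)), 10)
  expect_identical(total_objective(c(5, 5, 5, 5), c(0, 0, 0, 0)), 0)
  expect_identical(total_objective(c(0.5, 9, 0.25, 9), c(2, 0, 1, 0)), 1.25)
  expect_error(total_objective(c(1, 1, 1, 1), c(-1, 0, 0, 0)), "nonnegative")
  expect_error(total_objective(c(1, 1), c(1, 1, 1, 1)), "length 4")
})

test_that("loss reports satisfy the weighted-sum identity for random terms", {
  withr::with_seed(10, {
    for (r in 1:50) {
      terms <- rnorm(4)
      lam <- runif(4, 0, 20)
      rep <- loss_report(terms[1], terms[2], terms[3], terms[4], lam)
      expect_equal(rep$total, sum(lam * terms), tolerance = 1e-9)
    }
  })
})
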