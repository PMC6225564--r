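# Affine least squares, RANSAC, thin-plate splines, serialization.

test_that("fit_affine_lsq recovers identity and exact rigid motions", {
  set.seed(1)
  p <- matrix(stats::runif(30, -50, 50), 10, 3)
  id <- fit_affine_lsq(p, p)
  expect_lt(max(abs(id$linear - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  R <- rand_rotation(2); t <- c(4, -7, 11)
  q <- p %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  fit <- fit_affine_lsq(p, q)
  expect_lt(max(abs(fit$linear - R)), 1e-8)
  expect_lt(max(abs(fit$translation - t)), 1e-8)
})

test_that("fit_affine_lsq rejects degenerate geometry", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))  # coplanar
  expect_error(fit_affine_lsq(p, p + 1), "rank|coplanar")
  expect_error(fit_affine_lsq(p[1:3, ], p[1:3, ]), "at least 4")
})

test_that("fit_affine_lsq matches the normal-equations closed form", {
  for (i in 1:20) {
    set.seed(i + 50)
    n <- sample(5:40, 1)
    src <- matrix(stats::rnorm(3 * n, sd = 30), n, 3)
    dst <- matrix(stats::rnorm(3 * n, sd = 30), n, 3)
    fit <- fit_affine_lsq(src, dst)
    X <- cbind(src, 1)
    B <- solve(t(X) %*% X, t(X) %*% dst)  # independent closed form
    expect_lt(max(abs(t(fit$linear) - B[1:3, ])), 1e-8)
    expect_lt(max(abs(fit$translation - B[4, ])), 1e-8)
    # residual gradient is zero at the optimum
    r <- X %*% B - dst
    expect_lt(max(abs(t(X) %*% r)), 1e-7)
  }
})

test_that("RANSAC on outlier-free matches keeps everything", {
  set.seed(3)
  src <- matrix(stats::runif(120, -80, 80), 40, 3)
  A <- rand_rotation(4) * 1.05
  dst <- src %*% t(A) + matrix(c(3, 4, 5), 40, 3, byrow = TRUE)
  r <- ransac_affine(src, dst, threshold = 10, seed = 1)
  expect_true(r$success)
  expect_true(all(r$inlier_mask))
  full <- fit_affine_lsq(src, dst)
  expect_lt(max(abs(r$transform$linear - full$linear)), 1e-6)
  expect_lt(max(abs(r$transform$translation - full$translation)), 1e-6)
})

test_that("RANSAC separates inliers from uniform outliers", {
  inst <- ransac_instance(seed = 5)
  r <- ransac_affine(inst$src, inst$dst, threshold = 10, seed = 2)
  expect_true(r$success)
  expect_lt(sqrt(sum((r$transform$translation - inst$t)^2)), 2)
  expect_gte(sum(r$inlier_mask[inst$inlier]), 55)
  expect_lte(sum(r$inlier_mask[-inst$inlier]), 2)
  # flagged inliers satisfy the threshold against the refit model
  res <- sqrt(rowSums((apply_transform(r$transform, inst$src) - inst$dst)^2))
  expect_true(all(res[r$inlier_mask] <= r$threshold))
})

test_that("RANSAC input validation and determinism", {
  p <- matrix(stats::runif(9), 3, 3)
  expect_error(ransac_affine(p, p), "at least 4")
  inst <- ransac_instance(seed = 6)
  r1 <- ransac_affine(inst$src, inst$dst, threshold = 10, seed = 7)
  r2 <- ransac_affine(inst$src, inst$dst, threshold = 10, seed = 7)
  expect_identical(r1, r2)
})

test_that("RANSAC does not disturb the caller's RNG stream", {
  inst <- ransac_instance(seed = 8)
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  ransac_affine(inst$src, inst$dst, seed = 3)
  expect_identical(stats::runif(1), a)
})

test_that("TPS with lambda 0 interpolates and reproduces affine maps", {
  set.seed(9)
  src <- matrix(stats::runif(30, -60, 60), 10, 3)
  dst <- matrix(stats::runif(30, -60, 60), 10, 3)
  tps <- fit_tps(src, dst, regularization = 0)
  expect_lt(max(abs(apply_transform(tps, src) - dst)), 1e-6)
  # affinely generated correspondences: nonlinear weights vanish
  A <- rand_rotation(10) * 0.98; t <- c(5, 6, 7)
  dst_a <- src %*% t(A) + matrix(t, 10, 3, byrow = TRUE)
  tps_a <- fit_tps(src, dst_a, regularization = 0)
  expect_lt(max(abs(tps_a$weights)), 1e-8)
  grid <- matrix(stats::runif(90, -100, 100), 30, 3)
  want <- grid %*% t(A) + matrix(t, 30, 3, byrow = TRUE)
  expect_lt(max(abs(apply_transform(tps_a, grid) - want)), 1e-6)
})

test_that("TPS side conditions hold for every fitted instance", {
  for (i in 1:10) {
    set.seed(i + 400)
    n <- sample(4:40, 1)
    src <- matrix(stats::rnorm(3 * n, sd = 40), n, 3)
    dst <- src + matrix(stats::rnorm(3 * n, sd = 5), n, 3)
    tps <- fit_tps(src, dst, regularization = stats::runif(1, 0, 10))
    expect_lt(max(abs(colSums(tps$weights))), 1e-8)
    expect_lt(max(abs(t(tps$weights) %*% src)), 1e-6)
    expect_equal(tps_parameter_count(n), 3 * n + 12)
  }
})

test_that("TPS control-point residuals grow monotonically with lambda", {
  set.seed(11)
  src <- matrix(stats::runif(60, -50, 50), 20, 3)
  dst <- src + matrix(stats::rnorm(60, sd = 3), 20, 3)
  resid_at <- vapply(c(0, 1, 5, 20, 100), function(lam) {
    tps <- fit_tps(src, dst, regularization = lam)
    mean(sqrt(rowSums((apply_transform(tps, src) - dst)^2)))
  }, 0)
  expect_lt(resid_at[1], 1e-6)
  expect_true(all(diff(resid_at) >= -1e-9))
})

test_that("TPS rejects duplicate and coplanar sources", {
  src <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))
  expect_error(fit_tps(src, src), "duplicate")
  flat <- cbind(matrix(stats::runif(10), 5, 2), 0)
  expect_error(fit_tps(flat, flat), "coplanar|rank")
})

test_that("tps_parameter_count follows 3N + 12 with a 12-parameter affine block", {
  expect_equal(tps_parameter_count(0), 12)
  expect_equal(tps_parameter_count(1), 15)
  expect_equal(tps_parameter_count(6), 30)
  expect_equal(tps_parameter_count(100), 312)
  expect_error(tps_parameter_count(-1), "non-negative")
})

test_that("affine inversion composes to the identity", {
  expect_equal(invert_affine(affine_transform3d())$linear, diag(3))
  set.seed(12)
  tr <- affine_transform3d(rand_rotation(13) %*% diag(c(1.1, 0.95, 1.02)),
                           c(9, -2, 4))
  inv <- invert_affine(tr)
  p <- matrix(stats::runif(300, -100, 100), 100, 3)
  expect_lt(max(abs(apply_transform(inv, apply_transform(tr, p)) - p)), 1e-9)
  bad <- diag(3); bad[2, ] <- 0
  expect_error(affine_transform3d(bad), "singular")
})

test_that("transforms round-trip through JSON bit-exactly", {
  set.seed(14)
  tr <- affine_transform3d(rand_rotation(15) * 1.03, stats::rnorm(3, 0, 20))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, f)
  tr2 <- read_transform(f)
  expect_equal(tr2$linear, tr$linear, tolerance = 1e-15)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-15)
  src <- matrix(stats::runif(30, -50, 50), 10, 3)
  tps <- fit_tps(src, src + matrix(stats::rnorm(30), 10, 3))
  write_transform(tps, f)
  tps2 <- read_transform(f)
  p <- matrix(stats::runif(30, -80, 80), 10, 3)
  expect_equal(apply_transform(tps2, p), apply_transform(tps, p),
               tolerance = 1e-14)
})
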