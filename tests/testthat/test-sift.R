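# Scale-space detector and descriptors.

test_that("intensity normalization is robust, idempotent and affine-invariant", {
  set.seed(1)
  # values spanning [0, 1] with >= 1% mass at each end: clipping is a no-op
  x <- c(rep(0, 60), stats::runif(4096 - 120), rep(1, 60))
  v <- volume3d(array(sample(x), dim = c(16, 16, 16)))
  expect_lt(max(abs(normalize_intensities(v)$data - v$data)), 1e-6)
  # positive affine intensity maps normalize to the same output
  v2 <- volume3d(3.7 * v$data + 42, v$spacing, v$origin, v$direction)
  expect_lt(max(abs(normalize_intensities(v2)$data -
                    normalize_intensities(v)$data)), 1e-6)
  expect_error(normalize_intensities(volume3d(array(5, c(8, 8, 8)))),
               "degenerate|constant")
})

test_that("scale-space sigma schedule is geometric with ratio 2^(1/levels)", {
  v <- rand_volume(dim = c(32, 32, 32), seed = 2)
  pyr <- build_scale_space(v, levels_per_octave = 3L, sigma0 = 1.6)
  sig <- pyr$octaves[[1]]$sigma_vox
  expect_equal(sig[1], 1.6)
  expect_equal(sig[-1] / sig[-length(sig)],
               rep(2^(1 / 3), length(sig) - 1), tolerance = 1e-12)
  # absolute mm sigma doubles per octave
  expect_equal(pyr$octaves[[2]]$sigma_mm[1], 2 * pyr$octaves[[1]]$sigma_mm[1])
})

test_that("difference-of-Gaussians of a constant volume is zero", {
  v <- volume3d(array(0.5, c(16, 16, 16)))
  pyr <- build_scale_space(v)
  for (oct in pyr$octaves)   # single-precision smoothing internals
    for (dog in oct$dog) expect_true(all(abs(dog) < 1e-5))
})

test_that("Gaussian smoothing satisfies the semigroup property", {
  set.seed(3)
  d <- c(32L, 32L, 32L)
  x <- stats::rnorm(prod(d))
  ab <- siftreg:::cpp_gauss_smooth(siftreg:::cpp_gauss_smooth(x, d, 1.2), d, 1.6)
  c1 <- siftreg:::cpp_gauss_smooth(x, d, sqrt(1.2^2 + 1.6^2))
  # compare away from the boundary: edge-replicate padding (not the
  # Gaussian itself) is the only source of composition error
  keep <- array(FALSE, d)
  keep[9:24, 9:24, 9:24] <- TRUE
  expect_lt(sqrt(mean((array(ab, d)[keep] - array(c1, d)[keep])^2)), 1e-3)
})

test_that("build_scale_space rejects volumes that are too small", {
  expect_error(build_scale_space(rand_volume(dim = c(6, 32, 32))), "axis 1")
})

test_that("an isotropic Gaussian blob is detected at its centre and scale", {
  # generic off-lattice centre: a perfectly lattice-symmetric blob creates
  # exact value ties that no strict extremum test can break
  at <- c(30.3, 32.1, 30.7)
  v <- blob_volume(n = 64, spacing = 1, at = at, sigma_blob = 4)
  pyr <- build_scale_space(v)
  kp <- detect_keypoints(pyr, contrast_threshold = 0.005)
  expect_gt(nrow(kp), 0)
  top <- kp[which.max(abs(kp$response)), ]
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - at)^2)), 1)
  expect_lt(top$response, 0)   # a bright blob is a DoG minimum
  # in 3D the DoG response across scale peaks at sigma_blob * sqrt(2/3)
  # (maximiser of u (1+u)^(-5/2) with u = sigma^2/sigma_blob^2);
  # the detected scale must land within one pyramid level of that
  expect_lt(abs(log2(top$scale / (4 * sqrt(2 / 3)))), 1 / 3 + 0.05)
})

test_that("a uniform volume yields no keypoints", {
  v <- volume3d(array(0.3, c(24, 24, 24)))
  kp <- detect_keypoints(build_scale_space(v))
  expect_equal(nrow(kp), 0)
})

test_that("keypoints are covariant to integer-voxel translations", {
  at <- c(30.3, 32.1, 30.7)
  off <- c(3, -2, 4)
  v1 <- blob_volume(n = 64, at = at)
  v2 <- blob_volume(n = 64, at = at + off)
  top_of <- function(v) {
    kp <- detect_keypoints(build_scale_space(v), contrast_threshold = 0.005)
    kp[which.max(abs(kp$response)), ]
  }
  t1 <- top_of(v1); t2 <- top_of(v2)
  moved <- c(t2$x - t1$x, t2$y - t1$y, t2$z - t1$z)
  expect_lt(max(abs(moved - off)), 0.5)
})

test_that("detection and description are deterministic", {
  v <- textured_volume(n = 40, seed = 7)
  f1 <- detect_features(v)
  f2 <- detect_features(v)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_identical(f1$descriptors, f2$descriptors)
})

test_that("descriptors have unit norm (or are exactly zero) and fixed length", {
  f <- detect_features(textured_volume(n = 40, seed = 8))
  expect_gt(length(f), 0)
  expect_equal(ncol(f$descriptors), 768L)
  nrm <- sqrt(rowSums(f$descriptors^2))
  expect_true(all(abs(nrm - 1) < 1e-6 | nrm == 0))
  expect_true(all(f$descriptors >= 0))
})

test_that("detector and descriptors are invariant to affine intensity maps", {
  v <- textured_volume(n = 40, seed = 9)
  v2 <- volume3d(2.5 * v$data + 10, v$spacing, v$origin, v$direction)
  f1 <- detect_features(v)
  f2 <- detect_features(v2)
  expect_equal(nrow(f1$keypoints), nrow(f2$keypoints))
  p1 <- as.matrix(f1$keypoints[, c("x", "y", "z")])
  p2 <- as.matrix(f2$keypoints[, c("x", "y", "z")])
  expect_lt(max(abs(p1 - p2)), 0.5 * v$spacing[1])
  expect_lt(max(sqrt(rowSums((f1$descriptors - f2$descriptors)^2))), 1e-3)
})

test_that("matched descriptors of a shifted copy are close and discriminative", {
  v <- textured_volume(n = 48, spacing = 1.5, seed = 10)
  shift_vox <- c(5, 0, 0)
  arr2 <- v$data
  arr2[1:(48 - 5), , ] <- v$data[6:48, , ]  # content moves 5 voxels left
  v2 <- volume3d(arr2, v$spacing, v$origin, v$direction)
  f1 <- detect_features(v)
  f2 <- detect_features(v2)
  m <- mutual_match(f1, f2)
  expect_gt(nrow(m), 10)
  p1 <- as.matrix(f1$keypoints[m$idx_a, c("x", "y", "z")])
  p2 <- as.matrix(f2$keypoints[m$idx_b, c("x", "y", "z")])
  disp <- sweep(p1 - p2, 2, shift_vox * v$spacing, `-`)
  good <- sqrt(rowSums(disp^2)) < 2
  expect_gt(mean(good), 0.8)                 # geometry: matches follow the shift
  expect_lt(stats::median(m$distance[good]), 0.3)  # descriptor distance is small
})

test_that("a textured 128-cube volume yields features in the thousands", {
  f <- detect_features(textured_volume(n = 128, spacing = 1.5, seed = 11))
  expect_gte(length(f), 500)
  expect_lte(length(f), 50000)
})

test_that("feature sets round-trip through CSV", {
  f <- detect_features(textured_volume(n = 40, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(f, path)
  f2 <- read_features(path)
  expect_equal(f2$keypoints$x, f$keypoints$x, tolerance = 1e-6)
  expect_equal(dim(f2$descriptors), dim(f$descriptors))
  expect_equal(f2$descriptors, f$descriptors, tolerance = 1e-8,
               ignore_attr = TRUE)
})
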