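# Mutual matching, FOV pruning, local re-matching.

test_that("identical descriptor sets match to themselves at distance zero", {
  set.seed(1)
  desc <- matrix(stats::runif(5 * 16), 5, 16)
  fa <- fs_from(matrix(stats::runif(15), 5, 3), desc)
  m <- mutual_match(fa, fa)
  expect_equal(m$idx_a, m$idx_b)
  expect_equal(sort(m$idx_a), 1:5)
  expect_true(all(m$distance < 1e-7))
})

test_that("one-directional matches are discarded", {
  # b1 is nearest to both a1 and a2, but b1's nearest is a1
  da <- rbind(c(0, 0), c(0.4, 0), c(5, 5))
  db <- rbind(c(0.1, 0), c(3, 3), c(5.1, 5))
  fa <- fs_from(matrix(0, 3, 3) + 1:3, da)
  fb <- fs_from(matrix(0, 3, 3) + 1:3, db)
  m <- mutual_match(fa, fb)
  expect_true(all(c(1, 3) %in% m$idx_a))
  expect_false(2 %in% m$idx_a)
  expect_equal(m$idx_b[m$idx_a == 1], 1)
})

test_that("matching with an empty feature set yields an empty match set", {
  fa <- fs_from(matrix(1:6, 2, 3), matrix(stats::runif(8), 2, 4))
  fe <- feature_set(fa$keypoints[0, ], fa$descriptors[0, , drop = FALSE])
  expect_equal(nrow(mutual_match(fa, fe)), 0)
  expect_equal(nrow(mutual_match(fe, fa)), 0)
})

test_that("blocked matching equals the brute-force oracle on random instances", {
  for (i in 1:50) {
    set.seed(i + 200)
    na <- sample(5:120, 1); nb <- sample(5:120, 1)
    k <- sample(c(8, 16, 32), 1)
    fa <- fs_from(matrix(stats::rnorm(na * 3), na, 3),
                  matrix(stats::rnorm(na * k), na, k))
    fb <- fs_from(matrix(stats::rnorm(nb * 3), nb, 3),
                  matrix(stats::rnorm(nb * k), nb, k))
    got <- mutual_match(fa, fb)
    want <- mutual_match_oracle(fa, fb)
    expect_equal(got$idx_a, want$idx_a)
    expect_equal(got$idx_b, want$idx_b)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("mutual matching is symmetric", {
  set.seed(3)
  fa <- fs_from(matrix(stats::rnorm(60), 20, 3), matrix(stats::rnorm(320), 20, 16))
  fb <- fs_from(matrix(stats::rnorm(45), 15, 3), matrix(stats::rnorm(240), 15, 16))
  mab <- mutual_match(fa, fb)
  mba <- mutual_match(fb, fa)
  expect_equal(mab$idx_a, mba$idx_b[match(mab$idx_b, mba$idx_a)])
})

test_that("FOV pruning keeps exactly the features inside the dilated box", {
  cbct <- rand_volume(dim = c(11, 11, 11), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0), seed = 4)  # box [0,20]^3
  margin <- 10
  eps <- 0.01
  pos <- rbind(c(10, 10, 10),                  # inside
               c(20 + margin - eps, 10, 10),   # margin - eps outside: kept
               c(20 + margin + eps, 10, 10),   # margin + eps outside: removed
               c(-margin - eps, 10, 10))       # removed on the low face
  f <- fs_from(pos, matrix(stats::runif(16), 4, 4))
  out <- prune_to_fov(f, cbct, affine_transform3d(), margin = margin)
  expect_equal(attr(out, "original_indices"), c(1L, 2L))
  expect_equal(nrow(out$keypoints), 2)
  # infinite margin keeps everything
  out_inf <- prune_to_fov(f, cbct, affine_transform3d(), margin = Inf)
  expect_equal(nrow(out_inf$keypoints), 4)
})

test_that("FOV pruning follows the transform", {
  cbct <- rand_volume(dim = c(11, 11, 11), spacing = c(2, 2, 2), seed = 5)
  tr <- affine_transform3d(diag(3), c(100, 0, 0))  # CBCT box maps to [100,120]
  f <- fs_from(rbind(c(110, 10, 10), c(10, 10, 10)),
               matrix(stats::runif(8), 2, 4))
  out <- prune_to_fov(f, cbct, tr, margin = 5)
  expect_equal(attr(out, "original_indices"), 1L)
})

test_that("local matching reduces to global matching at infinite radius", {
  set.seed(6)
  fa <- fs_from(matrix(stats::rnorm(60, sd = 30), 20, 3),
                matrix(stats::rnorm(320), 20, 16))
  fb <- fs_from(matrix(stats::rnorm(45, sd = 30), 15, 3),
                matrix(stats::rnorm(240), 15, 16))
  g <- mutual_match(fa, fb)
  l <- local_match(fa, fb, affine_transform3d(), radius = Inf)
  expect_equal(l, g)
})

test_that("correspondences beyond the search radius are rejected", {
  desc <- matrix(c(1, 0, 0, 1), 2, 2)
  fa <- fs_from(rbind(c(0, 0, 0), c(50, 0, 0)), desc)
  # identical descriptors, but displaced 12 mm from the transformed position
  fb_far <- fs_from(rbind(c(12, 0, 0), c(62, 0, 0)), desc)
  m_far <- local_match(fa, fb_far, affine_transform3d(), radius = 10)
  expect_equal(nrow(m_far), 0)
  fb_near <- fs_from(rbind(c(4, 0, 0), c(54, 0, 0)), desc)
  m_near <- local_match(fa, fb_near, affine_transform3d(), radius = 10)
  expect_equal(m_near$idx_a, 1:2)
  expect_equal(m_near$idx_b, 1:2)
})

test_that("a single in-radius pair is forced", {
  fa <- fs_from(c(1, 2, 3), matrix(c(0.6, 0.8), 1, 2))
  fb <- fs_from(c(2, 2, 3), matrix(c(0, 1), 1, 2))
  m <- local_match(fa, fb, affine_transform3d(), radius = 10)
  expect_equal(nrow(m), 1)
  expect_equal(m$idx_a, 1L)
})

test_that("every local match satisfies both radius constraints", {
  set.seed(7)
  tr <- affine_transform3d(rand_rotation(7) * 1.02, c(5, -3, 2))
  fa <- fs_from(matrix(stats::rnorm(300, sd = 40), 100, 3),
                matrix(stats::rnorm(100 * 8), 100, 8))
  fb <- fs_from(matrix(stats::rnorm(300, sd = 40), 100, 3),
                matrix(stats::rnorm(100 * 8), 100, 8))
  radius <- 25
  m <- local_match(fa, fb, tr, radius = radius)
  if (nrow(m) > 0) {
    pa <- as.matrix(fa$keypoints[m$idx_a, c("x", "y", "z")])
    pb <- as.matrix(fb$keypoints[m$idx_b, c("x", "y", "z")])
    fwd <- sqrt(rowSums((apply_transform(tr, pa) - pb)^2))
    bwd <- sqrt(rowSums((apply_transform(invert_affine(tr), pb) - pa)^2))
    expect_true(all(fwd <= radius))
    expect_true(all(bwd <= radius))
    # subset of the radius-restricted mutual-consistency relation: one-to-one
    expect_false(anyDuplicated(m$idx_a) > 0)
    expect_false(anyDuplicated(m$idx_b) > 0)
  }
})

test_that("match sets round-trip through CSV", {
  m <- match_set(c(3L, 1L), c(2L, 5L), c(0.25, 0.125))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matches(m, path)
  expect_equal(read_matches(path), m)
})
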