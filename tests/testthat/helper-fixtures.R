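# Shared fixtures: all test data is generated in code at run time.

# random-intensity volume with optional physical metadata
rand_volume <- function(dim = c(16, 16, 16), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), direction = diag(3), seed = 1) {
  set.seed(seed)
  volume3d(array(stats::runif(prod(dim)), dim = dim), spacing = spacing,
           origin = origin, direction = direction)
}

# random proper rotation matrix
rand_rotation <- function(seed = 1) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  siftreg:::rotation_matrix(axis, stats::runif(1, 0, pi))
}

# band-limited random texture volume: white noise smoothed at sigma voxels,
# rescaled to [0, 1]
textured_volume <- function(n = 64, spacing = 1.5, sigma = 2, seed = 1) {
  set.seed(seed)
  d <- rep(as.integer(n), 3)
  x <- siftreg:::cpp_gauss_smooth(stats::rnorm(prod(d)), d, sigma)
  x <- (x - min(x)) / (max(x) - min(x))
  volume3d(array(x, dim = d), spacing = rep(spacing, 3))
}

# isotropic Gaussian blob (amplitude 1) at physical centre `at`
blob_volume <- function(n = 64, spacing = 1, at = c(30.5, 32, 31),
                        sigma_blob = 4) {
  d <- rep(as.integer(n), 3)
  g <- (seq_len(n) - 1) * spacing
  gx <- outer(outer(exp(-(g - at[1])^2 / (2 * sigma_blob^2)),
                    exp(-(g - at[2])^2 / (2 * sigma_blob^2))),
              exp(-(g - at[3])^2 / (2 * sigma_blob^2)))
  volume3d(array(gx, dim = d), spacing = rep(spacing, 3))
}

# feature set from bare coordinates + descriptor matrix
fs_from <- function(pos, desc) {
  pos <- matrix(pos, ncol = 3)
  feature_set(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         scale = 2, response = 0.1),
              matrix(desc, nrow = nrow(pos)))
}

# reduced-size phantom spec: same structure as the default study conditions,
# scaled down so repeated pipeline runs stay fast
small_phantom_spec <- function(seed, ...) {
  args <- list(ct_extent = c(270, 270, 300), ct_spacing = 2,
               cbct_fov = c(180, 160), cbct_spacing = 2,
               max_translation = 20, n_texture_blobs = 5000L,
               n_vertebrae = 7L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

# fast pipeline configuration matched to the 2 mm small phantoms
fast_config <- function(...) {
  registration_config(working_spacing = 2, ...)
}

# brute-force mutual nearest-neighbour oracle: plain per-row scans,
# independent of the blocked BLAS implementation path
mutual_match_oracle <- function(fa, fb) {
  da <- fa$descriptors; db <- fb$descriptors
  if (nrow(da) == 0 || nrow(db) == 0)
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      distance = numeric()))
  nn_of <- function(v, m) {
    d <- sqrt(colSums((t(m) - v)^2))
    which.min(d)  # ties: lowest index
  }
  fwd <- vapply(seq_len(nrow(da)), function(i) nn_of(da[i, ], db), 1L)
  bwd <- vapply(seq_len(nrow(db)), function(j) nn_of(db[j, ], da), 1L)
  keep <- which(bwd[fwd] == seq_len(nrow(da)))
  d <- vapply(keep, function(i) sqrt(sum((da[i, ] - db[fwd[i], ])^2)), 0)
  out <- data.frame(idx_a = keep, idx_b = fwd[keep], distance = d)
  out[order(out$distance, out$idx_a), ]
}

# simulated correspondences: n_in inliers under a known affine (+ noise) and
# n_out uniform outliers in a box
ransac_instance <- function(seed, n_in = 60, n_out = 40, noise = 1,
                            box = 200) {
  set.seed(seed)
  R <- rand_rotation(seed + 1000)
  t <- stats::runif(3, -30, 30)
  src <- matrix(stats::runif(3 * (n_in + n_out), -box / 2, box / 2), ncol = 3)
  dst <- src %*% t(R) + matrix(t, n_in + n_out, 3, byrow = TRUE)
  dst[seq_len(n_in), ] <- dst[seq_len(n_in), ] +
    matrix(stats::rnorm(3 * n_in, 0, noise), ncol = 3)
  dst[n_in + seq_len(n_out), ] <-
    matrix(stats::runif(3 * n_out, -box / 2, box / 2), ncol = 3)
  list(src = src, dst = dst, R = R, t = t, inlier = seq_len(n_in))
}
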