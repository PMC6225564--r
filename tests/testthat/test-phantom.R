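# Synthetic CT/CBCT phantom generator.

test_that("generation is deterministic for a fixed seed", {
  p1 <- generate_phantom_pair(small_phantom_spec(seed = 21))
  p2 <- generate_phantom_pair(small_phantom_spec(seed = 21))
  expect_identical(p1$ct$data, p2$ct$data)
  expect_identical(p1$cbct$data, p2$cbct$data)
  expect_identical(p1$landmarks_cbct, p2$landmarks_cbct)
  p3 <- generate_phantom_pair(small_phantom_spec(seed = 22))
  expect_false(identical(p1$cbct$data, p3$cbct$data))
})

test_that("the default-spec pair matches the clinical geometry it emulates", {
  pair <- generate_phantom_pair(phantom_spec(seed = 31))
  ct_ext <- dim(pair$ct$data) * pair$ct$spacing
  cb_ext <- dim(pair$cbct$data) * pair$cbct$spacing
  # CBCT physical extent ~ 250 x 250 x 190 mm; the CT covers ~3x the
  # CBCT's size (volume ratio; ~6x here against the inscribed cylinder)
  expect_equal(cb_ext, c(250, 250, 190), tolerance = 0.02)
  expect_gte(prod(ct_ext) / prod(cb_ext), 3)

  # the stored true map reproduces each landmark pair to 1e-6 mm
  mapped <- pair$true_map(as.matrix(pair$landmarks_cbct[, c("x", "y", "z")]))
  gap <- sqrt(rowSums((mapped - as.matrix(pair$landmarks_ct[, c("x", "y", "z")]))^2))
  expect_lt(max(gap), 1e-6)

  # >= 6 paired landmarks, all CBCT landmarks inside the cylindrical FOV
  expect_gte(nrow(pair$landmarks_cbct), 6)
  expect_identical(pair$landmarks_cbct$label, pair$landmarks_ct$label)
  r <- sqrt(pair$landmarks_cbct$x^2 + pair$landmarks_cbct$y^2)
  expect_true(all(r <= 125 & abs(pair$landmarks_cbct$z) <= 95))

  # pose change within the requested bounds
  A <- pair$true_affine$linear
  expect_lt(abs(det(A)) - 1, 0.1)
  expect_lte(sqrt(sum(pair$true_affine$translation^2)), 30 + 1e-9)

  # the aorta is contrast-filled only in the CT: compare the mean intensity
  # inside the tube against the CT scene without contrast
  ax <- pair$scene$aorta
  pts <- cbind(ax$cx, ax$cy, seq(-60, 60, by = 4))
  with_c <- siftreg:::scene_eval(pair$scene, pts, contrast = TRUE)
  no_c <- siftreg:::scene_eval(pair$scene, pts, contrast = FALSE)
  expect_gt(mean(with_c - no_c), 0.3)

  ## ground-truth residual field (cross-module consistency)
  expect_equal(max(true_error_field(pair, pair$true_map,
                                    matrix(stats::runif(60, -40, 40), 20, 3))), 0)
  shifted <- function(p) pair$true_map(p) + matrix(c(2, 0, 0), nrow(p), 3,
                                                   byrow = TRUE)
  expect_equal(true_error_field(pair, shifted,
                                matrix(stats::runif(30, -40, 40), 10, 3)),
               rep(2, 10), tolerance = 1e-12)
  est <- pair$true_affine   # any estimate: both routes must agree exactly
  e_lm <- landmark_errors(pair$landmarks_cbct, pair$landmarks_ct, est)
  e_tf <- true_error_field(pair, est,
                           as.matrix(pair$landmarks_cbct[, c("x", "y", "z")]))
  expect_equal(unname(e_lm), e_tf, tolerance = 1e-9)
})

test_that("an identity-pose noiseless phantom crops the CT into the CBCT", {
  # no pose change, no warp, no intensity mismatch, and no aorta contrast
  # (the contrast-filled lumen is deliberately absent from every CBCT)
  sp <- small_phantom_spec(seed = 23, max_rotation_deg = 0,
                           max_translation = 0, max_scale = 0,
                           nonlinear_amplitude = 0, intensity_gain = 1,
                           intensity_offset = 0, noise_sd = 0,
                           include_aorta_contrast = FALSE)
  pair <- generate_phantom_pair(sp)
  resampled <- resample_into(pair$ct, pair$cbct)
  # compare inside the cylinder (outside it the CBCT is zero by construction)
  q <- voxel_to_physical(pair$cbct,
                         as.matrix(expand.grid(0:(dim(pair$cbct$data)[1] - 1),
                                               0:(dim(pair$cbct$data)[2] - 1),
                                               0:(dim(pair$cbct$data)[3] - 1))))
  inside <- sqrt(q[, 1]^2 + q[, 2]^2) <= sp$cbct_fov[1] / 2 - 2 &
    abs(q[, 3]) <= sp$cbct_fov[2] / 2 - 2
  dif <- abs(pair$cbct$data - resampled$data)[array(inside, dim(pair$cbct$data))]
  # away from structure edges the two constructions agree exactly; the
  # largest differences sit at calcification edges, which are sharper than
  # a voxel and so cannot be reproduced by trilinear resampling
  expect_equal(stats::median(dif), 0)
  expect_lt(mean(dif), 0.01)
  expect_lt(stats::quantile(dif, 0.99), 0.1)
  expect_lt(max(dif), 1)
})

test_that("the smooth warp respects its amplitude cap", {
  pair <- generate_phantom_pair(small_phantom_spec(seed = 24))
  warp <- attr(pair$true_map, "warp")
  expect_lte(length(warp$sigma), 5)
  expect_true(all(warp$sigma >= 40))
  set.seed(1)
  pts <- matrix(stats::runif(3000, -90, 90), ncol = 3)
  disp <- sqrt(rowSums(siftreg:::warp_displacement(warp, pts)^2))
  expect_lte(max(disp), 5 * 1.02)  # peak calibrated on a 10 mm grid
  expect_gt(max(disp), 0.5)   # the warp is actually present
})

test_that("an invalid spec fails before any generation", {
  expect_error(phantom_spec(cbct_fov = c(900, 800)), "cannot fit")
  expect_error(phantom_spec(n_calcifications = 2))
  expect_error(phantom_spec(nonlinear_amplitude = -1))
})
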