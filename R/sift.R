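## 3D SIFT: scale-space keypoint detection and gradient-histogram descriptors.
##
## The detector is the classic difference-of-Gaussians pipeline lifted to
## three dimensions: an octave pyramid of Gaussian-smoothed grids, strict
## extremum tests over the 80-voxel scale-space neighbourhood, quadratic
## sub-voxel refinement, a contrast test on the interpolated response and a
## Hessian-based plate/edge rejection. Descriptors are gradient histograms
## over 4x4x4 spatial subregions with 12 solid-angle orientation bins
## (length 768), clipped at 0.2 and renormalised to unit length. No
## per-keypoint orientation frame is assigned: pose differences between the
## two acquisitions are small rotations that the affine RANSAC absorbs.

DESCRIPTOR_SUBREGIONS <- 4L      # spatial subregions per axis
DESCRIPTOR_ORIENTATIONS <- 12L   # solid-angle bins (icosahedron vertices)
DESCRIPTOR_LENGTH <- DESCRIPTOR_SUBREGIONS^3 * DESCRIPTOR_ORIENTATIONS
DESCRIPTOR_CLIP <- 0.2

# Unit vectors to the 12 vertices of a regular icosahedron.
icosahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c(1,  phi, 0),  c(-1,  phi, 0), c(1, -phi, 0),  c(-1, -phi, 0),
    c(phi, 0,  1),  c(phi, 0, -1),  c(-phi, 0,  1), c(-phi, 0, -1))
  t(v / sqrt(rowSums(v^2)))
}

#' Robust intensity normalization to [0, 1]
#'
#' Clips at the lower/upper intensity percentiles and rescales linearly, so
#' that the two modalities (HU-like CT, uncalibrated cone-beam CT) share a
#' common intensity range before feature detection. Invariant to positive
#' affine intensity maps whose effect stays within the clip range.
#'
#' @param volume a [volume3d] with more than one distinct intensity.
#' @param lower,upper clip percentiles in `[0, 1]` (defaults 0.01 / 0.99).
#' @return A [volume3d] with intensities in `[0, 1]`; metadata unchanged.
#' @export
normalize_intensities <- function(volume, lower = 0.01, upper = 0.99) {
  stopifnot(inherits(volume, "volume3d"), lower < upper)
  q <- stats::quantile(volume$data, c(lower, upper), names = FALSE, type = 7)
  if (q[2] - q[1] <= 0)
    stop("degenerate input: volume is constant over the clip range")
  x <- (volume$data - q[1]) / (q[2] - q[1])
  x[x < 0] <- 0
  x[x > 1] <- 1
  volume3d(x, volume$spacing, volume$origin, volume$direction)
}

#' Build a 3D difference-of-Gaussians scale-space pyramid
#'
#' Octaves are downsampled by 2; within each octave, `levels_per_octave + 3`
#' Gaussian levels are generated with sigma multiplied by
#' `2^(1/levels_per_octave)` per level, and adjacent levels are differenced.
#' The input grid is assumed to carry a nominal blur of 0.5 voxel.
#'
#' @param volume a [volume3d], normally isotropic and intensity-normalized.
#' @param n_octaves number of octaves, or `NULL` to continue while the
#'   smallest axis has at least 16 voxels.
#' @param levels_per_octave DoG sampling density per octave (default 3).
#' @param sigma0 base scale in voxels of the input grid (default 1.6).
#' @return An object of class `scale_space`: per octave, the Gaussian grids,
#'   the DoG grids, dims, and absolute sigma of every level in voxels and mm.
#' @export
build_scale_space <- function(volume, n_octaves = NULL, levels_per_octave = 3L,
                              sigma0 = 1.6) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$data)
  if (min(d) < 8L)
    stop("volume too small for a scale-space pyramid: axis ", which.min(d),
         " has ", min(d), " voxels (< 8)")
  if (max(abs(volume$spacing - volume$spacing[1])) > 1e-9 * volume$spacing[1])
    warning("scale space on an anisotropic grid: sigma in mm uses the first ",
            "spacing component; resample to isotropic first")
  s <- as.integer(levels_per_octave)
  nlev <- s + 3L
  max_oct <- max(1L, floor(log2(min(d) / 8)) + 1L)
  if (is.null(n_octaves)) n_octaves <- max_oct else
    n_octaves <- min(as.integer(n_octaves), max_oct)

  base <- as.numeric(volume$data)
  # lift the nominal 0.5-voxel blur of the sampled grid up to sigma0
  pre <- sqrt(max(sigma0^2 - 0.25, 0))
  if (pre > 0) base <- cpp_gauss_smooth(base, d, pre)

  octaves <- vector("list", n_octaves)
  cur <- base
  curd <- d
  for (o in seq_len(n_octaves)) {
    sig_oct <- sigma0 * 2^((seq_len(nlev) - 1) / s)  # octave-grid voxels
    gauss <- vector("list", nlev)
    gauss[[1]] <- cur
    for (l in 2:nlev) {
      inc <- sqrt(sig_oct[l]^2 - sig_oct[l - 1]^2)
      gauss[[l]] <- cpp_gauss_smooth(gauss[[l - 1]], curd, inc)
    }
    dog <- vector("list", nlev - 1L)
    for (l in seq_len(nlev - 1L)) dog[[l]] <- gauss[[l + 1]] - gauss[[l]]
    octaves[[o]] <- list(
      gauss = gauss, dog = dog, dim = curd,
      sigma_vox = sig_oct,
      sigma_mm = sig_oct * 2^(o - 1) * volume$spacing[1])
    if (o < n_octaves) {
      cur <- cpp_downsample2(gauss[[s + 1L]], curd)  # sigma there = 2*sigma0
      curd <- (curd + 1L) %/% 2L
    }
  }
  structure(list(octaves = octaves, levels_per_octave = s, sigma0 = sigma0,
                 spacing = volume$spacing[1], origin = volume$origin,
                 direction = volume$direction, base_dim = d),
            class = "scale_space")
}

#' Detect scale-space keypoints
#'
#' Keypoints are strict local extrema of the DoG grids over their 3x3x3x3
#' scale-space neighbourhood, refined to sub-voxel position and scale by a
#' quadratic fit, kept when the interpolated |response| reaches
#' `contrast_threshold` and the spatial Hessian passes a plate/edge test
#' (same-sign curvatures with eigenvalue anisotropy at most `edge_threshold`).
#'
#' @param pyramid a [build_scale_space()] result.
#' @param contrast_threshold minimum |DoG| response on normalized intensities.
#' @param edge_threshold maximum ratio of largest to smallest absolute
#'   spatial-Hessian eigenvalue.
#' @param max_features keep at most this many keypoints (largest |response|).
#' @return A data frame with one row per keypoint: physical position
#'   `x, y, z` (mm), `scale` (mm), `response`, `octave`, `level`, and the
#'   continuous voxel position on the octave grid (`vx, vy, vz`).
#' @export
detect_keypoints <- function(pyramid, contrast_threshold = 0.02,
                             edge_threshold = 10, max_features = 20000L) {
  stopifnot(inherits(pyramid, "scale_space"))
  s <- pyramid$levels_per_octave
  res <- vector("list", length(pyramid$octaves))
  for (o in seq_along(pyramid$octaves)) {
    oct <- pyramid$octaves[[o]]
    cand <- cpp_dog_extrema(oct$dog, oct$dim, 0.8 * contrast_threshold)
    if (nrow(cand) == 0L) next
    ref <- cpp_refine_keypoints(oct$dog, oct$dim, cand,
                                contrast_threshold, edge_threshold)
    ref <- ref[ref[, 6] > 0, , drop = FALSE]
    if (nrow(ref) == 0L) next
    vox <- ref[, 1:3, drop = FALSE]
    base_vox <- vox * 2^(o - 1)
    vol_meta <- list(spacing = rep(pyramid$spacing, 3), origin = pyramid$origin,
                     direction = pyramid$direction)
    pos <- sweep(sweep(base_vox, 2, vol_meta$spacing, `*`) %*%
                   t(vol_meta$direction), 2, vol_meta$origin, `+`)
    scale_mm <- pyramid$sigma0 * 2^((o - 1) + ref[, 4] / s) * pyramid$spacing
    res[[o]] <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      scale = scale_mm, response = ref[, 5],
      octave = o, level = ref[, 4],
      vx = vox[, 1], vy = vox[, 2], vz = vox[, 3])
  }
  kp <- do.call(rbind, res)
  if (is.null(kp)) {
    kp <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                     scale = numeric(), response = numeric(),
                     octave = integer(), level = numeric(),
                     vx = numeric(), vy = numeric(), vz = numeric())
    return(kp)
  }
  # deterministic order: by |response| descending, position as tie-break
  ord <- order(-abs(kp$response), kp$x, kp$y, kp$z, kp$scale)
  kp <- kp[ord, , drop = FALSE]
  if (nrow(kp) > max_features) kp <- kp[seq_len(max_features), , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

#' Compute descriptors for detected keypoints
#'
#' Gradients of the Gaussian level nearest each keypoint's scale are
#' accumulated into a 4x4x4 spatial x 12 orientation histogram over a window
#' proportional to scale (subregion width 3 sigma), trilinearly shared
#' between adjacent subregions and Gaussian-weighted over the window, then
#' clipped at 0.2 per bin and renormalised to unit Euclidean norm. Keypoints
#' whose window lies fully outside the grid are dropped.
#'
#' @param pyramid the [build_scale_space()] result the keypoints came from.
#' @param keypoints a [detect_keypoints()] data frame.
#' @return A `feature_set`: list with `keypoints` (data frame) and
#'   `descriptors` (matrix, one unit-norm or all-zero row per keypoint).
#' @export
compute_descriptors <- function(pyramid, keypoints) {
  stopifnot(inherits(pyramid, "scale_space"))
  n <- nrow(keypoints)
  dirs <- icosahedron_directions()
  desc <- matrix(0, n, DESCRIPTOR_LENGTH)
  keep <- rep(FALSE, n)
  if (n > 0) {
    s <- pyramid$levels_per_octave
    lev_idx <- pmin(pmax(round(keypoints$level), 0), s + 2) # Gaussian level
    for (o in unique(keypoints$octave)) {
      oct <- pyramid$octaves[[o]]
      for (l in unique(lev_idx[keypoints$octave == o])) {
        sel <- which(keypoints$octave == o & lev_idx == l)
        coords <- as.matrix(keypoints[sel, c("vx", "vy", "vz")])
        r <- cpp_descriptors(oct$gauss[[l + 1L]], oct$dim, coords,
                             oct$sigma_vox[l + 1L], dirs,
                             DESCRIPTOR_SUBREGIONS, DESCRIPTOR_CLIP)
        desc[sel, ] <- r$descriptors
        keep[sel] <- r$keep
      }
    }
  }
  feature_set(keypoints[keep, , drop = FALSE], desc[keep, , drop = FALSE])
}

#' Construct a feature set
#'
#' @param keypoints data frame with at least columns `x, y, z, scale,
#'   response` (mm / DoG units).
#' @param descriptors numeric matrix, one row per keypoint; each row has unit
#'   Euclidean norm or is all zero.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(keypoints, descriptors) {
  descriptors <- as.matrix(descriptors)
  if (nrow(keypoints) != nrow(descriptors))
    stop("keypoints and descriptors must be index-aligned")
  rownames(keypoints) <- NULL
  structure(list(keypoints = keypoints, descriptors = descriptors),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set: ", nrow(x$keypoints), " keypoints, descriptor length ",
      ncol(x$descriptors), "\n", sep = "")
  if (nrow(x$keypoints) > 0)
    cat("  scale range (mm):",
        paste(signif(range(x$keypoints$scale), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
length.feature_set <- function(x) nrow(x$keypoints)

#' Detect and describe features in one volume
#'
#' Convenience wrapper: intensity normalization, resampling to an isotropic
#' working grid, scale-space construction, keypoint detection and descriptor
#' computation. Keypoint positions are physical (mm), so features from grids
#' of different resolution are directly comparable.
#'
#' @param volume a [volume3d].
#' @param working_spacing isotropic working resolution in mm (default 1.5).
#' @param sigma0,levels_per_octave,contrast_threshold,edge_threshold,max_features
#'   detector parameters, see [build_scale_space()] and [detect_keypoints()].
#' @param normalize_percentiles length-2 clip percentiles for
#'   [normalize_intensities()].
#' @return A `feature_set`.
#' @export
detect_features <- function(volume, working_spacing = 1.5, sigma0 = 1.6,
                            levels_per_octave = 3L, contrast_threshold = 0.02,
                            edge_threshold = 10, max_features = 20000L,
                            normalize_percentiles = c(0.01, 0.99)) {
  v <- normalize_intensities(volume, normalize_percentiles[1],
                             normalize_percentiles[2])
  if (max(abs(v$spacing - working_spacing)) > 1e-9)
    v <- resample_isotropic(v, working_spacing)
  pyr <- build_scale_space(v, levels_per_octave = levels_per_octave,
                           sigma0 = sigma0)
  kp <- detect_keypoints(pyr, contrast_threshold, edge_threshold, max_features)
  compute_descriptors(pyr, kp)
}

#' Write a feature set to CSV
#'
#' Columns: `x,y,z,scale,response,d0..d{K-1}`.
#' @param features a `feature_set`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  k <- ncol(features$descriptors)
  df <- cbind(features$keypoints[, c("x", "y", "z", "scale", "response")],
              as.data.frame(features$descriptors))
  names(df) <- c("x", "y", "z", "scale", "response",
                 paste0("d", seq_len(k) - 1L))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature set written by [write_features()]
#' @param path CSV path.
#' @return A `feature_set`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  dcols <- grep("^d[0-9]+$", names(df))
  feature_set(df[, c("x", "y", "z", "scale", "response")],
              as.matrix(df[, dcols, drop = FALSE]))
}
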