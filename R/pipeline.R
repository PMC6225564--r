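## Two-stage feature-based registration pipeline.
##
## Stage 1: detect and describe 3D SIFT features in both volumes, match by
## mutual nearest-neighbour descriptor distance, and estimate a robust
## affine CBCT->CT transform with RANSAC at a high (10 mm) inlier threshold
## that tolerates the true nonlinear deformation. Stage 2: prune CT features
## outside the transformed CBCT field of view (plus a small margin),
## re-match with a transform-guided 10 mm local search, and re-run RANSAC
## at a tight 5 mm threshold. A thin-plate spline fitted on the stage-2
## inliers is the final map.

#' Registration configuration
#'
#' All distances are in physical mm, so the settings are independent of the
#' voxel grids.
#'
#' @param stage1_threshold RANSAC inlier threshold of the global stage (mm;
#'   default 10, deliberately high to absorb nonlinear deformation).
#' @param stage2_threshold RANSAC threshold of the local stage (mm; default
#'   5; must not exceed `stage1_threshold`).
#' @param local_radius local re-matching search radius (mm; default 10).
#' @param fov_margin dilation of the transformed CBCT field of view used to
#'   prune CT features (mm; default 10).
#' @param fov_shape `"box"` (default) or `"cylinder"`, see [prune_to_fov()].
#' @param working_spacing isotropic feature-extraction resolution (mm).
#' @param sigma0,levels_per_octave,contrast_threshold,edge_threshold,max_features
#'   detector settings, see [detect_features()].
#' @param normalize_percentiles robust intensity-normalization clip range.
#' @param ransac_confidence,ransac_max_iterations RANSAC schedule.
#' @param cbct_support_margin CBCT features closer than this multiple of
#'   their scale to the empty reconstruction background are dropped before
#'   matching (see [filter_background_support()]); 0 disables.
#' @param tps_regularization thin-plate-spline smoothing scale in mm
#'   (default 200). The stage-2 correspondences carry voxel-scale
#'   localization noise; with hundreds of control points an interpolating
#'   spline transfers that noise into the map, while smoothing on the
#'   kernel's mm scale keeps the smooth deformation trends. Set 0 for a
#'   pure interpolating spline.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(stage1_threshold = 10, stage2_threshold = 5,
                                local_radius = 10, fov_margin = 10,
                                fov_shape = "box", working_spacing = 1.5,
                                sigma0 = 1.6, levels_per_octave = 3L,
                                contrast_threshold = 0.02,
                                edge_threshold = 10, max_features = 20000L,
                                normalize_percentiles = c(0.01, 0.99),
                                ransac_confidence = 0.99,
                                ransac_max_iterations = 10000L,
                                tps_regularization = 200,
                                cbct_support_margin = 3) {
  stopifnot(stage1_threshold > 0, stage2_threshold > 0,
            stage2_threshold <= stage1_threshold, local_radius > 0,
            fov_margin > 0, working_spacing > 0, tps_regularization >= 0)
  structure(list(stage1_threshold = stage1_threshold,
                 stage2_threshold = stage2_threshold,
                 local_radius = local_radius, fov_margin = fov_margin,
                 fov_shape = fov_shape, working_spacing = working_spacing,
                 sigma0 = sigma0, levels_per_octave = levels_per_octave,
                 contrast_threshold = contrast_threshold,
                 edge_threshold = edge_threshold,
                 max_features = max_features,
                 normalize_percentiles = normalize_percentiles,
                 ransac_confidence = ransac_confidence,
                 ransac_max_iterations = ransac_max_iterations,
                 tps_regularization = tps_regularization,
                 cbct_support_margin = cbct_support_margin),
            class = "registration_config")
}

#' Load a registration configuration from JSON
#'
#' Unspecified keys take the [registration_config()] defaults.
#' @param path JSON file path.
#' @return A `registration_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(registration_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(registration_config, obj)
}

fail_result <- function(stage, counts, partial) {
  structure(c(list(status = "failure", failed_stage = stage, counts = counts),
              partial),
            class = "cbct_registration")
}

#' Register a CBCT volume to a CT volume
#'
#' Runs the full two-stage feature-based pipeline and returns the estimated
#' transforms with per-stage diagnostics. All estimated maps send CBCT
#' physical points to CT physical points. The run is deterministic for a
#' fixed `seed`.
#'
#' @param ct large field-of-view [volume3d] (e.g. CT angiography).
#' @param cbct small field-of-view [volume3d] (e.g. cone-beam CT).
#' @param config a [registration_config()].
#' @param seed integer seed for the RANSAC sampling.
#' @param features optional precomputed list `list(ct =, cbct =)` of
#'   `feature_set` objects (skips detection; used mainly by tests).
#' @return An object of class `cbct_registration` with fields
#'   `status` ("success"/"failure"), `failed_stage` (on failure),
#'   `affine_stage1`, `affine_stage2`, `tps`, `counts` (features per volume,
#'   mutual matches, stage-1 inliers, pruned CT features, local matches,
#'   stage-2 inliers), per-stage `ransac` results, the stage-2 inlier
#'   correspondences, and the `config` and `seed` used.
#' @export
register_volumes <- function(ct, cbct, config = registration_config(),
                             seed = 1L, features = NULL) {
  stopifnot(inherits(ct, "volume3d"), inherits(cbct, "volume3d"),
            inherits(config, "registration_config"))
  counts <- list()
  if (is.null(features)) {
    feat_ct <- detect_features(
      ct, working_spacing = config$working_spacing, sigma0 = config$sigma0,
      levels_per_octave = config$levels_per_octave,
      contrast_threshold = config$contrast_threshold,
      edge_threshold = config$edge_threshold,
      max_features = config$max_features,
      normalize_percentiles = config$normalize_percentiles)
    feat_cbct <- detect_features(
      cbct, working_spacing = config$working_spacing, sigma0 = config$sigma0,
      levels_per_octave = config$levels_per_octave,
      contrast_threshold = config$contrast_threshold,
      edge_threshold = config$edge_threshold,
      max_features = config$max_features,
      normalize_percentiles = config$normalize_percentiles)
  } else {
    feat_ct <- features$ct
    feat_cbct <- features$cbct
  }
  feat_cbct <- filter_background_support(feat_cbct, cbct,
                                         k = config$cbct_support_margin)
  counts$features_ct <- nrow(feat_ct$keypoints)
  counts$features_cbct <- nrow(feat_cbct$keypoints)
  partial <- list(features = list(ct = feat_ct, cbct = feat_cbct),
                  config = config, seed = seed)
  if (counts$features_ct < 4L || counts$features_cbct < 4L)
    return(fail_result("feature_detection", counts, partial))

  # stage 1: global mutual matching + permissive RANSAC
  m1 <- mutual_match(feat_cbct, feat_ct)
  counts$mutual_matches <- nrow(m1)
  if (nrow(m1) < 4L) return(fail_result("mutual_match", counts, partial))
  pa <- as.matrix(feat_cbct$keypoints[m1$idx_a, c("x", "y", "z")])
  pb <- as.matrix(feat_ct$keypoints[m1$idx_b, c("x", "y", "z")])
  r1 <- ransac_affine(pa, pb, threshold = config$stage1_threshold,
                      confidence = config$ransac_confidence,
                      max_iterations = config$ransac_max_iterations,
                      seed = seed)
  counts$stage1_inliers <- r1$n_inliers
  partial$ransac_stage1 <- r1
  if (!r1$success) return(fail_result("ransac_stage1", counts, partial))
  affine1 <- r1$transform

  # stage 2: FOV pruning, local re-matching, tight RANSAC
  feat_ct_pruned <- prune_to_fov(feat_ct, cbct, affine1,
                                 margin = config$fov_margin,
                                 shape = config$fov_shape)
  counts$pruned_ct_features <- nrow(feat_ct_pruned$keypoints)
  if (counts$pruned_ct_features < 4L)
    return(fail_result("fov_pruning", counts,
                       c(partial, list(affine_stage1 = affine1))))
  m2 <- local_match(feat_cbct, feat_ct_pruned, affine1,
                    radius = config$local_radius)
  counts$local_matches <- nrow(m2)
  if (nrow(m2) < 4L)
    return(fail_result("local_match", counts,
                       c(partial, list(affine_stage1 = affine1))))
  qa <- as.matrix(feat_cbct$keypoints[m2$idx_a, c("x", "y", "z")])
  qb <- as.matrix(feat_ct_pruned$keypoints[m2$idx_b, c("x", "y", "z")])
  r2 <- ransac_affine(qa, qb, threshold = config$stage2_threshold,
                      confidence = config$ransac_confidence,
                      max_iterations = config$ransac_max_iterations,
                      seed = seed + 1L)
  counts$stage2_inliers <- r2$n_inliers
  partial$ransac_stage2 <- r2
  if (!r2$success)
    return(fail_result("ransac_stage2", counts,
                       c(partial, list(affine_stage1 = affine1))))
  affine2 <- r2$transform

  # final map: thin-plate spline on the stage-2 inlier correspondences
  src <- qa[r2$inlier_mask, , drop = FALSE]
  dst <- qb[r2$inlier_mask, , drop = FALSE]
  dup <- duplicated(round(src / 1e-6))
  src <- src[!dup, , drop = FALSE]
  dst <- dst[!dup, , drop = FALSE]
  tps <- tryCatch(fit_tps(src, dst, regularization = config$tps_regularization),
                  error = function(e) NULL)
  if (is.null(tps))
    return(fail_result("tps_fit", counts,
                       c(partial, list(affine_stage1 = affine1,
                                       affine_stage2 = affine2))))

  structure(c(list(status = "success", failed_stage = NULL, counts = counts,
                   affine_stage1 = affine1, affine_stage2 = affine2,
                   tps = tps,
                   inlier_src = src, inlier_dst = dst),
              partial),
            class = "cbct_registration")
}

#' @export
print.cbct_registration <- function(x, ...) {
  cat("cbct_registration:", x$status)
  if (x$status != "success") cat(" at stage", x$failed_stage)
  cat("\n")
  cn <- c(features_ct = "CT features", features_cbct = "CBCT features",
          mutual_matches = "mutual matches", stage1_inliers = "stage-1 inliers",
          pruned_ct_features = "CT features in FOV",
          local_matches = "local matches", stage2_inliers = "stage-2 inliers")
  for (k in names(cn))
    if (!is.null(x$counts[[k]])) cat(sprintf("  %-20s %d\n", cn[k], x$counts[[k]]))
  if (x$status == "success")
    cat("  final map: thin-plate spline on", nrow(x$tps$control_points),
        "control points\n")
  invisible(x)
}

#' @export
summary.cbct_registration <- function(object, ...) {
  print(object)
  if (object$status == "success") {
    res <- residuals(object)
    cat("stage-2 inlier residuals under the final map (mm):\n")
    print(summary(res))
    print(object$affine_stage2)
  }
  invisible(object)
}

#' @export
residuals.cbct_registration <- function(object, ...) {
  if (object$status != "success")
    stop("no residuals: registration failed at stage ", object$failed_stage)
  sqrt(rowSums((apply_transform(object$tps, object$inlier_src) -
                  object$inlier_dst)^2))
}

#' @export
coef.cbct_registration <- function(object, ...) {
  if (object$status != "success") stop("registration failed")
  cbind(object$affine_stage2$linear, object$affine_stage2$translation)
}

#' Transform CBCT-space points with a fitted registration
#'
#' @param object a successful [register_volumes()] result.
#' @param newdata n x 3 matrix (or length-3 vector) of CBCT physical points.
#' @param map which estimated map to apply: the final `"tps"` (default),
#'   `"affine_stage2"`, or `"affine_stage1"`.
#' @param ... unused.
#' @return n x 3 matrix of CT physical points.
#' @export
predict.cbct_registration <- function(object, newdata,
                                      map = c("tps", "affine_stage2",
                                              "affine_stage1"), ...) {
  map <- match.arg(map)
  tr <- object[[map]]
  if (is.null(tr))
    stop("map '", map, "' was not estimated (failed at stage ",
         object$failed_stage, ")")
  apply_transform(tr, newdata)
}

#' Plot the inlier-residual cumulative curve of a registration
#'
#' @param x a successful [register_volumes()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cbct_registration <- function(x, ...) {
  res <- residuals(x)
  cc <- cumulative_curve(res)
  graphics::plot(cc$thresholds, 100 * cc$fraction, type = "s",
                 xlab = "residual (mm)", ylab = "cumulative % of inliers",
                 main = "stage-2 inlier residuals under the final map", ...)
  invisible(x)
}

## ---- fusion ----------------------------------------------------------------

# Numerically invert the final map at CT-space points: Newton iteration with
# the stage-2 affine linear part as Jacobian, affine-inverse initialisation.
invert_final_map <- function(result, pts, tol = 0.05, max_iter = 20L) {
  inv2 <- invert_affine(result$affine_stage2)
  q <- apply_transform(inv2, pts)
  active <- rep(TRUE, nrow(q))
  for (i in seq_len(max_iter)) {
    if (!any(active)) break
    r <- apply_transform(result$tps, q[active, , drop = FALSE]) -
      pts[active, , drop = FALSE]
    conv <- sqrt(rowSums(r^2)) < tol
    q[active, ] <- q[active, , drop = FALSE] - r %*% t(inv2$linear)
    active[active] <- !conv
  }
  if (any(active))  # non-converged voxels fall back to the affine inverse
    q[active, ] <- apply_transform(inv2, pts[active, , drop = FALSE])
  list(points = q, n_fallback = sum(active))
}

#' Fuse a registered CBCT into the CT grid
#'
#' Resamples the CBCT through the numerical inverse of the final
#' thin-plate-spline map onto the CT grid (per-voxel Newton iteration
#' initialised at the stage-2 affine inverse; voxels where the iteration
#' does not converge fall back to the affine inverse, with a warning when
#' they exceed 1 percent).
#'
#' @param ct,cbct the volumes that were registered.
#' @param result a successful [register_volumes()] result.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill fill value outside the CBCT (default 0).
#' @return A [volume3d] on the CT grid.
#' @export
fuse_volumes <- function(ct, cbct, result, interpolation = "trilinear",
                         fill = 0) {
  if (!identical(result$status, "success"))
    stop("cannot fuse: registration failed at stage ", result$failed_stage)
  n_fb <- 0L
  inv_fun <- function(pts) {
    r <- invert_final_map(result, pts)
    n_fb <<- n_fb + r$n_fallback
    r$points
  }
  out <- resample_into(cbct, ct, transform = inv_fun,
                       interpolation = interpolation, fill = fill)
  n_vox <- prod(dim(ct$data))
  if (n_fb > 0.01 * n_vox)
    warning(sprintf("map inversion did not converge at %.2f%% of voxels; %s",
                    100 * n_fb / n_vox, "affine fallback used there"))
  attr(out, "n_inversion_fallback") <- n_fb
  out
}

#' Checkerboard composite of two volumes on the same grid
#'
#' @param a,b [volume3d] objects on identical grids.
#' @param tile tile edge length in voxels (default 16).
#' @return A [volume3d] alternating tiles of `a` and `b`.
#' @export
checkerboard <- function(a, b, tile = 16L) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9 ||
      max(abs(a$direction - b$direction)) > 1e-9)
    stop("checkerboard requires identical grids")
  stopifnot(tile >= 1L)
  d <- dim(a$data)
  ix <- (0:(d[1] - 1L)) %/% tile
  iy <- (0:(d[2] - 1L)) %/% tile
  iz <- (0:(d[3] - 1L)) %/% tile
  parity <- (outer(outer(ix, iy, `+`), iz, `+`)) %% 2L == 0L
  out <- a$data
  out[!parity] <- b$data[!parity]
  volume3d(out, a$spacing, a$origin, a$direction)
}
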