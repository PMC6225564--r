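## Descriptor matching: global mutual nearest-neighbour correspondences
## (stage 1) and transform-guided local-radius re-matching (stage 2), plus
## field-of-view pruning of the large-FOV feature set.

#' Construct a match set
#'
#' @param idx_a,idx_b 1-based indices into feature sets A and B; one-to-one.
#' @param distance descriptor Euclidean distances, index-aligned.
#' @return A data frame of class `match_set`, sorted by ascending distance.
#' @export
match_set <- function(idx_a = integer(), idx_b = integer(),
                      distance = numeric()) {
  stopifnot(length(idx_a) == length(idx_b),
            length(idx_a) == length(distance))
  if (anyDuplicated(idx_a) || anyDuplicated(idx_b))
    stop("match set must be one-to-one")
  if (any(distance < 0)) stop("descriptor distances must be non-negative")
  ord <- order(distance, idx_a)
  structure(data.frame(idx_a = as.integer(idx_a)[ord],
                       idx_b = as.integer(idx_b)[ord],
                       distance = as.numeric(distance)[ord]),
            class = c("match_set", "data.frame"))
}

# Blocked squared-distance computation (BLAS): d2[i,j] = |a_i - b_j|^2.
descriptor_dist2 <- function(da, db) {
  a2 <- rowSums(da^2)
  b2 <- rowSums(db^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  d2
}

# Row-wise argmin over a distance matrix in column-blocks, ties to the
# lowest index. Returns list(idx, val).
blocked_row_min <- function(da, db, block = 2048L) {
  na <- nrow(da)
  best_val <- rep(Inf, na)
  best_idx <- rep(NA_integer_, na)
  for (j0 in seq(1L, nrow(db), by = block)) {
    jj <- j0:min(j0 + block - 1L, nrow(db))
    d2 <- descriptor_dist2(da, db[jj, , drop = FALSE])
    mi <- max.col(-d2, ties.method = "first")
    mv <- d2[cbind(seq_len(na), mi)]
    upd <- mv < best_val
    best_val[upd] <- mv[upd]
    best_idx[upd] <- jj[mi[upd]]
  }
  list(idx = best_idx, val = best_val)
}

#' Mutual nearest-neighbour matching
#'
#' Each feature of A is matched to its closest feature of B by descriptor
#' Euclidean distance, and vice versa; only pairs matched in both directions
#' are kept. Distance ties are broken by the lower index, so the result is
#' deterministic.
#'
#' @param features_a,features_b `feature_set` objects.
#' @return A [match_set()] sorted by ascending descriptor distance.
#' @export
mutual_match <- function(features_a, features_b) {
  da <- features_a$descriptors; db <- features_b$descriptors
  if (nrow(da) == 0L || nrow(db) == 0L) return(match_set())
  fwd <- blocked_row_min(da, db)
  bwd <- blocked_row_min(db, da)
  i <- seq_len(nrow(da))
  mutual <- bwd$idx[fwd$idx] == i
  match_set(i[mutual], fwd$idx[mutual], sqrt(fwd$val[mutual]))
}

#' Prune features to a transformed field of view
#'
#' Keeps the CT features whose position, mapped back through the inverse of
#' the CBCT-to-CT transform, lies inside the CBCT field of view dilated by
#' `margin` mm. The FOV is the CBCT physical bounding box by default; the
#' true cylindrical reconstruction volume (axis along the third voxel axis)
#' is available with `shape = "cylinder"`.
#'
#' @param features_ct a `feature_set` in CT space.
#' @param cbct the CBCT [volume3d].
#' @param transform [affine_transform3d] mapping CBCT to CT space.
#' @param margin dilation in mm; `Inf` keeps everything (default 10).
#' @param shape `"box"` or `"cylinder"`.
#' @return The pruned `feature_set`, with the original indices of the kept
#'   features in attribute `"original_indices"`.
#' @export
prune_to_fov <- function(features_ct, cbct, transform, margin = 10,
                         shape = c("box", "cylinder")) {
  shape <- match.arg(shape)
  n <- nrow(features_ct$keypoints)
  if (is.infinite(margin) || n == 0L) {
    out <- features_ct
    attr(out, "original_indices") <- seq_len(n)
    return(out)
  }
  inv <- invert_affine(transform)
  pts <- as.matrix(features_ct$keypoints[, c("x", "y", "z")])
  q <- apply_transform(inv, pts)                    # into CBCT physical space
  local <- sweep(q, 2, cbct$origin, `-`) %*% cbct$direction
  ext <- (dim(cbct$data) - 1) * cbct$spacing
  if (shape == "box") {
    keep <- local[, 1] >= -margin & local[, 1] <= ext[1] + margin &
            local[, 2] >= -margin & local[, 2] <= ext[2] + margin &
            local[, 3] >= -margin & local[, 3] <= ext[3] + margin
  } else {
    cx <- ext[1] / 2; cy <- ext[2] / 2
    r <- sqrt((local[, 1] - cx)^2 + (local[, 2] - cy)^2)
    keep <- r <= min(cx, cy) + margin &
            local[, 3] >= -margin & local[, 3] <= ext[3] + margin
  }
  out <- feature_set(features_ct$keypoints[keep, , drop = FALSE],
                     features_ct$descriptors[keep, , drop = FALSE])
  attr(out, "original_indices") <- which(keep)
  out
}

#' Transform-guided local matching
#'
#' Like [mutual_match()], but each feature of A (CBCT) is only compared to B
#' (CT) features lying within `radius` mm of its transformed position, and
#' each feature of B only to A features within `radius` of its
#' inverse-transformed position. Mutual consistency is still required.
#'
#' @param features_a `feature_set` in CBCT space.
#' @param features_b `feature_set` in CT space.
#' @param transform [affine_transform3d] mapping CBCT to CT space.
#' @param radius search radius in mm (default 10); `Inf` reduces to
#'   [mutual_match()].
#' @return A [match_set()].
#' @export
local_match <- function(features_a, features_b, transform, radius = 10) {
  stopifnot(radius > 0)
  if (is.infinite(radius)) return(mutual_match(features_a, features_b))
  da <- features_a$descriptors; db <- features_b$descriptors
  na <- nrow(da); nb <- nrow(db)
  if (na == 0L || nb == 0L) return(match_set())

  pa <- as.matrix(features_a$keypoints[, c("x", "y", "z")])
  pb <- as.matrix(features_b$keypoints[, c("x", "y", "z")])
  pa_t <- apply_transform(transform, pa)                 # A into CT space
  pb_t <- apply_transform(invert_affine(transform), pb)  # B into CBCT space

  # spatial feasibility masks (mm)
  fwd_feas <- descriptor_dist2(pa_t, pb) <= radius^2     # |T(a) - b|
  bwd_feas <- t(descriptor_dist2(pb_t, pa) <= radius^2)  # |T^-1(b) - a|

  d2 <- descriptor_dist2(da, db)
  df <- d2; df[!fwd_feas] <- Inf
  fwd_idx <- max.col(-df, ties.method = "first")
  fwd_ok <- is.finite(df[cbind(seq_len(na), fwd_idx)])
  db2 <- t(d2); db2[t(!bwd_feas)] <- Inf
  bwd_idx <- max.col(-db2, ties.method = "first")
  bwd_ok <- is.finite(db2[cbind(seq_len(nb), bwd_idx)])

  i <- which(fwd_ok)
  j <- fwd_idx[i]
  mutual <- bwd_ok[j] & bwd_idx[j] == i
  match_set(i[mutual], j[mutual], sqrt(d2[cbind(i[mutual], j[mutual])]))
}

#' Write a match set to CSV (`idx_a,idx_b,distance`)
#' @param matches a [match_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matches <- function(matches, path) {
  utils::write.csv(as.data.frame(matches), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a match set written by [write_matches()]
#' @param path CSV path.
#' @return A [match_set()].
#' @export
read_matches <- function(path) {
  df <- utils::read.csv(path)
  match_set(df$idx_a, df$idx_b, df$distance)
}

#' Drop features whose support window reaches the empty background
#'
#' Cone-beam reconstructions are exactly constant outside their cylindrical
#' field of view. Keypoints whose descriptor window overlaps that background
#' localise with a systematic inward bias (half of their support is
#' featureless), which contaminates the affine estimate with a spurious
#' scale. This filter removes features closer to the background region than
#' `k` times their own scale, probing a small sphere of directions around
#' each keypoint.
#'
#' @param features a `feature_set`.
#' @param volume the [volume3d] the features were detected in.
#' @param k support radius in units of keypoint scale (default 3, the
#'   descriptor subregion width); 0 disables the filter.
#' @return The filtered `feature_set`.
#' @export
filter_background_support <- function(features, volume, k = 3) {
  n <- nrow(features$keypoints)
  if (k <= 0 || n == 0L) return(features)
  v <- volume$data
  bg <- v <= min(v) + 1e-12
  if (!any(bg) || all(bg)) return(features)
  mask <- as.numeric(bg)
  dirs <- rbind(c(0, 0, 0), diag(3), -diag(3),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1),
                      c(1, 1, -1, -1, 1, 1, -1, -1),
                      c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  pos <- as.matrix(features$keypoints[, c("x", "y", "z")])
  rad <- k * features$keypoints$scale
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(dirs))) {
    pts <- pos + rad %o% dirs[i, ]
    vox <- physical_to_voxel(volume, pts)
    # points outside the grid count as background
    hit <- cpp_interp3(mask, dim(v), vox, 1, 1L) >= 0.5
    keep <- keep & !hit
  }
  out <- feature_set(features$keypoints[keep, , drop = FALSE],
                     features$descriptors[keep, , drop = FALSE])
  attr(out, "original_indices") <- which(keep)
  out
}
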