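## Geometric transforms: least-squares affine, geometry-aware RANSAC, and
## the 3D thin-plate spline. All transforms map CBCT physical points (mm)
## to CT physical points (mm): p' = A p + t.

#' Construct a 3D affine transform
#'
#' @param linear 3x3 matrix (non-singular).
#' @param translation length-3 numeric (mm).
#' @return An object of class `affine_transform3d` mapping `p' = A p + t`.
#' @export
affine_transform3d <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(linear)) < 1e-12)
    stop("singular linear part (det = ", format(det(linear)), ")")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform3d")
}

#' @export
print.affine_transform3d <- function(x, ...) {
  cat("affine_transform3d (CBCT -> CT), det =",
      format(det(x$linear), digits = 5), "\n")
  m <- cbind(x$linear, x$translation)
  dimnames(m) <- list(c("x'", "y'", "z'"), c("x", "y", "z", "t (mm)"))
  print(round(m, 5))
  invisible(x)
}

as_point_matrix <- function(points) {
  p <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Apply a transform to physical points
#'
#' @param transform an [affine_transform3d], a [fit_tps()] result, a plain
#'   function on n x 3 matrices, or `NULL` (identity).
#' @param points length-3 vector or n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(transform, points) {
  p <- as_point_matrix(points)
  if (is.null(transform)) return(p)
  if (is.function(transform)) return(transform(p))
  stop("unsupported transform of class ", paste(class(transform), collapse = "/"))
}

#' @export
apply_transform.affine_transform3d <- function(transform, points) {
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$linear), 2, transform$translation, `+`)
}

#' @export
apply_transform.tps_transform3d <- function(transform, points) {
  p <- as_point_matrix(points)
  out <- sweep(p %*% t(transform$linear), 2, transform$translation, `+`)
  cp <- transform$control_points
  n <- nrow(cp)
  if (n == 0L) return(out)
  # U(r) = r kernel, chunked over evaluation points; distances via explicit
  # coordinate differences (no cancellation at the control points)
  chunk <- max(1L, as.integer(ceiling(5e6 / n)))
  for (i0 in seq(1L, nrow(p), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(p))
    d2 <- outer(p[ii, 1], cp[, 1], `-`)^2 + outer(p[ii, 2], cp[, 2], `-`)^2 +
      outer(p[ii, 3], cp[, 3], `-`)^2
    out[ii, ] <- out[ii, ] + sqrt(d2) %*% transform$weights
  }
  out
}

#' Invert an affine transform
#' @param transform an [affine_transform3d].
#' @return The inverse [affine_transform3d].
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine_transform3d"))
  Ai <- tryCatch(solve(transform$linear),
                 error = function(e) stop("singular affine transform"))
  affine_transform3d(Ai, -Ai %*% transform$translation)
}

#' Least-squares affine fit to point correspondences
#'
#' Minimises `sum || A p_i + t - q_i ||^2` over the 12 affine parameters.
#'
#' @param points_a n x 3 source points (n >= 4, not all coplanar).
#' @param points_b n x 3 target points.
#' @return An [affine_transform3d].
#' @export
fit_affine_lsq <- function(points_a, points_b) {
  pa <- as_point_matrix(points_a); pb <- as_point_matrix(points_b)
  if (nrow(pa) != nrow(pb)) stop("point lists must have equal length")
  if (nrow(pa) < 4L) stop("need at least 4 point pairs, got ", nrow(pa))
  X <- cbind(pa, 1)
  qr_x <- qr(X)
  if (qr_x$rank < 4L)
    stop("rank-deficient source points (coplanar or collinear)")
  B <- qr.coef(qr_x, pb)  # 4 x 3
  affine_transform3d(t(B[1:3, , drop = FALSE]), B[4, ])
}

# Exact affine through 4 non-coplanar pairs; NULL when degenerate.
affine_from_four <- function(pa, pb) {
  X <- cbind(pa, 1)
  d <- det(X)
  if (!is.finite(d) || abs(d) < 1e-6 * max(abs(X))^3) return(NULL)
  B <- solve(X, pb)
  lin <- t(B[1:3, , drop = FALSE])
  if (abs(det(lin)) < 1e-12) return(NULL)
  affine_transform3d(lin, B[4, ])
}

#' Geometry-aware RANSAC affine estimation
#'
#' Repeatedly samples minimal 4-correspondence subsets, fits an exact affine,
#' and counts correspondences with residual at most `threshold` mm. The
#' consensus-maximal model is refit by [fit_affine_lsq()] on its inliers and
#' the inlier mask is recomputed against the refit (twice, so the mask and
#' model agree). The iteration count adapts to the observed inlier ratio at
#' the requested confidence, capped at `max_iterations`.
#'
#' @param points_a,points_b matched n x 3 point lists (n >= 4).
#' @param threshold inlier residual threshold in mm (stage 1 default 10 mm,
#'   stage 2 uses 5 mm).
#' @param confidence probability of hitting one all-inlier sample (default
#'   0.99).
#' @param max_iterations iteration cap (default 10000).
#' @param seed integer; fixes the sampling sequence. The caller's RNG state
#'   is saved and restored.
#' @param det_bounds length-2 sanity bounds on |det| of the linear part;
#'   candidate models outside them are rejected (default `c(0.5, 2)`,
#'   appropriate for patient pose changes; use `c(0, Inf)` to disable).
#' @return A list of class `ransac_result`: `transform`, `inlier_mask`,
#'   `n_iterations`, `threshold`, `success`, and `n_inliers`. On failure
#'   (no model with >= 4 inliers) `success` is `FALSE` and `transform` is
#'   `NULL`.
#' @export
ransac_affine <- function(points_a, points_b, threshold = 10,
                          confidence = 0.99, max_iterations = 10000L,
                          seed = 1L, det_bounds = c(0.5, 2)) {
  pa <- as_point_matrix(points_a); pb <- as_point_matrix(points_b)
  n <- nrow(pa)
  if (n != nrow(pb)) stop("point lists must have equal length")
  if (n < 4L) stop("RANSAC needs at least 4 matches, got ", n)
  stopifnot(threshold > 0)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  resid_count <- function(tr) {
    r <- sqrt(rowSums((apply_transform(tr, pa) - pb)^2))
    r <= threshold
  }

  best_mask <- NULL
  best_n <- 3L
  needed <- max_iterations
  it <- 0L
  while (it < needed && it < max_iterations) {
    it <- it + 1L
    idx <- sample.int(n, 4L)
    tr <- affine_from_four(pa[idx, , drop = FALSE], pb[idx, , drop = FALSE])
    if (is.null(tr)) next  # degenerate (near-coplanar) sample: redrawn
    dt <- abs(det(tr$linear))
    if (dt < det_bounds[1] || dt > det_bounds[2]) next  # implausible pose
    mask <- resid_count(tr)
    ni <- sum(mask)
    if (ni > best_n) {
      best_n <- ni
      best_mask <- mask
      w <- ni / n
      needed <- if (w >= 1) it else
        min(max_iterations,
            ceiling(log(1 - confidence) / log(1 - w^4)))
    }
  }

  if (is.null(best_mask))
    return(structure(list(transform = NULL, inlier_mask = rep(FALSE, n),
                          n_iterations = it, threshold = threshold,
                          success = FALSE, n_inliers = 0L),
                     class = "ransac_result"))

  # refit on consensus, recompute mask, refit once more so they agree
  mask <- best_mask
  tr <- NULL
  for (pass in 1:2) {
    tr_try <- tryCatch(fit_affine_lsq(pa[mask, , drop = FALSE],
                                      pb[mask, , drop = FALSE]),
                       error = function(e) NULL)
    if (is.null(tr_try)) break
    tr <- tr_try
    mask <- resid_count(tr)
    if (sum(mask) < 4L) break
  }
  success <- !is.null(tr) && sum(mask) >= 4L &&
    abs(det(tr$linear)) >= det_bounds[1] && abs(det(tr$linear)) <= det_bounds[2]
  structure(list(transform = if (success) tr else NULL,
                 inlier_mask = if (success) mask else rep(FALSE, n),
                 n_iterations = it, threshold = threshold,
                 success = success,
                 n_inliers = if (success) sum(mask) else 0L),
            class = "ransac_result")
}

#' @export
print.ransac_result <- function(x, ...) {
  cat("ransac_result:", if (x$success) "success" else "FAILURE",
      "-", x$n_inliers, "inliers of", length(x$inlier_mask),
      "matches at", x$threshold, "mm threshold,",
      x$n_iterations, "iterations\n")
  invisible(x)
}

## ---- thin-plate spline -----------------------------------------------------

#' Number of parameters of a 3D thin-plate spline
#'
#' A TPS on `n` 3D control points has `3 n + 12` parameters: 12 for the
#' global affine part and 3 per control point for the nonlinearity.
#'
#' @param n_points number of control points (>= 0).
#' @return `3 * n_points + 12`.
#' @export
tps_parameter_count <- function(n_points) {
  if (any(n_points < 0)) stop("n_points must be non-negative")
  3L * as.integer(n_points) + 12L
}

#' Fit a 3D thin-plate spline to point correspondences
#'
#' Solves the standard TPS linear system with the 3D biharmonic kernel
#' `U(r) = r` and side conditions (the nonlinear weights sum to zero and are
#' orthogonal to the control-point coordinates). With `lambda = 0` the map
#' interpolates the correspondences exactly; `lambda > 0` smooths via the
#' usual diagonal augmentation of the kernel block.
#'
#' @param source_points n x 3 control points (n >= 4, non-coplanar, no
#'   duplicates within 1e-6 mm).
#' @param target_points n x 3 target points.
#' @param regularization smoothing parameter lambda >= 0 (default 0).
#' @return An object of class `tps_transform3d` with fields
#'   `control_points` (n x 3), `weights` (n x 3 nonlinear coefficients),
#'   `linear` (3x3), `translation` (length 3), and `regularization`.
#' @export
fit_tps <- function(source_points, target_points, regularization = 0) {
  src <- as_point_matrix(source_points); dst <- as_point_matrix(target_points)
  n <- nrow(src)
  if (n != nrow(dst)) stop("point lists must have equal length")
  if (n < 4L) stop("TPS needs at least 4 correspondences, got ", n)
  stopifnot(regularization >= 0)
  D <- as.matrix(stats::dist(src))
  if (any(D[upper.tri(D)] < 1e-6))
    stop("duplicate source points (closer than 1e-6 mm)")
  if (qr(cbind(1, src))$rank < 4L)
    stop("rank-deficient (coplanar) source points")
  # solve in centred/scaled source coordinates for conditioning, then map
  # the solution back; U(r) = r is homogeneous so only scale factors appear
  ctr <- colMeans(src)
  scl <- mean(sqrt(rowSums(sweep(src, 2, ctr, `-`)^2)))
  if (scl <= 0) scl <- 1
  srcn <- sweep(src, 2, ctr, `-`) / scl
  P <- cbind(1, srcn)
  # U(r) = r is conditionally negative definite, so the smoothing term
  # enters with a negative sign (equivalently: fit with kernel -r and +lambda)
  K <- D / scl - diag(regularization / scl, n)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- solve(M, rhs)
  w <- sol[seq_len(n), , drop = FALSE] / scl
  a <- sol[n + 1:4, , drop = FALSE]   # rows: intercept, x', y', z'
  linear <- t(a[2:4, , drop = FALSE]) / scl
  translation <- a[1, ] - as.numeric(linear %*% ctr)
  structure(list(control_points = src, weights = w,
                 linear = linear, translation = translation,
                 regularization = regularization),
            class = "tps_transform3d")
}

#' @export
print.tps_transform3d <- function(x, ...) {
  cat("tps_transform3d (CBCT -> CT):", nrow(x$control_points),
      "control points,", tps_parameter_count(nrow(x$control_points)),
      "parameters, lambda =", x$regularization, "\n")
  cat("  max |nonlinear weight|:", format(max(abs(x$weights)), digits = 4), "\n")
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

#' Write a transform to JSON
#'
#' Numbers are serialized with 17 significant digits, so reading the file
#' back reproduces the transform bit-exactly.
#'
#' @param transform an [affine_transform3d] or `tps_transform3d`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  obj <- if (inherits(transform, "affine_transform3d")) {
    list(type = "affine", convention = "cbct_to_ct",
         matrix = as.numeric(t(cbind(transform$linear,
                                     transform$translation))))
  } else if (inherits(transform, "tps_transform3d")) {
    list(type = "tps", convention = "cbct_to_ct",
         affine = as.numeric(t(cbind(transform$linear,
                                     transform$translation))),
         control_points = transform$control_points,
         weights = transform$weights,
         regularization = transform$regularization)
  } else stop("unsupported transform class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path JSON path.
#' @return An [affine_transform3d] or `tps_transform3d`.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "affine")) {
    m <- matrix(obj$matrix, 3, 4, byrow = TRUE)
    affine_transform3d(m[, 1:3], m[, 4])
  } else if (identical(obj$type, "tps")) {
    m <- matrix(obj$affine, 3, 4, byrow = TRUE)
    structure(list(control_points = matrix(obj$control_points, ncol = 3),
                   weights = matrix(obj$weights, ncol = 3),
                   linear = m[, 1:3], translation = m[, 4],
                   regularization = obj$regularization),
              class = "tps_transform3d")
  } else stop("unrecognized transform file: ", path)
}
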