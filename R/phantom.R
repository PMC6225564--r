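## Synthetic abdominal CT/CBCT phantom with known ground truth.
##
## The scene is a fully analytic intensity function of physical position:
## a soft-tissue body cylinder with band-limited Gaussian-blob texture, a
## column of bright vertebra-like structures (body + spinous and transverse
## processes), a contrast-filled aorta tube present only in the CT, and
## small high-intensity calcification spots on the tube wall visible in
## both modalities. The CBCT samples the same scene (without the aorta
## contrast) through the inverse of a known CBCT-to-CT map - an affine pose
## change plus a smooth sum-of-Gaussian-bumps warp - crops it to the
## cylindrical reconstruction volume, and applies an intensity gain/offset
## and additive noise. Because the scene and the map are analytic, both
## volumes and dense ground-truth correspondences are available at any
## point, with no interpolation error in the simulated acquisition.

#' Specification of a synthetic CT/CBCT phantom pair
#'
#' Defaults emulate the clinical acquisition differences the registration
#' must overcome: a CT field of view about three times the CBCT's, a
#' cylindrical CBCT volume of 250 mm diameter x 190 mm height, a pose change
#' of up to 10 degrees rotation / 30 mm translation / 3 percent scale, a
#' smooth nonlinear deformation of a few mm, and an intensity gain/offset
#' mismatch with noise. Grids default to 1.5 mm isotropic voxels.
#'
#' @param ct_extent CT physical extent in mm per axis.
#' @param ct_spacing CT voxel spacing in mm (isotropic scalar or length 3).
#' @param cbct_fov cylinder `c(diameter, height)` in mm.
#' @param cbct_spacing CBCT voxel spacing in mm.
#' @param max_rotation_deg,max_translation,max_scale pose-change bounds; the
#'   drawn magnitudes lie in the upper half of each bound.
#' @param nonlinear_amplitude maximum displacement of the smooth warp (mm).
#' @param intensity_gain,intensity_offset CBCT intensity mismatch.
#' @param noise_sd additive Gaussian noise SD on the CBCT (scene units;
#'   the scene spans roughly 0..1).
#' @param n_vertebrae number of vertebra-like structures along the
#'   cranio-caudal axis.
#' @param n_calcifications number of calcification spots (>= 3).
#' @param include_aorta_contrast bright aorta lumen in the CT (default TRUE).
#' @param n_texture_blobs soft-tissue texture components.
#' @param seed integer; fixes every random choice of the pair.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(ct_extent = c(360, 360, 480), ct_spacing = 1.5,
                         cbct_fov = c(250, 190), cbct_spacing = 1.5,
                         max_rotation_deg = 10, max_translation = 30,
                         max_scale = 0.03, nonlinear_amplitude = 5,
                         intensity_gain = 1.4, intensity_offset = 0.1,
                         noise_sd = 0.02, n_vertebrae = 13L,
                         n_calcifications = 6L,
                         include_aorta_contrast = TRUE,
                         n_texture_blobs = 12000L, seed = 1L) {
  if (length(ct_spacing) == 1L) ct_spacing <- rep(ct_spacing, 3)
  stopifnot(length(ct_extent) == 3L, all(ct_extent > 0),
            all(ct_spacing > 0), length(cbct_fov) == 2L, all(cbct_fov > 0),
            cbct_spacing > 0, nonlinear_amplitude >= 0, noise_sd >= 0,
            n_calcifications >= 3L, n_vertebrae >= 3L)
  # the transformed CBCT cylinder must fit inside the CT extent
  reach <- sqrt((cbct_fov[1] / 2)^2 + (cbct_fov[2] / 2)^2)
  slack <- reach * (1 + max_scale) + max_translation
  if (slack > max(ct_extent) / 2 && slack > min(ct_extent) / 2 * sqrt(2))
    stop("CBCT field of view cannot fit inside the CT extent under the ",
         "allowed pose change")
  structure(list(ct_extent = ct_extent, ct_spacing = ct_spacing,
                 cbct_fov = cbct_fov, cbct_spacing = cbct_spacing,
                 max_rotation_deg = max_rotation_deg,
                 max_translation = max_translation, max_scale = max_scale,
                 nonlinear_amplitude = nonlinear_amplitude,
                 intensity_gain = intensity_gain,
                 intensity_offset = intensity_offset, noise_sd = noise_sd,
                 n_vertebrae = as.integer(n_vertebrae),
                 n_calcifications = as.integer(n_calcifications),
                 include_aorta_contrast = isTRUE(include_aorta_contrast),
                 n_texture_blobs = as.integer(n_texture_blobs),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# soft-edged profile: 1 inside, 0 outside, linear ramp of relative width w
soft_in <- function(m, w) pmin(pmax((1 - m) / w, 0), 1)

# Soft-tissue body envelope in [0, 1] at n x 3 physical points.
body_factor <- function(scene, pts) {
  b <- scene$body
  mb <- sqrt((pts[, 1] / b$a)^2 + (pts[, 2] / b$b)^2)
  soft_in(mb, 0.04) * soft_in(abs(pts[, 3]) / b$hz, 0.04)
}

# Evaluate the analytic structural scene (body envelope, vertebrae, aorta,
# calcifications - everything except the dense texture field) at an n x 3
# matrix of physical points (mm).
scene_eval <- function(scene, pts, contrast = TRUE) {
  pts <- as_point_matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]

  # body: elliptic cylinder of soft tissue
  body <- body_factor(scene, pts)
  v <- scene$body$amp * body

  # vertebrae: soft-edged ellipsoids (body + processes)
  v <- v + cpp_scene_ellipsoids(pts, as.matrix(scene$ellipsoids), 0.15)

  # aorta: contrast-filled lumen, CT only
  if (contrast && scene$aorta$amp > 0) {
    a <- scene$aorta
    sel <- which(abs(z) < a$hz & abs(x - a$cx) < a$r + 3 & abs(y - a$cy) < a$r + 3)
    if (length(sel)) {
      r <- sqrt((x[sel] - a$cx)^2 + (y[sel] - a$cy)^2)
      v[sel] <- v[sel] + a$amp * soft_in(r / a$r, 0.15) *
        soft_in(abs(z[sel]) / a$hz, 0.02)
    }
  }

  # calcifications: small bright soft-edged spheres on the tube wall
  ca <- scene$calcifications
  v <- v + cpp_scene_spheres(pts, as.matrix(ca[, c("cx", "cy", "cz", "r", "amp")]),
                             0.5)
  v
}

# Rodrigues rotation matrix about unit axis u by angle (radians).
rotation_matrix <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Evaluate the smooth warp displacement (n x 3) at CBCT-space points.
warp_displacement <- function(warp, pts) {
  disp <- matrix(0, nrow(pts), 3)
  if (is.null(warp) || length(warp$sigma) == 0L) return(disp)
  for (k in seq_along(warp$sigma)) {
    r2 <- (pts[, 1] - warp$centers[k, 1])^2 +
          (pts[, 2] - warp$centers[k, 2])^2 +
          (pts[, 3] - warp$centers[k, 3])^2
    g <- exp(-r2 / (2 * warp$sigma[k]^2))
    disp <- disp + outer(g, warp$amplitudes[k, ])
  }
  disp
}

# Build the true CBCT->CT map as a closure over (affine, warp).
make_true_map <- function(affine, warp) {
  force(affine); force(warp)
  f <- function(pts) {
    p <- if (is.matrix(pts)) pts else matrix(as.numeric(pts), ncol = 3)
    apply_transform(affine, p) + warp_displacement(warp, p)
  }
  attr(f, "affine") <- affine
  attr(f, "warp") <- warp
  f
}

# Invert the true map at target points p (CT space) by Newton iteration with
# the affine linear part as Jacobian; the warp is a small contraction.
invert_true_map <- function(true_map, pts, tol = 1e-10, max_iter = 100L) {
  affine <- attr(true_map, "affine")
  inv <- invert_affine(affine)
  p <- if (is.matrix(pts)) pts else matrix(as.numeric(pts), ncol = 3)
  q <- apply_transform(inv, p)
  for (i in seq_len(max_iter)) {
    r <- true_map(q) - p
    if (max(abs(r)) < tol) break
    q <- q - r %*% t(inv$linear)
  }
  q
}

#' Generate a synthetic CT/CBCT phantom pair
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_pair`: `ct` and `cbct` ([volume3d]),
#'   `true_map` (function CBCT physical -> CT physical, with the affine and
#'   warp parameters attached as attributes), `true_affine`,
#'   `landmarks_ct` / `landmarks_cbct` (paired data frames: 3 calcification
#'   spots and 3 vertebral corner points), and `spec`.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  ## ---- scene ---------------------------------------------------------------
  ext <- spec$ct_extent
  body <- list(a = ext[1] * 0.44, b = ext[2] * 0.33, hz = ext[3] / 2 - 10,
               amp = 0.25)
  ntx <- spec$n_texture_blobs
  texture <- data.frame(
    cx = stats::runif(ntx, -0.85, 0.85) * body$a,
    cy = stats::runif(ntx, -0.85, 0.85) * body$b,
    cz = stats::runif(ntx, -0.95, 0.95) * body$hz,
    sigma = stats::runif(ntx, 3, 9),
    amp = stats::runif(ntx, 0.06, 0.14) * sample(c(-1, 1), ntx, replace = TRUE))

  nv <- spec$n_vertebrae
  pitch <- 36
  zc <- (seq_len(nv) - (nv + 1) / 2) * pitch
  zc <- zc[abs(zc) < body$hz - 15]
  spine_y <- -60
  ell <- do.call(rbind, lapply(zc, function(z0) rbind(
    data.frame(cx = 0,   cy = spine_y,      cz = z0, rx = 18, ry = 14, rz = 12, amp = 0.6),
    data.frame(cx = 0,   cy = spine_y - 28, cz = z0, rx = 6,  ry = 14, rz = 6,  amp = 0.55),
    data.frame(cx = 24,  cy = spine_y,      cz = z0, rx = 16, ry = 5,  rz = 5,  amp = 0.5),
    data.frame(cx = -24, cy = spine_y,      cz = z0, rx = 16, ry = 5,  rz = 5,  amp = 0.5))))

  aorta <- list(cx = 8, cy = -20, r = 11, hz = body$hz - 10,
                amp = if (spec$include_aorta_contrast) 0.55 else 0)

  ncal <- spec$n_calcifications
  theta <- stats::runif(ncal, 0, 2 * pi)
  calc_z <- c(stats::runif(3, -30, 30),                    # "renal level" spots
              stats::runif(ncal - 3, -70, 70))
  calc_r <- stats::runif(ncal, 1.5, 4)
  calc <- data.frame(
    cx = aorta$cx + (aorta$r + 1) * cos(theta),
    cy = aorta$cy + (aorta$r + 1) * sin(theta),
    cz = calc_z, r = calc_r, amp = 0.9)

  scene <- list(body = body, texture = texture, ellipsoids = ell,
                aorta = aorta, calcifications = calc)

  ## ---- ground-truth map ----------------------------------------------------
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  angle <- spec$max_rotation_deg * pi / 180 * stats::runif(1, 0.5, 1) *
    sample(c(-1, 1), 1)
  scl <- 1 + spec$max_scale * stats::runif(1, -1, 1)
  tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
  tvec <- tdir * spec$max_translation * stats::runif(1, 0.5, 1)
  true_affine <- affine_transform3d(rotation_matrix(axis, angle) * scl, tvec)

  warp <- NULL
  if (spec$nonlinear_amplitude > 0) {
    nb <- 4L
    centers <- cbind(stats::runif(nb, -80, 80), stats::runif(nb, -80, 80),
                     stats::runif(nb, -70, 70))
    sigma <- stats::runif(nb, 40, 80)
    dirs <- matrix(stats::rnorm(3 * nb), nb, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- dirs * stats::runif(nb, 0.5, 1)
    warp <- list(centers = centers, sigma = sigma, amplitudes = amps)
    # rescale so the peak displacement magnitude equals the requested
    # amplitude (x a factor in [0.7, 1]) over the CBCT field of view
    gx <- seq(-spec$cbct_fov[1] / 2, spec$cbct_fov[1] / 2, by = 10)
    gz <- seq(-spec$cbct_fov[2] / 2, spec$cbct_fov[2] / 2, by = 10)
    grid <- as.matrix(expand.grid(gx, gx, gz))
    peak <- max(sqrt(rowSums(warp_displacement(warp, grid)^2)))
    target <- spec$nonlinear_amplitude * stats::runif(1, 0.7, 1)
    warp$amplitudes <- warp$amplitudes * (target / peak)
  }
  true_map <- make_true_map(true_affine, warp)

  ## ---- CT volume -----------------------------------------------------------
  # The dense soft-tissue texture field is rendered once on the CT grid; the
  # CBCT samples it through the warp by trilinear interpolation, while every
  # structural component (and hence the landmark truth) stays analytic.
  ctd <- pmax(2L, as.integer(round(ext / spec$ct_spacing)))
  ct_origin <- -(ctd - 1) * spec$ct_spacing / 2
  tex_vol <- cpp_render_blobs_grid(ctd, spec$ct_spacing, ct_origin,
                                   as.matrix(texture[, c("cx", "cy", "cz")]),
                                   texture$sigma, texture$amp)
  ct_arr <- array(0, dim = ctd)
  ij <- as.matrix(expand.grid(x = 0:(ctd[1] - 1L), y = 0:(ctd[2] - 1L)))
  slab <- max(1L, as.integer(ceiling(2e6 / (ctd[1] * ctd[2]))))
  for (z0 in seq(0L, ctd[3] - 1L, by = slab)) {
    zs <- z0:min(z0 + slab - 1L, ctd[3] - 1L)
    idx <- cbind(ij[rep(seq_len(nrow(ij)), times = length(zs)), , drop = FALSE],
                 rep(zs, each = nrow(ij)))
    pts <- sweep(idx, 2, spec$ct_spacing, `*`)
    pts <- sweep(pts, 2, ct_origin, `+`)
    sel <- (z0 * ctd[1] * ctd[2] + 1L):((z0 + length(zs)) * ctd[1] * ctd[2])
    ct_arr[, , zs + 1L] <- scene_eval(scene, pts, contrast = TRUE) +
      body_factor(scene, pts) * tex_vol[sel]
  }
  ct <- volume3d(ct_arr, spacing = spec$ct_spacing, origin = ct_origin)

  ## ---- CBCT volume ---------------------------------------------------------
  fov_r <- spec$cbct_fov[1] / 2
  fov_hz <- spec$cbct_fov[2] / 2
  cd <- pmax(2L, as.integer(round(c(spec$cbct_fov[1], spec$cbct_fov[1],
                                    spec$cbct_fov[2]) / spec$cbct_spacing)))
  cb_origin <- -(cd - 1) * spec$cbct_spacing / 2
  cb_arr <- array(0, dim = cd)
  ij2 <- as.matrix(expand.grid(x = 0:(cd[1] - 1L), y = 0:(cd[2] - 1L)))
  slab2 <- max(1L, as.integer(ceiling(2e6 / (cd[1] * cd[2]))))
  for (z0 in seq(0L, cd[3] - 1L, by = slab2)) {
    zs <- z0:min(z0 + slab2 - 1L, cd[3] - 1L)
    idx <- cbind(ij2[rep(seq_len(nrow(ij2)), times = length(zs)), , drop = FALSE],
                 rep(zs, each = nrow(ij2)))
    q <- sweep(idx, 2, rep(spec$cbct_spacing, 3), `*`)
    q <- sweep(q, 2, cb_origin, `+`)
    inside <- sqrt(q[, 1]^2 + q[, 2]^2) <= fov_r & abs(q[, 3]) <= fov_hz
    vals <- numeric(nrow(q))
    if (any(inside)) {
      p <- true_map(q[inside, , drop = FALSE])
      tex <- cpp_interp3(tex_vol, ctd,
                         sweep(sweep(p, 2, ct_origin, `-`), 2,
                               spec$ct_spacing, `/`), 0, 0L)
      vals[inside] <- spec$intensity_gain *
        (scene_eval(scene, p, contrast = FALSE) +
           body_factor(scene, p) * tex) + spec$intensity_offset
    }
    cb_arr[, , zs + 1L] <- vals
  }
  if (spec$noise_sd > 0) {
    msk <- array(FALSE, dim = cd)  # noise only inside the reconstruction FOV
    xs <- (0:(cd[1] - 1L)) * spec$cbct_spacing + cb_origin[1]
    ys <- (0:(cd[2] - 1L)) * spec$cbct_spacing + cb_origin[2]
    zs <- (0:(cd[3] - 1L)) * spec$cbct_spacing + cb_origin[3]
    rad <- outer(xs^2, ys^2, `+`)
    msk[] <- rep(sqrt(rad) <= fov_r, times = cd[3]) &
      rep(abs(zs) <= fov_hz, each = cd[1] * cd[2])
    noise <- stats::rnorm(sum(msk), 0, spec$noise_sd)
    cb_arr[msk] <- cb_arr[msk] + noise
  }
  cbct <- volume3d(cb_arr, spacing = rep(spec$cbct_spacing, 3),
                   origin = cb_origin)

  ## ---- landmarks -----------------------------------------------------------
  # 3 calcifications nearest the "renal" level, 3 vertebral body corners
  calc_sel <- order(abs(calc$cz))[1:3]
  vert_sel <- order(abs(zc))[1:3]
  lm_ct <- rbind(
    data.frame(label = paste0("calc", 1:3),
               x = calc$cx[calc_sel], y = calc$cy[calc_sel],
               z = calc$cz[calc_sel]),
    data.frame(label = paste0("vert", 1:3),
               x = 0, y = spine_y, z = zc[vert_sel] + 12))
  q_lm <- invert_true_map(true_map, as.matrix(lm_ct[, c("x", "y", "z")]))
  lm_cbct <- data.frame(label = lm_ct$label,
                        x = q_lm[, 1], y = q_lm[, 2], z = q_lm[, 3])
  in_fov <- sqrt(lm_cbct$x^2 + lm_cbct$y^2) <= fov_r & abs(lm_cbct$z) <= fov_hz
  if (!all(in_fov))
    stop("internal phantom inconsistency: landmark(s) outside the CBCT FOV: ",
         paste(lm_cbct$label[!in_fov], collapse = ", "))

  structure(list(ct = ct, cbct = cbct, true_map = true_map,
                 true_affine = true_affine, scene = scene,
                 landmarks_ct = lm_ct, landmarks_cbct = lm_cbct,
                 spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("phantom_pair (seed ", x$spec$seed, ")\n", sep = "")
  cat("  CT:   ", paste(dim(x$ct$data), collapse = " x "), " voxels @ ",
      paste(signif(x$ct$spacing, 3), collapse = "/"), " mm\n", sep = "")
  cat("  CBCT: ", paste(dim(x$cbct$data), collapse = " x "), " voxels @ ",
      signif(x$cbct$spacing[1], 3), " mm (cylindrical FOV ",
      x$spec$cbct_fov[1], " x ", x$spec$cbct_fov[2], " mm)\n", sep = "")
  cat("  ", nrow(x$landmarks_ct), " paired landmarks\n", sep = "")
  invisible(x)
}

#' Dense ground-truth residuals of an estimated map
#'
#' @param pair a [generate_phantom_pair()] result.
#' @param estimated an estimated CBCT-to-CT transform (affine, TPS, or
#'   function).
#' @param sample_points n x 3 matrix of CBCT physical points.
#' @return Numeric vector of residuals
#'   `|| estimated(p) - true_map(p) ||` in mm.
#' @export
true_error_field <- function(pair, estimated, sample_points) {
  p <- as_point_matrix(sample_points)
  sqrt(rowSums((apply_transform(estimated, p) - pair$true_map(p))^2))
}
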