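#' 3D scalar volume with physical-space metadata
#'
#' A `volume3d` holds a 3D intensity grid together with the mapping from
#' 0-based voxel indices to physical millimetre coordinates:
#' `p = origin + direction %*% (index * spacing)`. The origin is the physical
#' position of the *centre* of voxel (0,0,0), and `direction` is a 3x3
#' orthonormal matrix (column i is the physical direction of voxel axis i).
#'
#' @param data 3D numeric array of intensities (arbitrary units; CT values may
#'   be HU-like, cone-beam CT values are uncalibrated).
#' @param spacing numeric length-3, mm per voxel along each array axis; all > 0.
#' @param origin numeric length-3, mm position of the centre of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix; defaults to the identity.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimension(s)")
  if (any(dim(data) < 2L))
    stop("volume grid must have >= 2 voxels per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal (D'D = I within 1e-6)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat("volume3d: ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  cat("  extent (mm):", paste(signif(d * x$spacing, 5), collapse = " x "), "\n")
  cat("  intensity range:", paste(signif(range(x$data), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Map continuous voxel indices to physical points
#'
#' Indices are 0-based and may be fractional or outside the grid (the map is
#' affine and defined everywhere).
#'
#' @param volume a [volume3d].
#' @param index numeric vector of length 3 or an n x 3 matrix of 0-based
#'   voxel coordinates.
#' @return An n x 3 matrix of physical coordinates (mm).
#' @export
voxel_to_physical <- function(volume, index) {
  idx <- if (is.matrix(index)) index else matrix(as.numeric(index), ncol = 3)
  scaled <- sweep(idx, 2, volume$spacing, `*`)
  out <- scaled %*% t(volume$direction)
  sweep(out, 2, volume$origin, `+`)
}

#' Map physical points to continuous voxel indices
#'
#' Inverse of [voxel_to_physical()]; exact to rounding error because the
#' direction matrix is orthonormal.
#'
#' @param volume a [volume3d].
#' @param points numeric vector of length 3 or an n x 3 matrix of physical
#'   coordinates (mm).
#' @return An n x 3 matrix of 0-based continuous voxel coordinates.
#' @export
physical_to_voxel <- function(volume, points) {
  pts <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 3)
  centred <- sweep(pts, 2, volume$origin, `-`)
  local <- centred %*% volume$direction   # = t(direction) %*% p, row-wise
  sweep(local, 2, volume$spacing, `/`)
}

#' Physical corner points of a volume's voxel grid
#' @param volume a [volume3d].
#' @return 8 x 3 matrix of the physical positions of the corner voxel centres.
#' @export
volume_corners <- function(volume) {
  d <- dim(volume$data) - 1L
  idx <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  voxel_to_physical(volume, idx)
}

## ---- file I/O --------------------------------------------------------------

#' Read a volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) via the RNifti library and
#' MetaImage (`.mha`, single-file). The physical frame is taken from the file
#' header (voxel-centre origin, direction-matrix convention); no axis
#' reordering is performed.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"nifti"` or `"mha"`.
#' @return A [volume3d].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "mha")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mha$", path, ignore.case = TRUE)) "mha" else "nifti"
  }
  if (format == "mha") return(read_mha(path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), "D: ", path)
  xf <- RNifti::xform(img)
  lin <- unclass(xf)[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(lin^2))
  direction <- sweep(lin, 2, spacing, `/`)
  origin <- unclass(xf)[1:3, 4]
  arr <- array(as.numeric(img), dim = d)
  volume3d(arr, spacing = spacing, origin = origin, direction = direction)
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param volume a [volume3d].
#' @param path output path; `.mha` selects MetaImage, anything else NIfTI.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(write_mha(volume, path))
  img <- RNifti::asNifti(volume$data)
  m <- rbind(cbind(volume$direction %*% diag(volume$spacing), volume$origin),
             c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Minimal MetaImage (.mha) reader: ASCII header followed by a local raw block.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (ElementDataFile = LOCAL) MetaImage is supported")
  if (!identical(as.integer(hdr[["NDims"]]), 3L))
    stop("expected a 3D image, got NDims = ", hdr[["NDims"]], ": ", path)
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(hdr[["TransformMatrix"]]))
    matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]), 3, 3)
  else diag(3)
  type <- hdr[["ElementType"]]
  n <- prod(d)
  vals <- switch(type,
    "MET_DOUBLE" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "MET_FLOAT"  = readBin(con, "double", n = n, size = 4, endian = "little"),
    "MET_SHORT"  = as.numeric(readBin(con, "integer", n = n, size = 2,
                                      signed = TRUE, endian = "little")),
    "MET_USHORT" = as.numeric(readBin(con, "integer", n = n, size = 2,
                                      signed = FALSE, endian = "little")),
    "MET_UCHAR"  = as.numeric(readBin(con, "integer", n = n, size = 1,
                                      signed = FALSE, endian = "little")),
    stop("unsupported MetaImage ElementType: ", type))
  if (length(vals) != n) stop("truncated MetaImage pixel data: ", path)
  volume3d(array(vals, dim = d), spacing = spacing, origin = origin,
           direction = direction)
}

write_mha <- function(volume, path) {
  d <- dim(volume$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("TransformMatrix =", paste(format(as.numeric(volume$direction),
                                            digits = 17), collapse = " ")),
    paste("Offset =", paste(format(volume$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(volume$spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

## ---- resampling ------------------------------------------------------------

#' Resample a volume onto a reference grid
#'
#' Every voxel of `reference` is mapped through `transform` (a map from the
#' reference's physical space to the source's physical space) and the source
#' is interpolated there. Points falling outside the source grid receive
#' `fill`.
#'
#' @param source a [volume3d] supplying intensities.
#' @param reference a [volume3d] supplying the output grid and metadata.
#' @param transform `NULL` (identity), an [affine_transform3d], a
#'   [fit_tps()] result, or a function mapping an n x 3 matrix of reference
#'   physical points to n x 3 source physical points.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill fill value for out-of-source points (default 0).
#' @return A [volume3d] on the reference grid.
#' @export
resample_into <- function(source, reference, transform = NULL,
                          interpolation = c("trilinear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  mode <- if (interpolation == "nearest") 1L else 0L
  d <- dim(reference$data)
  out <- numeric(prod(d))
  # process in z-slabs to bound the size of the coordinate matrices
  slab <- max(1L, as.integer(ceiling(2e6 / (d[1] * d[2]))))
  ij <- as.matrix(expand.grid(x = 0:(d[1] - 1L), y = 0:(d[2] - 1L)))
  for (z0 in seq(0L, d[3] - 1L, by = slab)) {
    zs <- z0:min(z0 + slab - 1L, d[3] - 1L)
    idx <- cbind(ij[rep(seq_len(nrow(ij)), times = length(zs)), , drop = FALSE],
                 rep(zs, each = nrow(ij)))
    pts <- voxel_to_physical(reference, idx)
    mapped <- if (is.null(transform)) pts else apply_transform(transform, pts)
    src_idx <- physical_to_voxel(source, mapped)
    vals <- cpp_interp3(as.numeric(source$data), dim(source$data), src_idx,
                        fill, mode)
    out[(z0 * d[1] * d[2] + 1L):((z0 + length(zs)) * d[1] * d[2])] <- vals
  }
  volume3d(array(out, dim = d), spacing = reference$spacing,
           origin = reference$origin, direction = reference$direction)
}

#' Resample a volume to an isotropic grid covering the same extent
#'
#' @param volume a [volume3d].
#' @param spacing target isotropic spacing (mm).
#' @param interpolation passed to [resample_into()].
#' @return A [volume3d] with isotropic spacing.
#' @export
resample_isotropic <- function(volume, spacing = 1.5,
                               interpolation = "trilinear") {
  d <- dim(volume$data)
  extent <- (d - 1) * volume$spacing
  nd <- pmax(2L, as.integer(floor(extent / spacing)) + 1L)
  ref <- volume3d(array(0, dim = nd), spacing = rep(spacing, 3),
                  origin = volume$origin, direction = volume$direction)
  resample_into(volume, ref, transform = NULL, interpolation = interpolation)
}
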