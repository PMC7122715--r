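#' 3-D voxel image with world-coordinate geometry
#'
#' A `voxel_image` couples a 3-D array with the metadata needed to map voxel
#' indices to world millimetres: per-axis spacing, an origin and a 3x3
#' orthonormal direction matrix. The mapping is
#' `world = origin + direction %*% (index0 * spacing)` with 0-based indices;
#' all package geometry (centerlines, meshes, point clouds) lives in world mm
#' and voxel indices never leave the image modules.
#'
#' @param array numeric or integer 3-D array, axis order (x, y, z).
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix of axis direction cosines
#'   (columns are the world directions of the image axes).
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(array, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (length(dim(array)) != 3L || any(dim(array) < 1L))
    stop("'array' must be a 3-D array with all dims >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("'direction' must be orthonormal within 1e-6")
  structure(list(array = array, spacing = spacing, origin = origin,
                 direction = direction),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("voxel_image:", paste(dim(x$array), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm\n")
  invisible(x)
}

#' @rdname voxel_image
#' @param img a `voxel_image`.
#' @param index0 n x 3 matrix of 0-based voxel indices.
#' @return `index_to_world()`: n x 3 matrix of world positions (mm).
#' @export
index_to_world <- function(img, index0) {
  index0 <- rbind_mat(index0)
  m <- img$direction %*% diag(img$spacing)
  sweep(index0 %*% t(m), 2L, img$origin, "+")
}

#' @rdname voxel_image
#' @param points n x 3 matrix of world positions (mm).
#' @return `world_to_index()`: n x 3 matrix of fractional 0-based indices.
#' @export
world_to_index <- function(img, points) {
  points <- rbind_mat(points)
  m <- solve(img$direction %*% diag(img$spacing))
  sweep(points, 2L, img$origin, "-") %*% t(m)
}

rbind_mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

# Array value at the voxel nearest to each world point; `outside` for points
# beyond the grid.
value_at_world <- function(img, points, outside = 0) {
  idx <- round(world_to_index(img, points)) + 1
  d <- dim(img$array)
  ok <- idx[, 1L] >= 1 & idx[, 1L] <= d[1L] &
        idx[, 2L] >= 1 & idx[, 2L] <= d[2L] &
        idx[, 3L] >= 1 & idx[, 3L] <= d[3L]
  out <- rep(outside, nrow(idx))
  if (any(ok))
    out[ok] <- img$array[cbind(idx[ok, 1L], idx[ok, 2L], idx[ok, 3L])]
  out
}

# World coordinates of all voxels with a given label (n x 3).
label_voxel_centers <- function(img, label) {
  w <- which(img$array == label, arr.ind = TRUE)
  if (nrow(w) == 0L) stop(sprintf("label %s not present in image", label))
  index_to_world(img, w - 1)
}

#' Read a 3-D volume (MetaImage MHD/raw or NIfTI-1)
#'
#' Supported extensions: `.mhd` (MetaImage header + raw), `.nii`, `.nii.gz`.
#' The reader normalizes both formats to the same convention: 0-based indices,
#' axis order (x, y, z), world mapping
#' `origin + direction %*% (index0 * spacing)`.
#'
#' @param path file path.
#' @return A [voxel_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  lp <- tolower(path)
  if (grepl("\\.mhd$", lp)) return(read_mhd(path))
  if (grepl("\\.nii$", lp) || grepl("\\.nii\\.gz$", lp)) return(read_nifti_vi(path))
  stop(sprintf("unsupported image extension: %s (use .mhd, .nii or .nii.gz)", path))
}

#' Write a 3-D volume (MetaImage MHD/raw or NIfTI-1)
#'
#' @param img a [voxel_image].
#' @param path output path; format chosen by extension (`.mhd`, `.nii`,
#'   `.nii.gz`). MHD output writes a sibling `.raw` file.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  lp <- tolower(path)
  if (grepl("\\.mhd$", lp)) return(write_mhd(img, path))
  if (grepl("\\.nii$", lp) || grepl("\\.nii\\.gz$", lp)) return(write_nifti_vi(img, path))
  stop(sprintf("unsupported image extension: %s (use .mhd, .nii or .nii.gz)", path))
}

# -- MetaImage -----------------------------------------------------------

mhd_types <- c(MET_UCHAR = "uchar", MET_CHAR = "char", MET_SHORT = "short",
               MET_USHORT = "ushort", MET_INT = "int", MET_UINT = "uint",
               MET_FLOAT = "float", MET_DOUBLE = "double")

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*?)\\s*$", lines))
  hdr <- list()
  for (m in kv) if (length(m) == 3L) hdr[[m[2L]]] <- m[3L]
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("malformed MHD header %s: missing %s", path,
                 paste(miss, collapse = ", ")))
  if (as.integer(hdr$NDims) != 3L)
    stop(sprintf("%s: only NDims = 3 is supported", path))
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1L]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  direction <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1L]]), 3L, 3L)
  else diag(3)
  et <- hdr$ElementType
  if (!et %in% names(mhd_types))
    stop(sprintf("%s: unsupported ElementType %s", path, et))
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    rawpath <- path
    # data follows the header in the same file; find the byte offset
    skip <- sum(nchar(lines, type = "bytes") + 1L)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    skip <- 0L
  }
  if (!file.exists(rawpath))
    stop(sprintf("MHD data file not found: %s (referenced by %s)", rawpath, path))
  n <- prod(dims)
  sizes <- c(uchar = 1L, char = 1L, short = 2L, ushort = 2L, int = 4L,
             uint = 4L, float = 4L, double = 8L)
  ty <- mhd_types[[et]]
  sz <- sizes[[ty]]
  con <- file(rawpath, "rb")
  on.exit(close(con))
  if (skip > 0L) readBin(con, "raw", n = skip)
  what <- if (ty %in% c("float", "double")) "double" else "integer"
  vals <- readBin(con, what, n = n, size = sz,
                  signed = !(ty %in% c("uchar", "ushort")),
                  endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop(sprintf("truncated MHD data in %s: expected %d values, got %d (byte offset %d)",
                 rawpath, n, length(vals), skip + length(vals) * sz))
  voxel_image(array(vals, dim = dims), spacing, origin, direction)
}

write_mhd <- function(img, path) {
  a <- img$array
  intish <- all(a == round(a)) && !anyNA(a)
  if (intish && min(a) >= 0 && max(a) <= 255) {
    et <- "MET_UCHAR"; what <- as.integer(a); size <- 1L
  } else if (intish && min(a) >= -2147483647 && max(a) <= 2147483647) {
    et <- "MET_INT"; what <- as.integer(a); size <- 4L
  } else {
    et <- "MET_DOUBLE"; what <- as.double(a); size <- 8L
  }
  rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(as.vector(img$direction), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(img$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(img$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(a), collapse = " ")),
    paste("ElementType =", et),
    paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(what, con, size = size, endian = "little")
  invisible(path)
}

# -- NIfTI (delegated to RNifti) ----------------------------------------

read_nifti_vi <- function(path) {
  nii <- RNifti::readNifti(path)
  m <- RNifti::xform(nii)
  a <- as.array(nii)
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    stop(sprintf("%s: only 3-D NIfTI volumes are supported", path))
  lin <- m[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  direction <- sweep(lin, 2L, spacing, "/")
  voxel_image(a, spacing, m[1:3, 4L], direction)
}

write_nifti_vi <- function(img, path) {
  nii <- RNifti::asNifti(img$array)
  m <- rbind(cbind(img$direction %*% diag(img$spacing), img$origin),
             c(0, 0, 0, 1))
  nii <- RNifti::`sform<-`(nii, structure(m, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
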