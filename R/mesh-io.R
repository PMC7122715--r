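#' Read / write triangular surface meshes (OBJ, PLY, STL)
#'
#' Formats are chosen by extension. OBJ and PLY are written/read as ASCII;
#' STL is written as ASCII and read in both ASCII and binary form. STL stores
#' one vertex triple per facet, so [read_mesh()] re-welds coincident vertices
#' on STL input. Only triangle faces are supported; quads raise an error.
#'
#' @param path file path ending in `.obj`, `.ply` or `.stl`.
#' @return `read_mesh()`: a [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path),
         stop(sprintf("unsupported mesh extension: .%s (use .obj, .ply or .stl)", ext)))
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         stop(sprintf("unsupported mesh extension: .%s (use .obj, .ply or .stl)", ext)))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  tag <- vapply(toks, function(t) if (length(t)) t[1L] else "", "")
  vl <- toks[tag == "v"]
  fl <- toks[tag == "f"]
  verts <- do.call(rbind, lapply(vl, function(t) as.numeric(t[2:4])))
  faces <- lapply(fl, function(t) {
    idx <- t[-1L]
    if (length(idx) != 3L)
      stop(sprintf("%s: unsupported element with %d vertices (triangles only)",
                   path, length(idx)))
    as.integer(sub("/.*$", "", idx))
  })
  surface_mesh(verts, do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", fmt_num(mesh$vertices[, 1L]),
                   fmt_num(mesh$vertices[, 2L]), fmt_num(mesh$vertices[, 3L])), con)
  writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1L], "ply"))
    stop(sprintf("%s: not a PLY file", path))
  endh <- match("end_header", lines)
  if (is.na(endh)) stop(sprintf("%s: PLY header not terminated", path))
  hdr <- lines[seq_len(endh)]
  if (any(grepl("^format\\s+binary", hdr)))
    stop(sprintf("%s: binary PLY is not supported", path))
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(endh + 1L):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(t) as.numeric(t[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- lapply(frows, function(t) {
    cnt <- as.integer(t[1L])
    if (cnt != 3L)
      stop(sprintf("%s: unsupported element with %d vertices (triangles only)", path, cnt))
    as.integer(t[2:4]) + 1L  # PLY face indices are 0-based
  })
  surface_mesh(verts, do.call(rbind, faces))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1L]), fmt_num(mesh$vertices[, 2L]),
                   fmt_num(mesh$vertices[, 3L])), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5L)
  mesh <- if (identical(rawToChar(head), "solid")) read_stl_ascii(path)
          else read_stl_binary(path)
  weld_vertices(mesh)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop(sprintf("%s: STL vertex count not a multiple of 3", path))
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = nf * 50L)
  if (length(rec) != nf * 50L)
    stop(sprintf("truncated binary STL %s at byte offset %d", path, 84L + length(rec)))
  m <- matrix(rec, nrow = 50L)
  coords <- vapply(seq_len(nf), function(i) {
    readBin(m[13:48, i], "double", n = 9L, size = 4L, endian = "little")
  }, numeric(9L))
  verts <- matrix(t(coords), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  nrm <- face_normals(mesh)
  v1 <- face_corner(mesh, 1L); v2 <- face_corner(mesh, 2L); v3 <- face_corner(mesh, 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lungtree", con)
  body <- paste0("facet normal ", fmt_num(nrm[, 1L]), " ", fmt_num(nrm[, 2L]),
                 " ", fmt_num(nrm[, 3L]), "\n",
                 "outer loop\n",
                 "vertex ", fmt_num(v1[, 1L]), " ", fmt_num(v1[, 2L]), " ", fmt_num(v1[, 3L]), "\n",
                 "vertex ", fmt_num(v2[, 1L]), " ", fmt_num(v2[, 2L]), " ", fmt_num(v2[, 3L]), "\n",
                 "vertex ", fmt_num(v3[, 1L]), " ", fmt_num(v3[, 2L]), " ", fmt_num(v3[, 3L]), "\n",
                 "endloop\nendfacet")
  writeLines(body, con)
  writeLines("endsolid lungtree", con)
}
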