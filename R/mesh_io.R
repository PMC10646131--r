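# STL (ASCII and binary) and ASCII PLY readers/writers. Vertices are in mm.
# STL stores triangle soup; on read, vertices are welded by exact coordinate
# match (identical input coordinates map to identical float32 patterns, so a
# write-read round trip preserves the vertex count of a welded mesh).

#' Read a surface mesh from STL or PLY
#'
#' The format is chosen from the file extension (`.stl` or `.ply`). Both
#' binary and ASCII STL dialects are handled; PLY must be ASCII.
#'
#' @param path file path.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) kt_format_error(paste("no such mesh file:", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         kt_format_error(sprintf("unknown mesh extension '.%s' for '%s' (want .stl or .ply)",
                                 ext, path)))
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path file path ending in `.stl` or `.ply`.
#' @param binary for STL, write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         kt_format_error(sprintf("unknown mesh extension '.%s' (want .stl or .ply)", ext)))
  invisible(path)
}

## ---- STL -------------------------------------------------------------------

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "binary STL (kneetrack)"))
  writeBin(hdr[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- face_normals(mesh)
  tri <- mesh$vertices[t(mesh$faces), , drop = FALSE]     # 3 rows per face
  # interleave: normal, v1, v2, v3 as 12 floats per face
  block <- matrix(0, nrow = 12L, ncol = nf)
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(tri[seq(1L, 3L * nf, by = 3L), , drop = FALSE])
  block[7:9, ] <- t(tri[seq(2L, 3L * nf, by = 3L), , drop = FALSE])
  block[10:12, ] <- t(tri[seq(3L, 3L * nf, by = 3L), , drop = FALSE])
  for (i in seq_len(nf)) {
    writeBin(block[, i], con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  nrm <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  lines <- character(7L * nrow(f) + 2L)
  lines[1L] <- "solid kneetrack"
  k <- 1L
  for (i in seq_len(nrow(f))) {
    lines[k + 1L] <- sprintf("  facet normal %.9g %.9g %.9g",
                             nrm[i, 1L], nrm[i, 2L], nrm[i, 3L])
    lines[k + 2L] <- "    outer loop"
    for (j in 1:3)
      lines[k + 2L + j] <- sprintf("      vertex %.9g %.9g %.9g",
                                   v[f[i, j], 1L], v[f[i, j], 2L], v[f[i, j], 3L])
    lines[k + 6L] <- "    endloop"
    lines[k + 7L] <- "  endfacet"
    k <- k + 7L
  }
  lines[k + 1L] <- "endsolid kneetrack"
  writeLines(lines, path)
  invisible(path)
}

is_ascii_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 512L)
  # raw-level check: binary STLs contain arbitrary bytes, so never decode
  length(grepRaw("solid", head_raw[seq_len(min(16L, length(head_raw)))],
                 fixed = TRUE)) > 0L &&
    length(grepRaw("facet", head_raw, fixed = TRUE)) > 0L
}

read_stl <- function(path) {
  if (is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84L)
    kt_format_error(sprintf("corrupt binary STL '%s': shorter than header", path))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nf <= 0 || sz < 84 + 50 * nf)
    kt_format_error(sprintf(
      "corrupt or truncated binary STL '%s': %d facets declared, %d bytes present",
      path, nf, sz))
  raw_body <- readBin(con, "raw", n = 50L * nf)
  # each 50-byte record: 12 float32 then uint16; drop the attribute bytes
  keep <- rep(c(rep(TRUE, 48L), FALSE, FALSE), nf)
  floats <- readBin(raw_body[keep], "numeric", n = 12L * nf, size = 4L,
                    endian = "little")
  m <- matrix(floats, nrow = 12L)
  tri <- rbind(t(m[4:6, , drop = FALSE]), t(m[7:9, , drop = FALSE]),
               t(m[10:12, , drop = FALSE]))
  # rows currently grouped v1...v1, v2...v2, v3...v3; reorder per-face
  idx <- c(t(matrix(seq_len(3L * nf), ncol = 3L)))
  weld_triangles(tri[idx, , drop = FALSE], path)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vlines) || length(vlines) %% 3L != 0L)
    kt_format_error(sprintf("corrupt ASCII STL '%s': vertex count %d not a multiple of 3",
                            path, length(vlines)))
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3L)))
  if (anyNA(nums)) kt_format_error(sprintf("corrupt ASCII STL '%s': bad vertex line", path))
  weld_triangles(nums, path)
}

weld_triangles <- function(tri, path) {
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L])
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  surface_mesh(verts, faces[!degen, , drop = FALSE])
}

## ---- PLY (ASCII) -----------------------------------------------------------

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0", "comment kneetrack",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L])
  fl <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || txt[1L] != "ply")
    kt_format_error(sprintf("'%s' is not a PLY file", path))
  if (!any(grepl("^format ascii", txt[1:10])))
    kt_format_error(sprintf("'%s': only ASCII PLY is supported", path))
  endh <- match("end_header", txt)
  if (is.na(endh)) kt_format_error(sprintf("corrupt PLY '%s': no end_header", path))
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", txt, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", txt, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf) || length(txt) < endh + nv + nf)
    kt_format_error(sprintf("corrupt or truncated PLY '%s'", path))
  vrows <- strsplit(trimws(txt[endh + seq_len(nv)]), "\\s+")
  verts <- t(vapply(vrows, function(x) as.numeric(x[1:3]), numeric(3L)))
  frows <- strsplit(trimws(txt[endh + nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(frows, function(x) as.integer(x[2:4]) + 1L, integer(3L)))
  if (anyNA(verts) || anyNA(faces))
    kt_format_error(sprintf("corrupt PLY '%s': unparsable rows", path))
  surface_mesh(verts, faces)
}
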