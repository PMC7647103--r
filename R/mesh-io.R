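# Surface meshes and STL input/output.
#
# CT-derived mandibles are exchanged as STL (binary or ASCII), coordinates in
# millimetres; units are taken as-is, no rescaling. Both dialects are read
# into the same triangle-soup representation with duplicate vertices merged.

#' Triangle surface mesh
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) < 4) stop("a surface mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("mesh coordinates must be finite")
  if (nrow(faces) < 1) stop("a surface mesh needs at least one face")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces; bbox [%.1f..%.1f] x [%.1f..%.1f] x [%.1f..%.1f] mm\n",
              nrow(x$vertices), nrow(x$faces),
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2]),
              min(x$vertices[, 3]), max(x$vertices[, 3])))
  invisible(x)
}

# merge exactly repeated soup vertices into an indexed mesh
soup_to_mesh <- function(tri_coords) {
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3])
  idx <- match(key, key[!duplicated(key)])
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Read a mandible mesh from an STL file
#'
#' Accepts both the binary and the ASCII dialect; the dialect is detected from
#' the file content, not the extension. Coordinates are interpreted as
#' millimetres as-is.
#'
#' @param path Path to an STL file.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 15) stop(sprintf("STL format error at byte 0: file too short (%d bytes)", sz))
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  Encoding(txt) <- "bytes"
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) && grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 84) stop("STL format error at byte 80: binary header truncated")
  invisible(readBin(con, "raw", n = 80))
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + ntri * 50
  if (sz != expected)
    stop(sprintf("STL format error at byte %d: expected %d triangles (%d bytes), file has %d bytes",
                 84, ntri, expected, sz))
  raw <- readBin(con, "raw", n = ntri * 50)
  m <- matrix(raw, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * ntri, endian = "little")
  fl <- matrix(fl, ncol = 12, byrow = TRUE)           # normal + 3 vertices
  coords <- rbind(fl[, 4:6, drop = FALSE], fl[, 7:9, drop = FALSE], fl[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  soup_to_mesh(coords[ord, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("STL format error: ASCII file contains no vertex records")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  coords <- do.call(rbind, nums)
  if (any(!is.finite(coords)) || nrow(coords) %% 3 != 0)
    stop("STL format error: malformed ASCII vertex records")
  soup_to_mesh(coords)
}

#' Write a mesh as STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  V <- mesh$vertices
  # both STL dialects carry float32 coordinates (the ASCII writer prints the
  # float32-rounded value exactly), so they read back identically
  V[] <- readBin(writeBin(as.numeric(V), raw(), size = 4), "numeric",
                 size = 4, n = length(V))
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    block <- cbind(nrm, a, b, c_)
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mandimorph", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(
        sprintf("  facet normal %.16e %.16e %.16e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.16e %.16e %.16e", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.16e %.16e %.16e", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.16e %.16e %.16e", c_[i, 1], c_[i, 2], c_[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mandimorph", con)
  }
  invisible(path)
}

# rigid/similarity helpers used across tests and the measurement layer
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0), scale = 1) {
  surface_mesh(sweep(scale * mesh$vertices %*% t(R), 2, -as.numeric(t)), mesh$faces)
}

mirror_mesh <- function(mesh) {
  V <- mesh$vertices
  V[, 1] <- -V[, 1]
  surface_mesh(V, mesh$faces[, c(1, 3, 2), drop = FALSE])
}
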