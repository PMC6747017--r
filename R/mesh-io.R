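#' Read a triangulated surface from STL, PLY or OFF
#'
#' Binary and ASCII STL are both accepted (sniffed automatically), PLY is the
#' ASCII dialect and OFF the plain dialect. Coordinates are taken to be mm.
#' Face indices are converted to 1-based at this boundary. STL soups are
#' welded into an indexed mesh; the result is validated.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"off"`; default from the extension.
#' @return a [trimesh].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "ply", "off"))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         off = read_off(path))
}

#' Write a triangulated surface to STL, PLY or OFF
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @param format `"stl"` (binary by default), `"ply"` (ASCII) or `"off"`;
#'   default from the extension.
#' @param binary for STL: write the binary dialect (float32 coordinates).
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "ply", "off"))
  ok <- tryCatch({
    switch(format,
           stl = if (binary) write_stl_bin(mesh, path) else write_stl_ascii(mesh, path),
           ply = write_ply(mesh, path),
           off = write_off(mesh, path))
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(n) && n > 0 && sz == 84 + 50 * as.numeric(n)) is_binary <- TRUE
  }
  if (is_binary) {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little",
                 signed = TRUE)
    seek(con, 80L)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri <- matrix(0, n * 3, 3)
    for (i in seq_len(n)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      if (length(rec) < 12L)
        stop(sprintf("truncated binary STL at byte %d (facet %d of %d)",
                     84 + 50 * (i - 1), i, n))
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2L) # attribute byte count
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt)
    if (!length(vl)) {
      bad <- grep("^\\s*(solid|facet|outer|endloop|endfacet|endsolid)", txt,
                  invert = TRUE)
      off <- if (length(bad)) sum(nchar(txt[seq_len(bad[1] - 1)]) + 1L) else 0L
      stop(sprintf("cannot parse ASCII STL (no vertex records); first unrecognised content near byte %d", off))
    }
    toks <- strsplit(trimws(txt[vl]), "\\s+")
    bad <- which(vapply(toks, length, 1L) != 4L)
    if (length(bad)) {
      line <- vl[bad[1]]
      stop(sprintf("malformed STL vertex on line %d (byte offset %d)", line,
                   sum(nchar(txt[seq_len(line - 1)]) + 1L)))
    }
    tri <- do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
    if (any(!is.finite(tri))) stop("non-numeric vertex coordinates in STL")
    if (nrow(tri) %% 3 != 0)
      stop("ASCII STL vertex count is not a multiple of 3")
  }
  weld_soup(tri)
}

# index a triangle soup (3 consecutive rows per face) into a trimesh
weld_soup <- function(tri) {
  key <- apply(round(tri, 6), 1, paste, collapse = " ")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  V <- tri[first, , drop = FALSE]
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(V, F)
}

write_stl_bin <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  F <- mesh$faces
  writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
  V <- mesh$vertices
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c[i, ])), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  F <- mesh$faces
  V <- mesh$vertices
  lines <- c("solid earfield")
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    n <- crossprod_3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    n <- n / max(sqrt(sum(n^2)), 1e-30)
    lines <- c(lines,
               sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
               "    endloop", "  endfacet")
  }
  writeLines(c(lines, "endsolid earfield"), path)
  invisible(path)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || trimws(txt[1]) != "ply")
    stop("not a PLY file (missing 'ply' magic at byte 0)")
  hend <- match("end_header", trimws(txt))
  if (is.na(hend)) stop("PLY header has no end_header")
  header <- txt[seq_len(hend)]
  if (any(grepl("^format\\s+binary", header)))
    stop("binary PLY is not supported; write ASCII PLY")
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face element counts")
  body <- txt[(hend + 1):length(txt)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop(sprintf("PLY body truncated near byte %d",
                 sum(nchar(txt[seq_len(hend)]) + 1L)))
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vt, function(t) as.numeric(t[1:3])))
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- do.call(rbind, lapply(ft, function(t) {
    n <- as.integer(t[1])
    if (n != 3L) stop("only triangular PLY faces are supported")
    as.integer(t[2:4])
  }))
  trimesh(V, F + 1L)
}

write_ply <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces - 1L
  hdr <- c("ply", "format ascii 1.0", "comment earfield surface (mm)",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
  fl <- sprintf("3 %d %d %d", F[, 1], F[, 2], F[, 3])
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!length(txt) || trimws(txt[1]) != "OFF")
    stop("not an OFF file (missing 'OFF' magic at byte 0)")
  cnt <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- cnt[1]
  nf <- cnt[2]
  if (length(txt) < 2 + nv + nf) stop("OFF file truncated")
  vt <- strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vt, function(t) as.numeric(t[1:3])))
  ft <- strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+")
  F <- do.call(rbind, lapply(ft, function(t) {
    if (as.integer(t[1]) != 3L) stop("only triangular OFF faces are supported")
    as.integer(t[2:4])
  }))
  trimesh(V, F + 1L)
}

write_off <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces - 1L
  writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(F)),
               sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("3 %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  invisible(path)
}

#' Read labeled 3D points ("label x y z" in mm, '#' comments)
#'
#' The shared plain-text format for fiducials and electrode positions.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
read_fiducials <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  txt <- txt[nzchar(trimws(txt))]
  toks <- strsplit(trimws(txt), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad)) stop("malformed fiducial line ", bad[1], " in ", path)
  out <- data.frame(label = vapply(toks, `[`, "", 1L),
                    x = as.numeric(vapply(toks, `[`, "", 2L)),
                    y = as.numeric(vapply(toks, `[`, "", 3L)),
                    z = as.numeric(vapply(toks, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) stop("duplicate labels in ", path)
  if (any(!is.finite(as.matrix(out[, 2:4])))) stop("non-finite coordinates in ", path)
  out
}

#' Write labeled 3D points
#' @param points data.frame with `label`, `x`, `y`, `z` (mm).
#' @param path output path.
#' @export
write_fiducials <- function(points, path) {
  writeLines(c("# label x y z (mm)",
               sprintf("%s %.9g %.9g %.9g", points$label, points$x, points$y,
                       points$z)), path)
  invisible(path)
}

# labeled points as a plain matrix with rownames
fiducial_matrix <- function(points) {
  m <- as.matrix(points[, c("x", "y", "z")])
  rownames(m) <- points$label
  m
}
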