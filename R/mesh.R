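#' Triangulated surface mesh
#'
#' Constructs a `trimesh`: a closed, consistently wound (outward normals,
#' positive signed volume) 2-manifold triangle surface in millimetres.
#' Duplicate vertices closer than `merge_tol` are merged and degenerate faces
#' (area below `area_tol`) dropped before validation.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param labels optional character vector of per-face region labels (e.g.
#'   `"ear"` for a carved region); `NA` for unlabeled faces.
#' @param validate check the closed-manifold invariants (default `TRUE`).
#' @param merge_tol vertices closer than this (mm) are merged at load.
#' @param area_tol faces with area (mm^2) below this are dropped at load.
#' @return an object of class `trimesh` with elements `vertices`, `faces`
#'   (1-based), and optional `labels`.
#' @export
trimesh <- function(vertices, faces, labels = NULL, validate = TRUE,
                    merge_tol = 1e-4, area_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(!is.finite(vertices))) stop("mesh vertices must be finite")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")

  # merge near-duplicate vertices by snapping to a merge_tol grid
  key <- paste(round(vertices[, 1] / merge_tol), round(vertices[, 2] / merge_tol),
               round(vertices[, 3] / merge_tol))
  first <- !duplicated(key)
  if (!all(first)) {
    map <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    faces[] <- map[faces]
  }
  # drop collapsed and degenerate faces
  collapsed <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  keep <- !collapsed & area >= area_tol
  if (!all(keep)) {
    faces <- faces[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  if (length(used) < nrow(vertices)) {
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    faces[] <- remap[faces]
  }
  m <- structure(list(vertices = vertices, faces = faces, labels = labels),
                 class = "trimesh")
  if (validate) {
    v <- validate_mesh(m)
    if (!v$closed)
      stop("surface is not closed: ", v$n_boundary_edges,
           " boundary edge(s), e.g. vertices ",
           paste(utils::head(v$boundary_edges, 3L), collapse = "; "))
    if (!v$manifold)
      stop("surface is not 2-manifold: ", v$n_overused_edges,
           " edge(s) shared by more than two faces")
    if (!v$oriented)
      stop("inconsistent face winding (some edges traversed twice in the ",
           "same direction)")
    if (v$volume < 0) { # consistently wound but inside-out: flip
      m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
    }
  }
  m
}

#' Validate mesh invariants
#'
#' Checks closedness (every edge shared by exactly two faces), manifoldness,
#' consistent winding, and reports the Euler characteristic and signed volume.
#'
#' @param mesh a [trimesh].
#' @return list with `closed`, `manifold`, `oriented`, `euler`, `volume`
#'   (signed, mm^3), `n_vertices`, `n_faces`, plus boundary-edge diagnostics.
#' @export
validate_mesh <- function(mesh) {
  F <- mesh$faces
  nv <- nrow(mesh$vertices)
  ed <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  lo <- pmin(ed[, 1], ed[, 2])
  hi <- pmax(ed[, 1], ed[, 2])
  key <- (lo - 1) * nv + hi # unique undirected key
  cnt <- table(key)
  boundary <- as.numeric(names(cnt)[cnt == 1])
  overused <- as.numeric(names(cnt)[cnt > 2])
  # orientation: each undirected edge must appear once per direction
  dirkey <- (ed[, 1] - 1) * nv + ed[, 2]
  oriented <- !anyDuplicated(dirkey)
  ne <- length(cnt)
  bedges <- if (length(boundary)) {
    paste0(floor((boundary - 1) / nv) + 1, "-", ((boundary - 1) %% nv) + 1)
  } else character(0)
  list(closed = length(boundary) == 0 && length(overused) == 0,
       manifold = length(overused) == 0,
       oriented = oriented,
       euler = nv - ne + nrow(F),
       volume = cpp_mesh_volume(mesh$vertices, mesh$faces - 1L),
       n_vertices = nv, n_faces = nrow(F),
       n_boundary_edges = length(boundary),
       n_overused_edges = length(overused),
       boundary_edges = bedges)
}

#' @export
print.trimesh <- function(x, ...) {
  lab <- if (!is.null(x$labels)) {
    u <- unique(stats::na.omit(x$labels))
    if (length(u)) paste0("; labeled regions: ", paste(u, collapse = ", ")) else ""
  } else ""
  cat(sprintf("trimesh: %d vertices, %d faces, volume %.1f mm^3%s\n",
              nrow(x$vertices), nrow(x$faces),
              cpp_mesh_volume(x$vertices, x$faces - 1L), lab))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward orientation.
#'
#' @param mesh a [trimesh].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) cpp_mesh_volume(mesh$vertices, mesh$faces - 1L)

#' Area-weighted outward vertex normals
#' @param mesh a [trimesh].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) cpp_vertex_normals(mesh$vertices, mesh$faces - 1L)

#' Per-face areas (mm^2) and centroids
#' @param mesh a [trimesh].
#' @return list with `area` (m-vector) and `centroid` (m x 3).
#' @export
face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(area = 0.5 * sqrt(rowSums(cr^2)), centroid = (a + b + c) / 3)
}

#' Signed solid angle subtended by a surface or triangle
#'
#' Uses the standard arctangent (van Oosterom-Strackee) formula per triangle;
#' for a mesh the per-triangle values are summed. For any closed outward
#' surface the result is 4*pi for interior points and 0 for exterior points.
#'
#' @param point numeric 3-vector (mm).
#' @param x a [trimesh], or a 3 x 3 matrix whose rows are triangle vertices.
#' @param tol distance (mm) below which the point counts as on the surface and
#'   a near-singular warning naming the closest triangle is raised.
#' @return solid angle in steradians.
#' @export
solid_angle <- function(point, x, tol = 1e-3) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3)
  if (inherits(x, "trimesh")) {
    cp <- cpp_closest_point(matrix(point, 1), x$vertices, x$faces - 1L)
    if (cp$distance < tol)
      warning(sprintf(paste0("point is within %.2g mm of the surface ",
                             "(triangle %d): solid angle is near-singular"),
                      cp$distance, cp$face + 1L))
    cpp_solid_angle(matrix(point, 1), x$vertices, x$faces - 1L)[1]
  } else {
    tri <- as.matrix(x)
    stopifnot(nrow(tri) == 3, ncol(tri) == 3)
    y <- sweep(tri, 2, point)
    n1 <- sqrt(sum(y[1, ]^2)); n2 <- sqrt(sum(y[2, ]^2)); n3 <- sqrt(sum(y[3, ]^2))
    num <- det(y)
    den <- n1 * n2 * n3 + sum(y[1, ] * y[2, ]) * n3 +
      sum(y[1, ] * y[3, ]) * n2 + sum(y[2, ] * y[3, ]) * n1
    2 * atan2(num, den)
  }
}

#' Minimum distance between two surfaces
#'
#' Exact minimum over all point pairs on the two triangulated surfaces
#' (vertex-face and edge-edge cases are both resolved exactly).
#'
#' @param mesh_a,mesh_b [trimesh] objects.
#' @return list with `distance` (mm) and the closest `point_a`, `point_b`.
#' @export
surface_distance <- function(mesh_a, mesh_b) {
  r <- cpp_mesh_distance(mesh_a$vertices, mesh_a$faces - 1L,
                         mesh_b$vertices, mesh_b$faces - 1L)
  list(distance = r$distance, point_a = as.numeric(r$point_a),
       point_b = as.numeric(r$point_b))
}

#' Distance from points to a surface
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a [trimesh].
#' @return list with `distance` (n), `point` (n x 3 closest surface points) and
#'   `face` (1-based face index).
#' @export
point_surface_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- cpp_closest_point(points, mesh$vertices, mesh$faces - 1L)
  list(distance = as.numeric(r$distance), point = r$point, face = r$face + 1L)
}

#' Are points strictly inside a closed surface?
#' @param points n x 3 matrix (mm).
#' @param mesh a closed [trimesh].
#' @return logical vector.
#' @export
inside_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  as.logical(cpp_inside_mesh(points, mesh$vertices, mesh$faces - 1L))
}

# one round of midpoint (1-to-4) subdivision; labels are inherited
subdivide_midpoint <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  ed <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  lo <- pmin(ed[, 1], ed[, 2])
  hi <- pmax(ed[, 1], ed[, 2])
  key <- (lo - 1) * nv + hi
  ukey <- unique(key)
  midx <- match(key, ukey)
  ulo <- floor((ukey - 1) / nv) + 1
  uhi <- (ukey - 1) %% nv + 1
  mids <- (V[ulo, , drop = FALSE] + V[uhi, , drop = FALSE]) / 2
  Vn <- rbind(V, mids)
  m12 <- nv + midx[seq_len(nrow(F))]
  m23 <- nv + midx[nrow(F) + seq_len(nrow(F))]
  m31 <- nv + midx[2 * nrow(F) + seq_len(nrow(F))]
  Fn <- rbind(cbind(F[, 1], m12, m31),
              cbind(F[, 2], m23, m12),
              cbind(F[, 3], m31, m23),
              cbind(m12, m23, m31))
  labs <- if (!is.null(mesh$labels)) rep(mesh$labels, 4) else NULL
  trimesh(Vn, Fn, labels = labs, validate = FALSE)
}

#' Remesh a surface to a target face count
#'
#' Midpoint subdivision (if refinement is needed) followed by quadric
#' edge-collapse decimation. Faces carrying the `dense_region` label are kept
#' at higher resolution: collapse costs inside the region are scaled by
#' `density_ratio^2` so the mean triangle area there ends up roughly
#' `density_ratio` times smaller than elsewhere.
#'
#' @param mesh a closed [trimesh].
#' @param target_faces requested face count (>= 100); the result is within
#'   about 10 percent of this.
#' @param dense_region optional face-label kept at higher resolution.
#' @param density_ratio target ratio of mean triangle area outside vs inside
#'   the dense region.
#' @return a closed [trimesh]. If decimation would break manifoldness the
#'   input is returned unmodified with a warning.
#' @export
remesh <- function(mesh, target_faces, dense_region = NULL, density_ratio = 4) {
  stopifnot(target_faces >= 100)
  m <- mesh
  # with a dense region the input must be fine enough that the dense patch can
  # keep sub-target-sized triangles while the rest coarsens
  need <- if (is.null(dense_region)) target_faces else 4 * target_faces
  while (nrow(m$faces) < need) m <- subdivide_midpoint(m)
  w <- rep(1, nrow(m$vertices))
  fa <- face_areas(m)$area
  dense_faces <- if (!is.null(dense_region) && !is.null(m$labels)) {
    !is.na(m$labels) & m$labels == dense_region
  } else rep(FALSE, nrow(m$faces))
  if (any(dense_faces)) {
    dv <- unique(as.vector(m$faces[dense_faces, ]))
    w[dv] <- (3 * density_ratio)^2 # length^4 cost => area contrast ~ 3*ratio
    # area budget: dense faces ~ density_ratio times smaller than the rest
    s_d <- sum(fa[dense_faces])
    s_e <- sum(fa[!dense_faces])
    a_d <- (s_d + s_e / density_ratio) / target_faces
    cap_dense <- 1.2 * a_d
    cap_sparse <- 2 * density_ratio * a_d
  } else {
    cap_dense <- -1
    cap_sparse <- 2 * sum(fa) / target_faces # uniform sizing
  }
  r <- cpp_decimate(m$vertices, m$faces - 1L, as.integer(target_faces), w,
                    cap_dense, cap_sparse)
  out <- tryCatch(trimesh(r$vertices, r$faces + 1L), error = function(e) e)
  if (inherits(out, "error") || !validate_mesh(out)$closed) {
    warning("remesh would break manifoldness; returning input unmodified")
    return(mesh)
  }
  # re-attach dense-region labels by proximity to the original labeled patch
  if (!is.null(dense_region) && !is.null(mesh$labels)) {
    sel <- !is.na(mesh$labels) & mesh$labels == dense_region
    if (any(sel)) {
      sub <- submesh(mesh, sel)
      cen <- face_areas(out)$centroid
      edge <- sqrt(mean(face_areas(mesh)$area[sel]))
      tol <- 0.3 * edge # tight: exclude the boundary ring of coarse faces
      d <- cpp_closest_point(cen, sub$vertices, sub$faces - 1L, -1, 3 * edge)$distance
      out$labels <- ifelse(d < tol, dense_region, NA_character_)
    }
  }
  out
}

# face-subset mesh (open; for proximity queries only)
submesh <- function(mesh, face_sel) {
  F <- mesh$faces[face_sel, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  F[] <- remap[F]
  structure(list(vertices = mesh$vertices[used, , drop = FALSE], faces = F,
                 labels = NULL), class = "trimesh")
}
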