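#' Icosphere
#'
#' Geodesic sphere by repeated 1-to-4 subdivision of an icosahedron with
#' reprojection to the sphere; `20 * 4^subdivisions` faces.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of subdivision rounds (0 = icosahedron).
#' @param center optional 3-vector center (mm).
#' @return a [trimesh].
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- trimesh(V, F, validate = FALSE)
  for (i in seq_len(subdivisions)) {
    m <- subdivide_midpoint(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m$vertices <- sweep(m$vertices * radius, 2, center, `+`)
  trimesh(m$vertices, m$faces)
}

# Closed surface of revolution around an axis through `base` with direction
# `axis` (unit). profile: data.frame-ish with columns s (axial position, mm,
# increasing) and r (radius >= 0 at the ends it is capped with a fan).
# Used for the parametric ear-impression solid (concha bowl + canal).
revolve_solid <- function(profile_s, profile_r, axis, base, n_seg = 36) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame
  up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- crossprod_3(axis, up)
  u <- u / sqrt(sum(u^2))
  w <- crossprod_3(axis, u)
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  np <- length(profile_s)
  stopifnot(np >= 2, length(profile_r) == np)
  verts <- list()
  ring_index <- matrix(NA_integer_, np, n_seg)
  nextv <- 0L
  cap_lo <- NA_integer_
  cap_hi <- NA_integer_
  for (i in seq_len(np)) {
    if (profile_r[i] <= 1e-9) next
    ring <- t(vapply(theta, function(t)
      base + axis * profile_s[i] + profile_r[i] * (cos(t) * u + sin(t) * w),
      numeric(3)))
    verts[[length(verts) + 1]] <- ring
    ring_index[i, ] <- nextv + seq_len(n_seg)
    nextv <- nextv + n_seg
  }
  # apex vertices close both ends (flat cap fan when the end radius is
  # positive, cone tip when it tapers to zero)
  verts[[length(verts) + 1]] <- matrix(base + axis * profile_s[1], 1)
  cap_lo <- nextv + 1L
  nextv <- nextv + 1L
  verts[[length(verts) + 1]] <- matrix(base + axis * profile_s[np], 1)
  cap_hi <- nextv + 1L
  nextv <- nextv + 1L
  V <- do.call(rbind, verts)
  F <- list()
  rings <- which(!is.na(ring_index[, 1]))
  for (k in seq_len(length(rings) - 1)) {
    r1 <- ring_index[rings[k], ]
    r2 <- ring_index[rings[k + 1], ]
    for (j in seq_len(n_seg)) {
      jn <- j %% n_seg + 1
      F[[length(F) + 1]] <- c(r1[j], r2[jn], r2[j])
      F[[length(F) + 1]] <- c(r1[j], r1[jn], r2[jn])
    }
  }
  first <- ring_index[rings[1], ]
  last <- ring_index[rings[length(rings)], ]
  for (j in seq_len(n_seg)) {
    jn <- j %% n_seg + 1
    F[[length(F) + 1]] <- c(cap_lo, first[jn], first[j])
    F[[length(F) + 1]] <- c(cap_hi, last[j], last[jn])
  }
  trimesh(V, do.call(rbind, F))
}
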