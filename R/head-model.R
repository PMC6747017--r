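#' Multi-shell head model
#'
#' Ordered nested boundary surfaces `[scalp, outer_skull, inner_skull, brain]`
#' with compartment conductivities. The default conductivities are
#' `sigma_scalp = 0.33`, `sigma_skull = 0.0132`, `sigma_csf = 1.79` and
#' `sigma_brain = 0.33` S/m, assigned to the compartments scalp-to-outer-skull,
#' outer-to-inner-skull, inner-skull-to-brain and inside-brain respectively.
#'
#' @param scalp,outer_skull,inner_skull,brain closed [trimesh] surfaces (mm).
#' @param conductivities named numeric vector with entries `scalp`, `skull`,
#'   `csf`, `brain` (S/m).
#' @param min_distance minimum inter-surface distance the model is expected to
#'   satisfy (mm).
#' @param check verify nesting/distance invariants (default TRUE).
#' @return object of class `head_model` with `surfaces` (named list) and
#'   `conductivities`.
#' @export
head_model <- function(scalp, outer_skull, inner_skull, brain,
                       conductivities = c(scalp = 0.33, skull = 0.0132,
                                          csf = 1.79, brain = 0.33),
                       min_distance = 1, check = TRUE) {
  surfaces <- list(scalp = scalp, outer_skull = outer_skull,
                   inner_skull = inner_skull, brain = brain)
  stopifnot(all(vapply(surfaces, inherits, TRUE, "trimesh")))
  need <- c("scalp", "skull", "csf", "brain")
  if (!all(need %in% names(conductivities)))
    stop("conductivities must be named: ", paste(need, collapse = ", "))
  if (any(conductivities[need] <= 0)) stop("conductivities must be positive")
  m <- structure(list(surfaces = surfaces,
                      conductivities = conductivities[need],
                      min_distance = min_distance),
                 class = "head_model")
  if (check) {
    rep_ <- check_nesting(m)
    if (!all(rep_$nested))
      stop("surfaces are not strictly nested: ",
           paste(rep_$pair[!rep_$nested], collapse = ", "))
  }
  m
}

#' @export
print.head_model <- function(x, ...) {
  cat("head_model (mm):\n")
  for (nm in names(x$surfaces)) {
    s <- x$surfaces[[nm]]
    cat(sprintf("  %-11s %6d faces, volume %10.0f mm^3\n", nm,
                nrow(s$faces), mesh_volume(s)))
  }
  cat(sprintf("  conductivities (S/m): scalp %.3g, skull %.3g, CSF %.3g, brain %.3g\n",
              x$conductivities["scalp"], x$conductivities["skull"],
              x$conductivities["csf"], x$conductivities["brain"]))
  invisible(x)
}

#' Check nesting and minimum-distance invariants of a head model
#'
#' For every adjacent surface pair, tests that all vertices of the inner
#' surface lie strictly inside the outer one and that the pairwise surface
#' distance is at least `dmin`.
#'
#' @param model a [head_model].
#' @param dmin minimum distance (mm); default the model's `min_distance`.
#' @return data.frame with one row per adjacent pair: `pair`, `nested`
#'   (logical), `distance` (mm), `distance_ok`, and the worst offending
#'   vertex index of the inner surface (`worst_vertex`, NA when nested).
#' @export
check_nesting <- function(model, dmin = model$min_distance) {
  s <- model$surfaces
  nm <- names(s)
  out <- NULL
  for (k in 1:3) {
    outer <- s[[k]]
    inner <- s[[k + 1]]
    ins <- inside_mesh(inner$vertices, outer)
    worst <- NA_integer_
    if (!all(ins)) {
      d <- point_surface_distance(inner$vertices[!ins, , drop = FALSE], outer)$distance
      worst <- which(!ins)[which.max(d)]
    }
    dist <- surface_distance(outer, inner)$distance
    out <- rbind(out, data.frame(pair = paste(nm[k], nm[k + 1], sep = "-"),
                                 nested = all(ins), distance = dist,
                                 distance_ok = dist >= dmin,
                                 worst_vertex = worst))
  }
  out
}

#' Carve ear-impression volumes out of the scalp surface
#'
#' Boolean volume difference `scalp - union(impressions)` computed by
#' implicit-surface extraction (marching tetrahedra on a lattice with exact
#' edge-surface intersections), then decimated back to about the input
#' resolution with the carved region kept denser. Faces on the carved surface
#' are labeled `"ear"`.
#'
#' @param scalp closed [trimesh].
#' @param impressions a single [trimesh] or list of 1-2 registered impression
#'   meshes intersecting the scalp volume.
#' @param voxel lattice spacing (mm) for the boolean extraction.
#' @param target_faces face budget of the carved result; default keeps about
#'   the input count plus the ear region.
#' @param density_ratio how much denser the carved "ear" region is kept.
#' @return carved scalp [trimesh] with `"ear"` face labels.
#' @export
carve_ears <- function(scalp, impressions, voxel = 0.8, target_faces = NULL,
                       density_ratio = 4) {
  if (inherits(impressions, "trimesh")) impressions <- list(impressions)
  stopifnot(length(impressions) >= 1, length(impressions) <= 2)
  # impressions entirely outside the scalp volume do not carve
  act <- vapply(impressions, function(im) {
    any(inside_mesh(im$vertices, scalp)) ||
      any(inside_mesh(scalp$vertices, im))
  }, TRUE)
  if (!any(act)) {
    warning("impression(s) entirely outside the scalp volume; scalp unchanged")
    return(scalp)
  }
  impressions <- impressions[act]
  r <- cpp_boolean_difference(scalp$vertices, scalp$faces - 1L,
                              lapply(impressions, `[[`, "vertices"),
                              lapply(impressions, function(im) im$faces - 1L),
                              voxel, 3 * voxel)
  # keep slivers intact here (merging would open the surface); decimation
  # below removes them
  cur <- tryCatch(trimesh(r$vertices, r$faces + 1L, merge_tol = 1e-9,
                          area_tol = 0),
                  error = function(e)
                    stop("boolean difference produced a non-manifold ",
                         "surface: ", conditionMessage(e), call. = FALSE))
  if (is.null(target_faces)) target_faces <- max(nrow(scalp$faces), 2000L)
  # label carved faces by proximity to the impression surfaces, then decimate
  cur$labels <- label_near(cur, impressions, 1.5 * voxel)
  out <- remesh(cur, target_faces, dense_region = "ear",
                density_ratio = density_ratio)
  out$labels <- label_near(out, impressions, 1.5 * voxel)
  out
}

label_near <- function(mesh, impressions, tol) {
  cen <- face_areas(mesh)$centroid
  near <- rep(FALSE, nrow(cen))
  for (im in impressions) {
    d <- cpp_closest_point(cen, im$vertices, im$faces - 1L, -1, 3 * tol)$distance
    near <- near | d < tol
  }
  ifelse(near, "ear", NA_character_)
}

#' Enforce a minimum distance between nested head-model surfaces
#'
#' Processes surface pairs from the outside in (scalp, outer skull, inner
#' skull, brain): vertices of the inner surface closer than `dmin` to the
#' already-fixed outer surface are displaced inward along their area-weighted
#' vertex normals, followed by a few Laplacian smoothing iterations on the
#' displaced patch; repeated until the pairwise distance is at least `dmin`.
#' A model that already satisfies `dmin` is returned unchanged.
#'
#' @param model a [head_model] (nesting may violate `dmin`, e.g. after
#'   carving).
#' @param dmin minimum inter-surface distance (mm).
#' @param smooth_iters Laplacian smoothing iterations per displacement round.
#' @param max_rounds maximum displacement rounds per surface pair.
#' @return a [head_model] satisfying nesting and the `dmin` rule.
#' @export
enforce_min_distance <- function(model, dmin = 1, smooth_iters = 5,
                                 max_rounds = 30) {
  s <- model$surfaces
  for (k in 2:4) {
    outer <- s[[k - 1]]
    inner <- s[[k]]
    s[[k]] <- push_inside(inner, outer, dmin, smooth_iters, max_rounds,
                          name = names(s)[k])
  }
  out <- model
  out$surfaces <- s
  out$min_distance <- dmin
  rep_ <- check_nesting(out, dmin)
  if (!all(rep_$nested & rep_$distance_ok))
    stop("could not enforce the minimum distance: ",
         paste(rep_$pair[!(rep_$nested & rep_$distance_ok)], collapse = ", "))
  out
}

# displace `inner` inward until >= dmin from the fixed `outer` surface.
# Per round, a required inward displacement is gathered at the inner-surface
# vertices from two sides (inner vertices too close to `outer`, and `outer`
# vertices too close to / intruding into the inner volume, which catches thin
# features passing between coarse inner-mesh vertices), turned into a smooth
# field by decayed dilation plus Laplacian smoothing over the patch, and
# applied along the inward vertex normals.
push_inside <- function(inner, outer, dmin, smooth_iters, max_rounds, name) {
  d0 <- point_surface_distance(inner$vertices, outer)$distance
  inside0 <- inside_mesh(inner$vertices, outer)
  if (all(inside0) && min(d0) >= dmin &&
      surface_distance(outer, inner)$distance >= dmin)
    return(inner) # bitwise unchanged
  vol0 <- mesh_volume(inner)
  adj <- vertex_adjacency(inner)
  m <- inner
  slack <- 0.1
  for (round in seq_len(max_rounds)) {
    req <- numeric(nrow(m$vertices))
    # inner vertices vs the fixed surface
    pr <- point_surface_distance(m$vertices, outer)
    ins <- inside_mesh(m$vertices, outer)
    d <- ifelse(ins, pr$distance, -pr$distance) # signed clearance
    req <- pmax(req, dmin + slack - d) * (d < dmin)
    # fixed-surface vertices vs the inner volume (sub-vertex features such as
    # a carved canal passing between coarse inner-mesh vertices): the inner
    # surface is star-shaped here, so every inner vertex radially aligned with
    # a too-close fixed vertex must sink below it
    pr2 <- cpp_closest_point(outer$vertices, m$vertices, m$faces - 1L,
                             -1, 4 * dmin)
    ins2 <- inside_mesh(outer$vertices, m)
    d2 <- ifelse(ins2, -pr2$distance, pr2$distance)
    close2 <- which(is.finite(d2) & d2 < dmin)
    if (length(close2)) {
      ctr <- colMeans(m$vertices)
      vv <- sweep(m$vertices, 2, ctr)
      rv <- sqrt(rowSums(vv^2))
      vhat <- vv / rv
      h <- 1.5 * sqrt(mean(face_areas(m)$area)) # about one edge length
      for (i in close2) {
        p <- outer$vertices[i, ] - ctr
        rp <- sqrt(sum(p^2))
        cos0 <- cos(min(h / rp, pi / 4))
        sel <- as.numeric(vhat %*% (p / rp)) > cos0 & rv > rp - dmin - slack
        req[sel] <- pmax(req[sel], rv[sel] - (rp - dmin - slack))
      }
    }
    if (max(req) <= 0) {
      if (surface_distance(outer, m)$distance >= dmin) break
      # residual edge-edge proximity: nudge the closest patch
      cp <- cpp_closest_point(matrix(surface_distance(outer, m)$point_b, 1),
                              m$vertices, m$faces - 1L)
      req[m$faces[cp$face + 1L, ]] <- 0.5
    }
    req <- pmin(req, 2) # cap per-round displacement: dent gradually
    disp <- req
    for (it in 1:6) { # decayed dilation spreads the dent smoothly
      nmax <- vapply(seq_along(disp), function(v)
        max(disp[adj[[v]]], 0), numeric(1))
      disp <- pmax(disp, 0.65 * nmax)
    }
    patch <- which(disp > 0)
    for (it in seq_len(smooth_iters)) {
      upd <- vapply(patch, function(v) mean(disp[adj[[v]]]), numeric(1))
      disp[patch] <- pmax(0.5 * disp[patch] + 0.5 * upd, req[patch])
    }
    # inward direction: radial toward the surface centroid (vertex normals
    # point into the carved tube once a dent forms and trap vertices there)
    ctr <- colMeans(m$vertices)
    dirs <- sweep(m$vertices, 2, ctr)
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
    m$vertices <- m$vertices - dirs * disp
    if (mesh_volume(m) <= 0)
      stop("minimum-distance displacement inverted the ", name, " surface")
  }
  if (mesh_volume(m) <= 0.05 * vol0)
    stop("minimum-distance displacement nearly collapsed the ", name, " surface")
  m
}

vertex_adjacency <- function(mesh) {
  F <- mesh$faces
  ed <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  split(ed[, 2], ed[, 1])
}
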