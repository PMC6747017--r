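#' Potential of a current dipole in an infinite homogeneous medium
#'
#' `v = q . (r - r0) / (4 pi sigma |r - r0|^3)`; the source term of the BEM
#' right-hand side.
#'
#' @param position dipole position (mm).
#' @param moment dipole moment (A*m).
#' @param points n x 3 observation points (mm).
#' @param sigma conductivity (S/m).
#' @return potentials (V).
#' @export
infinite_potential <- function(position, moment, points, sigma) {
  stopifnot(sigma > 0)
  P <- matrix(as.numeric(points), ncol = 3) * 1e-3
  r0 <- as.numeric(position) * 1e-3
  d <- sweep(P, 2, r0)
  r2 <- rowSums(d^2)
  if (any(r2 < 1e-24)) stop("observation point at the dipole position")
  as.numeric(d %*% as.numeric(moment)) / (4 * pi * sigma * r2^1.5)
}

#' Assemble the BEM system for a head model
#'
#' Vertex collocation with linear shape functions and analytically integrated
#' double-layer elements. The operator's free additive constant is removed by
#' rank-one deflation. The pieces required by the isolated problem approach
#' (IPA; isolation at the inner skull, the outer face of the low-conductivity
#' layer) are precomputed: the isolated sub-operator on inner skull + brain
#' and the inner-skull double-layer block.
#'
#' @param model a [head_model] whose surfaces satisfy the minimum-distance
#'   rule.
#' @param min_gap refuse assembly when surfaces are closer than this (mm).
#' @return object of class `bem_system`.
#' @export
bem_assemble <- function(model, min_gap = 0.5) {
  gaps <- check_nesting(model, dmin = min_gap)
  if (!all(gaps$nested))
    stop("head model surfaces are not nested")
  if (!all(gaps$distance_ok))
    stop("surfaces closer than ", min_gap, " mm (",
         paste(gaps$pair[!gaps$distance_ok], collapse = ", "),
         "); run enforce_min_distance() first")
  s <- model$surfaces
  nvert <- vapply(s, function(m) nrow(m$vertices), 1L)
  offset <- cumsum(c(0L, nvert))[1:4]
  V <- do.call(rbind, lapply(s, `[[`, "vertices")) * 1e-3 # SI
  F <- do.call(rbind, lapply(1:4, function(k) s[[k]]$faces - 1L + offset[k]))
  surf_of <- rep(1:4, nvert)
  sig <- model$conductivities
  # sigma inside / outside per surface (1 scalp .. 4 brain)
  sin_ <- c(sig[["scalp"]], sig[["skull"]], sig[["csf"]], sig[["brain"]])
  sout <- c(0, sig[["scalp"]], sig[["skull"]], sig[["csf"]])
  D <- cpp_bem_dmatrix(V, V, F)
  N <- nrow(D)
  idx <- split(seq_len(N), surf_of)
  omega_in <- numeric(N)
  for (k in 1:4)
    omega_in[idx[[k]]] <- rowSums(D[idx[[k]], idx[[k]], drop = FALSE])
  alpha <- sout[surf_of] + (sin_[surf_of] - sout[surf_of]) * omega_in / (4 * pi)
  jump <- (sin_ - sout)[surf_of]
  A <- -sweep(D, 2, jump / (4 * pi), `*`)
  diag(A) <- diag(A) + alpha
  # deflation: fix the free constant (zero-mean solutions)
  A <- A + mean(alpha) / N * matrix(1, N, N)
  # isolated problem on inner skull + brain (sigma outside inner skull -> 0)
  i34 <- c(idx[[3]], idx[[4]])
  sin0 <- c(NA, NA, sig[["csf"]], sig[["brain"]])
  sout0 <- c(NA, NA, 0, sig[["csf"]])
  surf34 <- surf_of[i34]
  alpha0 <- sout0[surf34] + (sin0[surf34] - sout0[surf34]) * omega_in[i34] / (4 * pi)
  jump0 <- (sin0 - sout0)[surf34]
  A0 <- -sweep(D[i34, i34, drop = FALSE], 2, jump0 / (4 * pi), `*`)
  diag(A0) <- diag(A0) + alpha0
  A0 <- A0 + mean(alpha0) / length(i34) * matrix(1, length(i34), length(i34))
  D3 <- D[, idx[[3]], drop = FALSE] # inner-skull double-layer block
  structure(list(A = A, A_iso = A0, D3 = D3,
                 omega_in = omega_in, alpha = alpha,
                 vertices = V, faces = F + 1L, surf_of = surf_of, idx = idx,
                 i34 = i34, nvert = nvert, offset = offset,
                 conductivities = sig, model = model),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("bem_system: %d boundary vertices (%s), deflated, IPA-ready\n",
              nrow(x$A), paste(x$nvert, collapse = "+")))
  invisible(x)
}

# right-hand side g = sigma * v_inf at all boundary vertices (SI obs) for a
# set of dipoles; cols are dipoles (moment folded in)
bem_rhs <- function(system, positions, moments) {
  pos <- matrix(as.numeric(positions), ncol = 3) * 1e-3
  mom <- matrix(as.numeric(moments), ncol = 3)
  G <- cpp_dipole_g(system$vertices, pos)
  nd <- nrow(pos)
  out <- matrix(0, nrow(G), nd)
  for (d in seq_len(nd))
    out[, d] <- G[, 3 * d - 2:0] %*% mom[d, ]
  out
}

# w-system right-hand side of the IPA from the isolated solution u0
ipa_rhs <- function(system, u0) {
  sk <- system$conductivities[["skull"]]
  n3 <- length(system$idx[[3]])
  u0m <- if (is.matrix(u0)) u0 else matrix(u0, ncol = 1)
  u3 <- u0m[seq_len(n3), , drop = FALSE]
  rhs <- -(sk / (4 * pi)) * (system$D3 %*% u3)
  i3 <- system$idx[[3]]
  rhs[i3, ] <- rhs[i3, , drop = FALSE] -
    sk * (1 - system$omega_in[i3] / (4 * pi)) * u3
  rhs
}

#' Solve the BEM forward problem for one or more dipoles
#'
#' With `use_ipa = TRUE` (default) the solution uses the isolated problem
#' approach: the sub-problem isolated at the inner skull (conductivity zero
#' outside) is solved first, and the full system is then solved for a
#' correction whose source terms are proportional to the small skull
#' conductivity, avoiding the numerical error amplification of the
#' sigma_skull / sigma_csf ~ 1/100 jump.
#'
#' @param system a [bem_system].
#' @param positions dipole positions, n x 3 (mm); must be strictly inside the
#'   brain surface.
#' @param moments dipole moments, n x 3 (A*m).
#' @param use_ipa logical.
#' @return matrix (boundary vertices x dipoles) of potentials (V), zero-mean
#'   over the collocation nodes (the deflation constant).
#' @export
bem_solve <- function(system, positions, moments, use_ipa = TRUE) {
  pos <- matrix(as.numeric(positions), ncol = 3)
  mom <- matrix(as.numeric(moments), ncol = 3)
  stopifnot(nrow(pos) == nrow(mom))
  brain <- system$model$surfaces$brain
  ins <- inside_mesh(pos, brain)
  if (!all(ins)) stop("dipole(s) outside the brain surface: ",
                      paste(which(!ins), collapse = ", "))
  d <- point_surface_distance(pos, brain)$distance
  if (any(d < 1))
    warning("dipole(s) within 1 mm of the brain surface: ",
            paste(which(d < 1), collapse = ", "))
  g <- bem_rhs(system, pos, mom)
  if (!use_ipa) {
    v <- solve(system$A, g)
    return(sweep(v, 2, colMeans(v)))
  }
  u0 <- solve(system$A_iso, g[system$i34, , drop = FALSE])
  w <- solve(system$A, ipa_rhs(system, u0))
  v <- w
  v[system$i34, ] <- v[system$i34, , drop = FALSE] + u0
  sweep(v, 2, colMeans(v)) # report zero-mean potentials
}

#' Cartesian source grid inside the brain surface
#'
#' Axis-aligned lattice at the given spacing (aligned to multiples of the
#' spacing), clipped to nodes strictly inside the brain surface. Nodes within
#' `margin` of the surface are kept but flagged near-boundary.
#'
#' @param brain closed [trimesh] of the brain surface.
#' @param spacing lattice spacing (mm), default 4.
#' @param margin near-boundary flag distance (mm), default = `spacing`.
#' @return object of class `source_grid`: `nodes` (n x 3 mm),
#'   `near_boundary`, `spacing`, `ijk` (integer lattice coordinates).
#' @export
build_source_grid <- function(brain, spacing = 4, margin = spacing) {
  stopifnot(spacing > 0)
  rng <- apply(brain$vertices, 2, range)
  ax <- lapply(1:3, function(k)
    seq(floor(rng[1, k] / spacing), ceiling(rng[2, k] / spacing)) * spacing)
  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(nodes) <- NULL
  ins <- inside_mesh(nodes, brain)
  nodes <- nodes[ins, , drop = FALSE]
  d <- point_surface_distance(nodes, brain)$distance
  keep <- d > 1e-9 # strictly inside (not on the surface)
  nodes <- nodes[keep, , drop = FALSE]
  d <- d[keep]
  structure(list(nodes = nodes, near_boundary = d < margin, spacing = spacing,
                 ijk = round(sweep(nodes, 2, spacing, `/`))),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("source_grid: %d nodes at %g mm spacing (%d near-boundary)\n",
              nrow(x$nodes), x$spacing, sum(x$near_boundary)))
  invisible(x)
}

# snap electrodes to the scalp surface; sparse interpolation matrix over all
# boundary vertices (barycentric weights on the containing scalp face)
electrode_interpolator <- function(system, electrodes, max_dist = 10) {
  scalp <- system$model$surfaces$scalp
  pts <- as.matrix(electrodes[, c("x", "y", "z")])
  pr <- point_surface_distance(pts, scalp)
  far <- pr$distance > max_dist
  if (any(far))
    stop("electrode(s) farther than ", max_dist, " mm from the scalp: ",
         paste(electrodes$label[far], collapse = ", "))
  E <- matrix(0, nrow(pts), nrow(system$A))
  for (e in seq_len(nrow(pts))) {
    f <- scalp$faces[pr$face[e], ]
    tri <- scalp$vertices[f, , drop = FALSE]
    wb <- barycentric_weights(pr$point[e, ], tri)
    E[e, system$offset[1] + f] <- wb
  }
  E
}

barycentric_weights <- function(p, tri) {
  v0 <- tri[2, ] - tri[1, ]
  v1 <- tri[3, ] - tri[1, ]
  v2 <- p - tri[1, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

#' Compute the lead field matrix
#'
#' Potentials at the electrodes for unit dipole moments along x, y, z at every
#' source-grid node, via per-electrode transfer rows (one transposed solve per
#' electrode against the BEM operator), so the cost is independent of the
#' number of sources beyond the source-term evaluation. Reference convention
#' of the result is `"raw"` (the deflated BEM potential; no electrode
#' subtracted).
#'
#' @param system a [bem_system].
#' @param grid a [source_grid].
#' @param electrodes data.frame with `label`, `x`, `y`, `z` (mm) on or near
#'   the scalp (or carved-ear) surface, optionally `group`.
#' @param use_ipa use the isolated problem approach (default TRUE).
#' @param chunk sources per block in the source-term evaluation.
#' @return object of class `leadfield`: `values` (electrodes x sources x 3,
#'   volts per A*m), `electrodes`, `grid`, `reference`.
#' @export
compute_leadfield <- function(system, grid, electrodes, use_ipa = TRUE,
                              chunk = 4000L) {
  E <- electrode_interpolator(system, electrodes)
  TT <- t(solve(t(system$A), t(E))) # n_elec x N transfer
  src <- grid$nodes * 1e-3
  ns <- nrow(src)
  ne <- nrow(E)
  if (use_ipa) {
    sk <- system$conductivities[["skull"]]
    i3 <- system$idx[[3]]
    n3 <- length(i3)
    n34 <- length(system$i34)
    K <- matrix(0, ne, n34)
    K[, seq_len(n3)] <- -(sk / (4 * pi)) * (TT %*% system$D3) -
      sk * sweep(TT[, i3, drop = FALSE], 2, 1 - system$omega_in[i3] / (4 * pi), `*`)
    Tiso <- t(solve(t(system$A_iso), t(K)))
    obs <- system$vertices[system$i34, , drop = FALSE]
    Tuse <- Tiso
  } else {
    obs <- system$vertices
    Tuse <- TT
  }
  vals <- matrix(0, ne, 3 * ns)
  for (st in seq(1, ns, by = chunk)) {
    en <- min(st + chunk - 1, ns)
    G <- cpp_dipole_g(obs, src[st:en, , drop = FALSE])
    vals[, (3 * st - 2):(3 * en)] <- Tuse %*% G
  }
  lf <- array(0, c(ne, ns, 3))
  lf[, , 1] <- vals[, seq(1, 3 * ns, 3)]
  lf[, , 2] <- vals[, seq(2, 3 * ns, 3)]
  lf[, , 3] <- vals[, seq(3, 3 * ns, 3)]
  structure(list(values = lf, electrodes = electrodes, grid = grid,
                 reference = "raw", use_ipa = use_ipa),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %d electrodes x %d sources x 3 (V per A*m), reference: %s\n",
              dim(x$values)[1], dim(x$values)[2], x$reference))
  invisible(x)
}

#' Re-reference a lead field matrix
#'
#' @param lfm a [leadfield].
#' @param mode `"average"` or the label of a common reference electrode.
#' @return the re-referenced [leadfield] (`reference` tag updated).
#' @export
rereference <- function(lfm, mode = "average") {
  v <- lfm$values
  if (identical(mode, "average")) {
    ref <- apply(v, c(2, 3), mean)
    for (e in seq_len(dim(v)[1])) v[e, , ] <- v[e, , ] - ref
    lfm$reference <- "average"
  } else {
    i <- match(mode, lfm$electrodes$label)
    if (is.na(i)) stop("unknown electrode label: ", mode)
    ref <- v[i, , ]
    for (e in seq_len(dim(v)[1])) v[e, , ] <- v[e, , ] - ref
    lfm$reference <- paste0("common:", mode)
  }
  lfm$values <- v
  lfm
}

# lead-field rows for one electrode label: sources x 3 matrix
leadfield_row <- function(lfm, label) {
  i <- match(label, lfm$electrodes$label)
  if (is.na(i)) stop("unknown electrode label: ", label)
  lfm$values[i, , ]
}

#' Shape and magnitude error between two potential vectors
#'
#' `RDM = || v1/||v1|| - v2/||v2|| ||` and `MAG = ||v1|| / ||v2||`, the
#' standard forward-solver accuracy metrics.
#'
#' @param v1 numeric vector (tested solution).
#' @param v2 numeric vector (reference solution).
#' @return named vector with `rdm` and `mag`.
#' @export
rdm_mag <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  c(rdm = sqrt(sum((v1 / n1 - v2 / n2)^2)), mag = n1 / n2)
}
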