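#' Concentric-sphere head specification
#'
#' @param radii ascending radii (mm) of brain, inner skull, outer skull and
#'   scalp surfaces. Defaults give plausible CSF/skull/scalp thicknesses.
#' @param conductivities named compartment conductivities (S/m).
#' @param faces approximate triangle count per shell.
#' @return object of class `sphere_spec`.
#' @export
sphere_spec <- function(radii = c(78, 80, 86, 92),
                        conductivities = c(scalp = 0.33, skull = 0.0132,
                                           csf = 1.79, brain = 0.33),
                        faces = 3000) {
  stopifnot(length(radii) == 4, all(diff(radii) > 0))
  if (any(diff(radii) < 1))
    stop("adjacent shell gaps must be at least 1 mm")
  structure(list(radii = as.numeric(radii), conductivities = conductivities,
                 faces = faces), class = "sphere_spec")
}

#' Four-shell concentric-sphere head model
#'
#' Nested icospheres at the radii of `spec`, each remeshed to about
#' `spec$faces` triangles.
#'
#' @param spec a [sphere_spec].
#' @return a [head_model].
#' @export
make_sphere_head <- function(spec = sphere_spec()) {
  mk <- function(r) {
    sub <- 1
    while (20 * 4^sub < spec$faces) sub <- sub + 1
    m <- icosphere(r, sub)
    if (nrow(m$faces) > 1.1 * spec$faces) m <- remesh(m, spec$faces)
    m
  }
  r <- spec$radii
  head_model(scalp = mk(r[4]), outer_skull = mk(r[3]), inner_skull = mk(r[2]),
             brain = mk(r[1]), conductivities = spec$conductivities,
             min_distance = 1)
}

#' Ear-carve and electrode-layout specification for the synthetic head
#'
#' The ear impression is a revolved profile: a concha bowl tapering into an
#' ear-canal cylinder along the +/-X axis. Not anatomically faithful, but it
#' reproduces the property ear-EEG exploits: a concave carve in which in-ear
#' electrodes span a volume.
#'
#' @param concha_radius,concha_depth bowl radius/depth (mm).
#' @param canal_radius,canal_depth canal radius and additional depth (mm).
#' @param n_inear in-ear electrodes per ear.
#' @param n_periauricular electrodes on a ring around each ear.
#' @param n_scalp scalp-cap electrodes.
#' @return object of class `ear_spec`.
#' @export
ear_spec <- function(concha_radius = 14, concha_depth = 6, canal_radius = 4.5,
                     canal_depth = 7, n_inear = 15, n_periauricular = 10,
                     n_scalp = 128) {
  stopifnot(n_inear >= 1, n_periauricular >= 0, n_scalp >= 1,
            concha_radius > canal_radius, concha_depth > 0, canal_depth >= 0)
  structure(list(concha_radius = concha_radius, concha_depth = concha_depth,
                 canal_radius = canal_radius, canal_depth = canal_depth,
                 n_inear = n_inear, n_periauricular = n_periauricular,
                 n_scalp = n_scalp), class = "ear_spec")
}

# parametric ear impression solid for side +1 (right, +X) or -1 (left)
ear_impression_solid <- function(sphere, ears, side) {
  R <- sphere$radii[4]
  lip <- 5 # sticks out of the scalp so the boolean is clean
  s <- c(-lip, 0, seq(0.15, 1, length.out = 8) * ears$concha_depth,
         ears$concha_depth + c(0.25, 0.6, 0.9, 1) * ears$canal_depth)
  taper <- function(t) ears$canal_radius +
    (ears$concha_radius - ears$canal_radius) * (cos(pi * t / 2))^1.5
  # blunt canal tip (flat cap): features stay above the carve voxel scale
  r <- c(ears$concha_radius, ears$concha_radius,
         taper(seq(0.15, 1, length.out = 8)),
         rep(ears$canal_radius, 3), 0.7 * ears$canal_radius)
  axis <- c(-side, 0, 0) # pointing into the head
  base <- c(side * R, 0, 0)
  revolve_solid(s, r, axis = axis, base = base, n_seg = 40)
}

#' Synthetic ear-augmented head with electrode layouts
#'
#' Carves a parametric concha-bowl + ear-canal solid into the scalp sphere on
#' both sides, enforces the 1 mm inter-surface rule, and lays out in-ear
#' electrodes on the carved surface (spanning a volume), a periauricular ring
#' around each carve, and a quasi-uniform scalp cap. Deterministic given
#' `seed`.
#'
#' @param sphere a [sphere_spec].
#' @param ears an [ear_spec].
#' @param seed integer seed controlling the (deterministic) layout phase.
#' @return list with `model` (a [head_model] whose scalp carries `"ear"` face
#'   labels) and `electrodes` (data.frame: `label`, `x`, `y`, `z`, `group`
#'   with groups `left-ear`, `right-ear`, `periauricular`, `scalp`).
#' @export
make_ear_head <- function(sphere = sphere_spec(), ears = ear_spec(), seed = 1) {
  depth_total <- ears$concha_depth + ears$canal_depth
  budget <- sphere$radii[4] - sphere$radii[1] # carve may dent skull and brain
  if (depth_total >= budget)
    stop(sprintf("carve depth %.1f mm exceeds the feasible budget %.1f mm",
                 depth_total, budget))
  base <- make_sphere_head(sphere)
  impL <- ear_impression_solid(sphere, ears, -1)
  impR <- ear_impression_solid(sphere, ears, +1)
  carved <- carve_ears(base$surfaces$scalp, list(impL, impR))
  model <- head_model(carved, base$surfaces$outer_skull,
                      base$surfaces$inner_skull, base$surfaces$brain,
                      conductivities = sphere$conductivities, check = FALSE)
  model <- enforce_min_distance(model, dmin = 1)
  elec <- layout_electrodes(model, sphere, ears, seed)
  list(model = model, electrodes = elec)
}

layout_electrodes <- function(model, sphere, ears, seed) {
  scalp <- model$surfaces$scalp
  R <- sphere$radii[4]
  snap <- function(pts) point_surface_distance(pts, scalp)$point

  inear_side <- function(side, prefix) {
    # parametric targets on the carve profile, snapped to the carved surface
    ax <- c(-side, 0, 0)
    base <- c(side * R, 0, 0)
    ring <- function(depth, rad, n, phase) {
      th <- phase + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      t(vapply(th, function(t)
        base + ax * depth + rad * (cos(t) * c(0, 1, 0) + sin(t) * c(0, 0, 1)),
        numeric(3)))
    }
    phase0 <- (seed %% 360) * pi / 180
    p <- rbind(
      ring(ears$concha_depth + 0.3 * ears$canal_depth, ears$canal_radius, 4, phase0),
      ring(ears$concha_depth + 0.75 * ears$canal_depth, ears$canal_radius, 4,
           phase0 + pi / 4),
      ring(0.55 * ears$concha_depth, 0.75 * ears$concha_radius, 6, phase0 + pi / 6),
      matrix(base + ax * (ears$concha_depth + ears$canal_depth), 1))
    p <- p[seq_len(min(nrow(p), ears$n_inear)), , drop = FALSE]
    data.frame(label = sprintf("%s%02d", prefix, seq_len(nrow(p))),
               snapped_df(snap(p)),
               group = paste0(if (side < 0) "left" else "right", "-ear"),
               stringsAsFactors = FALSE)
  }
  peri_side <- function(side, prefix) {
    n <- ears$n_periauricular %/% 2 + (side < 0) * (ears$n_periauricular %% 2)
    if (n == 0) return(NULL)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + (seed %% 7) / 7
    ang <- asin(pmin((ears$concha_radius + 8) / R, 1)) # angular ring radius
    p <- t(vapply(th, function(t) {
      dirv <- c(side * cos(ang), sin(ang) * cos(t), sin(ang) * sin(t))
      R * dirv
    }, numeric(3)))
    data.frame(label = sprintf("%s%02d", prefix, seq_len(n)),
               snapped_df(snap(p)), group = "periauricular",
               stringsAsFactors = FALSE)
  }
  # quasi-uniform cap: Fibonacci spiral on the upper sphere, away from the ears
  golden <- pi * (3 - sqrt(5))
  ncand <- ears$n_scalp * 3
  i <- seq_len(ncand)
  z <- 1 - (i - 0.5) / ncand * 1.35      # z/R from 1 down to about -0.35
  th <- golden * i + 2 * pi * ((seed * 1103515245 + 12345) %% 2048) / 2048
  cand <- cbind(sqrt(pmax(1 - z^2, 0)) * cos(th),
                sqrt(pmax(1 - z^2, 0)) * sin(th), z) * R
  keep <- sqrt(cand[, 2]^2 + cand[, 3]^2) >
    (ears$concha_radius + 12) | abs(cand[, 1]) < 0.7 * R
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), ears$n_scalp)), , drop = FALSE]
  scalp_df <- data.frame(label = sprintf("S%03d", seq_len(nrow(cand))),
                         snapped_df(snap(cand)), group = "scalp",
                         stringsAsFactors = FALSE)
  rbind(inear_side(-1, "EL"), inear_side(+1, "ER"),
        peri_side(-1, "PL"), peri_side(+1, "PR"), scalp_df)
}

snapped_df <- function(p) data.frame(x = p[, 1], y = p[, 2], z = p[, 3])

#' Analytic potential of a dipole in concentric conducting spheres
#'
#' Legendre-series solution for a current dipole inside the innermost shell
#' of a 4-layer isotropic concentric-sphere conductor (insulated outside),
#' evaluated at arbitrary points. The independent oracle for the BEM solver.
#'
#' @param position dipole position (mm).
#' @param moment dipole moment (A*m).
#' @param points n x 3 matrix of observation points (mm), anywhere in the
#'   conductor (typically scalp-surface points).
#' @param spec a [sphere_spec].
#' @param max_degree series truncation degree (>= 50 recommended).
#' @return potentials in volts.
#' @export
analytic_sphere_potential <- function(position, moment, points,
                                      spec = sphere_spec(), max_degree = 100) {
  R <- spec$radii * 1e-3 # SI
  sig <- unname(spec$conductivities[c("brain", "csf", "skull", "scalp")])
  r0 <- as.numeric(position) * 1e-3
  q <- as.numeric(moment)
  P <- matrix(as.numeric(points), ncol = 3) * 1e-3
  b <- sqrt(sum(r0^2))
  if (b >= R[1]) stop("dipole eccentricity >= 1 (outside the innermost shell)")
  r <- sqrt(rowSums(P^2))
  # tolerate slightly-off-surface mesh vertices (smooth continuation of the
  # outer-layer solution)
  if (any(r > R[4] * 1.01)) stop("observation points outside the scalp")
  layer <- findInterval(r * (1 - 1e-12), R) + 1 # 1..4
  layer[layer > 4] <- 4
  rhat0 <- if (b > 1e-12) r0 / b else c(0, 0, 1)
  qr_ <- sum(q * rhat0)
  xhat <- P / r
  cosg <- pmin(pmax(as.numeric(xhat %*% rhat0), -1), 1)
  tvec <- xhat - outer(cosg, rhat0) # |tvec| = sin(gamma)
  qt <- as.numeric(tvec %*% q)
  # Legendre recurrences
  Pn1 <- cosg # P_1
  Pn0 <- rep(1, length(cosg)) # P_0
  dPn <- rep(1, length(cosg)) # P_1'
  dPn0 <- rep(0, length(cosg)) # P_0'
  out <- numeric(nrow(P))
  for (n in seq_len(max_degree)) {
    coefs <- sphere_layer_coefs(n, R, sig, b)
    radial <- numeric(length(r))
    for (k in 1:4) {
      sel <- layer == k
      if (!any(sel)) next
      A <- coefs$A[k]
      B <- coefs$B[k]
      radial[sel] <- A * (r[sel] / R[k])^n + B * (R[k] / r[sel])^(n + 1)
      if (k == 1) {
        s_n <- src_coef(n, b, r[sel], sig[1])
        radial[sel] <- radial[sel] + s_n
      }
    }
    out <- out + radial * (n * qr_ * Pn1 + qt * dPn)
    # advance recurrences to degree n+1
    Pn2 <- ((2 * n + 1) * cosg * Pn1 - n * Pn0) / (n + 1)
    dPn2 <- ((2 * n + 1) * (Pn1 + cosg * dPn) - n * dPn0) / (n + 1) # P_{n+1}'
    Pn0 <- Pn1
    Pn1 <- Pn2
    dPn0 <- dPn
    dPn <- dPn2
  }
  out
}

# source radial coefficient  b^(n-1) / (4 pi sigma r^(n+1))  evaluated stably
src_coef <- function(n, b, r, sigma) {
  if (b < 1e-12) {
    if (n == 1) 1 / (4 * pi * sigma * r^2) else numeric(length(r)) * 0
  } else {
    exp((n - 1) * log(b / r)) / (4 * pi * sigma * r^2)
  }
}

# per-degree layer coefficients A_k, B_k (B_1 = 0) from the interface and
# outer-boundary conditions; all entries O(1) by the per-layer scaling.
sphere_layer_coefs <- function(n, R, sig, b) {
  # unknowns: A1, A2, B2, A3, B3, A4, B4
  M <- matrix(0, 7, 7)
  rhs <- numeric(7)
  iA <- c(1, 2, 4, 6)
  iB <- c(NA, 3, 5, 7)
  fval <- function(k, r) c((r / R[k])^n, if (!is.na(iB[k])) (R[k] / r)^(n + 1))
  fder <- function(k, r) c((n / r) * (r / R[k])^n,
                           if (!is.na(iB[k])) -((n + 1) / r) * (R[k] / r)^(n + 1))
  s_at <- function(r) src_coef(n, b, r, sig[1])
  row <- 1
  for (k in 1:3) {
    r <- R[k]
    # continuity of u
    M[row, iA[k]] <- fval(k, r)[1]
    if (!is.na(iB[k])) M[row, iB[k]] <- fval(k, r)[2]
    M[row, iA[k + 1]] <- -fval(k + 1, r)[1]
    M[row, iB[k + 1]] <- -fval(k + 1, r)[2]
    rhs[row] <- if (k == 1) -s_at(r) else 0
    row <- row + 1
    # continuity of sigma du/dr (times r)
    M[row, iA[k]] <- sig[k] * r * fder(k, r)[1]
    if (!is.na(iB[k])) M[row, iB[k]] <- sig[k] * r * fder(k, r)[2]
    M[row, iA[k + 1]] <- -sig[k + 1] * r * fder(k + 1, r)[1]
    M[row, iB[k + 1]] <- -sig[k + 1] * r * fder(k + 1, r)[2]
    rhs[row] <- if (k == 1) sig[1] * r * ((n + 1) / r) * s_at(r) else 0
    row <- row + 1
  }
  # insulated outer boundary
  M[row, iA[4]] <- n
  M[row, iB[4]] <- -(n + 1)
  sol <- solve(M, rhs)
  list(A = sol[iA], B = c(0, sol[iB[2:4]]))
}

#' Closed-form dipole potential on a homogeneous conducting sphere
#'
#' Exact surface potential of a current dipole inside a homogeneous sphere
#' with insulating exterior (the single-shell limit the multilayer series
#' must reproduce).
#'
#' @param position dipole position (mm).
#' @param moment dipole moment (A*m).
#' @param points n x 3 points on the sphere surface (mm).
#' @param radius sphere radius (mm).
#' @param sigma conductivity (S/m).
#' @return potentials in volts.
#' @export
homogeneous_sphere_potential <- function(position, moment, points, radius,
                                         sigma = 0.33) {
  R <- radius * 1e-3
  r0 <- as.numeric(position) * 1e-3
  q <- as.numeric(moment)
  P <- matrix(as.numeric(points), ncol = 3) * 1e-3
  b <- sqrt(sum(r0^2))
  if (b < 1e-12) {
    # pure n=1 limit
    return(3 * as.numeric(P %*% q) / (4 * pi * sigma * R^3))
  }
  x <- b / R
  rhat0 <- r0 / b
  xh <- P / sqrt(rowSums(P^2))
  cosg <- pmin(pmax(as.numeric(xh %*% rhat0), -1), 1)
  dt <- sqrt(pmax(1 - 2 * x * cosg + x^2, 1e-30)) # |r - r0| / R
  qr_ <- sum(q * rhat0)
  tvec <- xh - outer(cosg, rhat0)
  qt <- as.numeric(tvec %*% q)
  sin2 <- pmax(1 - cosg^2, 0)
  term_r <- 2 * x * (cosg - x) / dt^3 + 1 / dt - 1
  term_t <- 2 * x / dt^3 + ((x - cosg) / dt + cosg) / pmax(sin2, 1e-14)
  near_axis <- sin2 < 1e-12
  # qt -> 0 on the axis; keep the product finite
  term_t[near_axis] <- 0
  (qr_ * term_r + qt * term_t) / (4 * pi * sigma * b * R)
}
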