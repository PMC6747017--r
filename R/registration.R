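#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric 3-vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection); not a rigid transform")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform] objects.
#' @return the composed [rigid_transform].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Apply a rigid transform to points or a mesh
#' @param x an n x 3 matrix of points (mm), a 3-vector, or a [trimesh].
#' @param transform a [rigid_transform].
#' @return object of the same kind as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "trimesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  pts <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  out <- pts %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, `+`)
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Least-squares rigid fit between corresponding labeled point sets
#'
#' Closed-form solution of the orthogonal Procrustes problem via the SVD of
#' the cross-covariance (Kabsch / Umeyama without scaling): finds the proper
#' rotation and translation minimizing the sum of squared distances between
#' `transform(source)` and `target`. A reflection-only optimum is corrected to
#' the best proper rotation with a warning.
#'
#' @param source,target n x 3 matrices (n >= 3) or data.frames with
#'   `label`,`x`,`y`,`z`; when both carry labels, rows are matched by label.
#' @return list with `transform` ([rigid_transform]) and `rmse` (mm) over the
#'   fitted points.
#' @export
fit_rigid <- function(source, target) {
  if (is.data.frame(source)) source <- fiducial_matrix(source)
  if (is.data.frame(target)) target <- fiducial_matrix(target)
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (!is.null(rownames(source)) && !is.null(rownames(target))) {
    if (!setequal(rownames(source), rownames(target)))
      stop("source and target labels differ: ",
           paste(symdiff_chr(rownames(source), rownames(target)), collapse = ", "))
    target <- target[rownames(source), , drop = FALSE]
  }
  n <- nrow(source)
  if (n < 3 || nrow(target) != n)
    stop("need at least 3 corresponding point pairs")
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2, cs)
  T_ <- sweep(target, 2, ct)
  # collinearity check: second singular value of the centered source
  sv <- svd(S)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: source points are collinear")
  H <- crossprod(S, T_) # 3x3 cross-covariance
  dec <- svd(H)
  d <- det(dec$v %*% t(dec$u))
  if (d < 0)
    warning("optimal orthogonal map is a reflection; corrected to a proper rotation")
  D <- diag(c(1, 1, sign(d)))
  R <- dec$v %*% D %*% t(dec$u)
  t_ <- ct - as.numeric(R %*% cs)
  tr <- rigid_transform(R, t_)
  fitted <- apply_transform(source, tr)
  rmse <- sqrt(mean(rowSums((fitted - target)^2)))
  list(transform = tr, rmse = rmse)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Align digitizer coordinates to the head-model frame
#'
#' Rigid fit on the three anatomical landmarks (nasion, left and right
#' pre-auricular points) present in both sets. Mirror-image landmark sets
#' (e.g. swapped pre-auricular labels) are rejected: the optimal orthogonal
#' map would be a reflection.
#'
#' @param digitized_landmarks,mesh_landmarks data.frames (`label`,`x`,`y`,`z`)
#'   both containing labels `nasion`, `lpa`, `rpa` (case-insensitive).
#' @return a [rigid_transform] mapping digitizer coordinates into the
#'   head-model frame.
#' @export
align_head_coordinates <- function(digitized_landmarks, mesh_landmarks) {
  need <- c("nasion", "lpa", "rpa")
  pick <- function(df) {
    lab <- tolower(df$label)
    miss <- setdiff(need, lab)
    if (length(miss)) stop("missing landmark label(s): ", paste(miss, collapse = ", "))
    m <- fiducial_matrix(df)[match(need, lab), , drop = FALSE]
    rownames(m) <- need
    m
  }
  src <- pick(digitized_landmarks)
  tgt <- pick(mesh_landmarks)
  # a swapped left/right pair makes the two triangles mirror images: detect via
  # the reflection branch of the rigid fit and refuse.
  withCallingHandlers(
    fit_rigid(src, tgt)$transform,
    warning = function(w) {
      if (grepl("reflection", conditionMessage(w)))
        stop("landmark sets are mirror images (check left/right pre-auricular labels)")
    })
}

#' Register an earpiece (CAD frame) into the head frame
#'
#' Rigid fit of the five earpiece fiducial markers P1-P5 from the CAD frame to
#' their digitized positions in the head frame; the ear-impression mesh and
#' the CAD electrode positions are carried along by the fitted transform.
#'
#' @param impression_mesh [trimesh] of the scanned ear impression (CAD frame).
#' @param model_fiducials data.frame of P1-P5 in the CAD frame.
#' @param digitized_fiducials data.frame of the same labels in the head frame.
#' @param electrode_positions_cad optional data.frame of electrode positions
#'   in the CAD frame.
#' @return list with `mesh` (head frame), `electrodes` (head frame or NULL),
#'   `transform`, and `rmse` (mm) of the fiducial fit.
#' @export
place_earpiece <- function(impression_mesh, model_fiducials, digitized_fiducials,
                           electrode_positions_cad = NULL) {
  src <- fiducial_matrix(model_fiducials)
  if (nrow(src) < 5) stop("expected the five fiducial markers P1-P5")
  # non-coplanarity: smallest singular value of the centered set
  sv <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv[3] < 1) # mm; P1-P5 are chosen to span a volume
    warning(sprintf(paste0("earpiece fiducials are nearly coplanar (thickness ",
                           "%.2f mm): rotation about the plane normal is ",
                           "ill-constrained"), sv[3]))
  fit <- fit_rigid(model_fiducials, digitized_fiducials)
  elec <- NULL
  if (!is.null(electrode_positions_cad)) {
    elec <- electrode_positions_cad
    elec[, c("x", "y", "z")] <-
      apply_transform(fiducial_matrix(electrode_positions_cad), fit$transform)
  }
  list(mesh = apply_transform(impression_mesh, fit$transform),
       electrodes = elec, transform = fit$transform, rmse = fit$rmse)
}
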