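#' Component map (per-electrode coefficients of one component)
#'
#' The per-electrode projection weights `c_mn` of one independent component
#' (one column of the inverse mixing matrix), with electrode group labels
#' used for group-wise evaluation.
#'
#' @param values numeric vector of coefficients, one per electrode.
#' @param labels electrode labels.
#' @param groups electrode group per electrode (e.g. `left-ear`, `scalp`,
#'   `right-ear`).
#' @param component component index.
#' @return object of class `component_map`.
#' @export
component_map <- function(values, labels, groups = NULL, component = 1L) {
  stopifnot(length(values) == length(labels))
  if (any(!is.finite(values))) stop("component map has missing coefficients")
  if (is.null(groups)) groups <- rep("scalp", length(values))
  structure(list(values = as.numeric(values), labels = as.character(labels),
                 groups = as.character(groups), component = component),
            class = "component_map")
}

#' Restrict a component map to selected electrode groups
#' @param map a [component_map].
#' @param groups group labels to keep.
#' @return the restricted [component_map].
#' @export
restrict_map <- function(map, groups) {
  sel <- map$groups %in% groups
  component_map(map$values[sel], map$labels[sel], map$groups[sel], map$component)
}

#' Precompute the scan structures for dipole fitting on a lead field
#'
#' Per-node 3x3 Gram inverses of the (average-referenced) lead fields for an
#' electrode subset; reused across many [fit_dipole()] calls.
#'
#' @param lfm a [leadfield].
#' @param labels electrode labels to fit on (default: all in the LFM).
#' @return object of class `dipole_fitter`.
#' @export
dipole_fitter <- function(lfm, labels = lfm$electrodes$label) {
  rows <- match(labels, lfm$electrodes$label)
  if (anyNA(rows)) stop("labels not in the lead field: ",
                        paste(labels[is.na(rows)], collapse = ", "))
  L <- lfm$values[rows, , , drop = FALSE]
  ne <- length(rows)
  ns <- dim(L)[2]
  # average reference the lead fields over the used electrodes
  for (k in 1:3) L[, , k] <- sweep(L[, , k], 2, colMeans(L[, , k]))
  g11 <- colSums(L[, , 1] * L[, , 1]); g22 <- colSums(L[, , 2] * L[, , 2])
  g33 <- colSums(L[, , 3] * L[, , 3]); g12 <- colSums(L[, , 1] * L[, , 2])
  g13 <- colSums(L[, , 1] * L[, , 3]); g23 <- colSums(L[, , 2] * L[, , 3])
  det_ <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
    g13 * (g12 * g23 - g22 * g13)
  det_[abs(det_) < 1e-300] <- NA
  i11 <- (g22 * g33 - g23^2) / det_
  i22 <- (g11 * g33 - g13^2) / det_
  i33 <- (g11 * g22 - g12^2) / det_
  i12 <- -(g12 * g33 - g13 * g23) / det_
  i13 <- (g12 * g23 - g13 * g22) / det_
  i23 <- -(g11 * g23 - g12 * g13) / det_
  grid <- lfm$grid
  # dense lattice index for trilinear interpolation
  ijk <- grid$ijk
  lo <- apply(ijk, 2, min)
  dims <- apply(ijk, 2, max) - lo + 1L
  lat <- array(NA_integer_, dims)
  lat[cbind(ijk[, 1] - lo[1] + 1L, ijk[, 2] - lo[2] + 1L, ijk[, 3] - lo[3] + 1L)] <-
    seq_len(ns)
  structure(list(L = L, labels = labels, grid = grid,
                 gram_inv = cbind(i11, i22, i33, i12, i13, i23),
                 lattice = lat, lat_lo = lo), class = "dipole_fitter")
}

# best moment + residual at every node for map vector c (average-referenced)
scan_nodes <- function(fitter, cvec) {
  L <- fitter$L
  b1 <- as.numeric(crossprod(L[, , 1], cvec))
  b2 <- as.numeric(crossprod(L[, , 2], cvec))
  b3 <- as.numeric(crossprod(L[, , 3], cvec))
  gi <- fitter$gram_inv
  quad <- gi[, "i11"] * b1^2 + gi[, "i22"] * b2^2 + gi[, "i33"] * b3^2 +
    2 * (gi[, "i12"] * b1 * b2 + gi[, "i13"] * b1 * b3 + gi[, "i23"] * b2 * b3)
  ss <- sum(cvec^2)
  resid <- pmax(ss - quad, 0)
  list(resid = resid, ss = ss)
}

# trilinear-interpolated lead field (ne x 3) at an off-grid position;
# NULL when the enclosing cell is not fully inside the grid
interp_leadfield <- function(fitter, pos) {
  grid <- fitter$grid
  h <- grid$spacing
  f <- pos / h
  i0 <- floor(f)
  w <- f - i0
  idx <- matrix(0L, 8, 1)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  wts <- numeric(8)
  ids <- integer(8)
  for (k in 1:8) {
    c_ <- i0 + corners[k, ]
    li <- c_ - fitter$lat_lo + 1L
    if (any(li < 1) || any(li > dim(fitter$lattice))) return(NULL)
    id <- fitter$lattice[li[1], li[2], li[3]]
    if (is.na(id)) return(NULL)
    ids[k] <- id
    wts[k] <- prod(ifelse(corners[k, ] == 1, w, 1 - w))
  }
  G <- matrix(0, dim(fitter$L)[1], 3)
  for (k in 1:8)
    if (wts[k] > 0) G <- G + wts[k] * fitter$L[, ids[k], ]
  G
}

#' Fit a single equivalent current dipole to a component map
#'
#' Coarse scan over the source grid (the optimal moment at each node is a
#' linear least-squares problem) followed by derivative-free (Nelder-Mead)
#' refinement of the location with trilinearly interpolated lead fields.
#' The objective is the residual variance (RV, percent). Both the map and the
#' lead fields are average-referenced over the fitted electrodes, which makes
#' the objective independent of the recording reference.
#'
#' @param map a [component_map] (typically restricted to the scalp group) or a
#'   plain named numeric vector of coefficients.
#' @param lfm a [leadfield] or a precomputed [dipole_fitter].
#' @param refine run the local refinement (default TRUE).
#' @return object of class `dipole_fit`: `position` (mm), `moment` (map units
#'   per A*m scale), `rv` (percent), `on_hull` (TRUE when the optimum touches
#'   the grid hull), `fitted` (modeled coefficients on the fitted electrodes).
#' @export
fit_dipole <- function(map, lfm, refine = TRUE) {
  fitter <- if (inherits(lfm, "dipole_fitter")) lfm else dipole_fitter(lfm)
  if (inherits(map, "component_map")) {
    rows <- match(fitter$labels, map$labels)
    if (anyNA(rows)) stop("component map lacks electrodes: ",
                          paste(fitter$labels[is.na(rows)], collapse = ", "))
    cvec <- map$values[rows]
  } else {
    cvec <- as.numeric(map)
    if (length(cvec) != dim(fitter$L)[1])
      stop("map length does not match the fitter's electrode count")
  }
  if (length(cvec) < 8) stop("need at least 8 electrodes for a dipole fit")
  if (all(abs(cvec) < 1e-300)) stop("all-zero component map")
  cvec <- cvec - mean(cvec)
  sc <- scan_nodes(fitter, cvec)
  best <- which.min(sc$resid)
  grid <- fitter$grid
  pos <- grid$nodes[best, ]
  rvfun <- function(p) {
    G <- interp_leadfield(fitter, p)
    if (is.null(G)) return(1e9)
    qrG <- qr(G)
    res <- sum(qr.resid(qrG, cvec)^2)
    100 * res / sc$ss
  }
  on_hull <- is.null(interp_leadfield(fitter, pos)) || grid$near_boundary[best]
  if (refine) {
    opt <- stats::optim(pos, rvfun, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    if (opt$value <= 100 * sc$resid[best] / sc$ss + 1e-12 && opt$value < 1e8) {
      pos <- opt$par
    }
  }
  G <- interp_leadfield(fitter, pos)
  if (is.null(G)) { # refinement left the hull; fall back to the best node
    pos <- grid$nodes[best, ]
    G <- fitter$L[, best, ]
    on_hull <- TRUE
  }
  qrG <- qr(G)
  mom <- qr.coef(qrG, cvec)
  mom[is.na(mom)] <- 0
  fitted <- as.numeric(G %*% mom)
  rv <- 100 * sum((cvec - fitted)^2) / sc$ss
  structure(list(position = as.numeric(pos), moment = as.numeric(mom), rv = rv,
                 on_hull = on_hull, fitted = fitted, labels = fitter$labels),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("dipole_fit: position (%.1f, %.1f, %.1f) mm, RV %.2f%%%s\n",
              x$position[1], x$position[2], x$position[3], x$rv,
              if (x$on_hull) " [on grid hull]" else ""))
  invisible(x)
}

#' Quantize a location to the nearest source-grid node
#'
#' Euclidean nearest node; ties are broken by the lowest node index. Locations
#' outside the grid hull (distance beyond half a lattice diagonal) are flagged.
#'
#' @param location 3-vector (mm).
#' @param grid a [source_grid].
#' @return list with `node` (index), `distance` (mm) and `outside_hull`.
#' @export
quantize_source <- function(location, grid) {
  if (nrow(grid$nodes) == 0) stop("empty source grid")
  d2 <- colSums((t(grid$nodes) - as.numeric(location))^2)
  node <- which.min(d2) # which.min takes the first (lowest index) on ties
  d <- sqrt(d2[node])
  list(node = node, distance = d,
       outside_hull = d > sqrt(3) / 2 * grid$spacing + 1e-9)
}

#' Modeled component map from a source-grid node
#'
#' The forward projection `f_mn` of a dipole at a (typically quantized) grid
#' node to all lead-field electrodes, with the moment fitted by least squares
#' to the component map on a chosen electrode subset (the scalp group, in the
#' evaluation procedure).
#'
#' @param map a [component_map] covering the LFM electrodes.
#' @param lfm a [leadfield].
#' @param node source-grid node index.
#' @param fit_labels electrode labels used to fit the moment (default: the
#'   `scalp` group of the map).
#' @return a [component_map] of modeled coefficients `f_mn` (all electrodes).
#' @export
modeled_map <- function(map, lfm, node, fit_labels = NULL) {
  if (is.null(fit_labels)) fit_labels <- map$labels[map$groups == "scalp"]
  rows <- match(fit_labels, lfm$electrodes$label)
  cvec <- map$values[match(fit_labels, map$labels)]
  G <- lfm$values[rows, node, ]
  G <- sweep(G, 2, colMeans(G))
  mom <- qr.coef(qr(G), cvec - mean(cvec))
  mom[is.na(mom)] <- 0
  allrows <- match(map$labels, lfm$electrodes$label)
  if (anyNA(allrows)) stop("map electrodes missing from the lead field")
  f <- as.numeric(lfm$values[allrows, node, ] %*% mom)
  component_map(f, map$labels, map$groups, map$component)
}

#' Group-wise Pearson correlation between a component map and its model
#'
#' `C_m = cov(c_mn, f_mn) / sqrt(var(c_mn) var(f_mn))` computed separately
#' over each electrode group (left ear, scalp, right ear, ...).
#'
#' @param c_map,f_map [component_map]s on the same electrodes.
#' @return named numeric vector of correlations per group; `NA` (with a
#'   `reason` attribute) where a group has zero variance.
#' @export
correlation_by_group <- function(c_map, f_map) {
  stopifnot(identical(c_map$labels, f_map$labels))
  gr <- unique(c_map$groups)
  out <- stats::setNames(numeric(length(gr)), gr)
  reasons <- character(0)
  for (g in gr) {
    sel <- c_map$groups == g
    if (sum(sel) < 2) {
      out[g] <- NA
      reasons <- c(reasons, paste0(g, ": fewer than 2 electrodes"))
      next
    }
    cv <- c_map$values[sel]
    fv <- f_map$values[sel]
    if (var(cv) < 1e-300 || var(fv) < 1e-300) {
      out[g] <- NA
      reasons <- c(reasons, paste0(g, ": zero variance"))
      next
    }
    out[g] <- stats::cov(cv, fv) / sqrt(var(cv) * var(fv))
  }
  if (length(reasons)) attr(out, "reason") <- reasons
  out
}

#' Residual variance between a component map and its model
#'
#' `RV = 100 * var(c - f) / var(c)` (percent) over an electrode subset;
#' 100 percent means the model explains nothing beyond the mean.
#'
#' @param c_map,f_map [component_map]s on the same electrodes (or plain
#'   numeric vectors).
#' @param subset optional electrode labels or logical/integer selector.
#' @return RV in percent.
#' @export
residual_variance <- function(c_map, f_map, subset = NULL) {
  cv <- if (inherits(c_map, "component_map")) c_map$values else as.numeric(c_map)
  fv <- if (inherits(f_map, "component_map")) f_map$values else as.numeric(f_map)
  if (!is.null(subset)) {
    sel <- if (is.character(subset)) match(subset, c_map$labels) else subset
    cv <- cv[sel]
    fv <- fv[sel]
  }
  if (var(cv) < 1e-300) stop("zero variance in the component map subset")
  100 * var(cv - fv) / var(cv)
}

#' Percent variance accounted for by one component
#'
#' `PVAF_m = 100 - 100 * mean_n var(x_n(t) - y_mn(t)) / var(x_n(t))`, with
#' `y_mn(t) = (W^-1)_nm u_m(t)` the back-projection of component `m`.
#' Zero-variance (silent) channels are excluded with a warning.
#'
#' @param recording a [recording].
#' @param mixing a [mixing_model].
#' @param m component index.
#' @return PVAF in percent.
#' @export
pvaf <- function(recording, mixing, m) {
  x <- recording$data
  stopifnot(nrow(x) == nrow(mixing$inv_mixing),
            ncol(x) == ncol(mixing$timecourses))
  y <- outer(mixing$inv_mixing[, m], mixing$timecourses[m, ])
  vx <- apply(x, 1, var)
  keep <- vx > 1e-300
  if (!all(keep))
    warning(sum(!keep), " silent channel(s) excluded from PVAF")
  vr <- apply(x[keep, , drop = FALSE] - y[keep, , drop = FALSE], 1, var)
  100 - 100 * mean(vr / vx[keep])
}

#' Select the best-modeled in-brain components
#'
#' Filters fitted dipoles to those inside the brain volume, sorts by residual
#' variance (ascending) and keeps the first `k` (ties broken by component
#' index). "Inside the brain volume" uses the brain surface when supplied,
#' otherwise membership of the source-grid hull (within half a lattice
#' diagonal of a grid node).
#'
#' @param results data.frame with at least `component`, `rv`, `x`, `y`, `z`.
#' @param grid a [source_grid].
#' @param k number of components to keep (default 12, the evaluation's
#'   predefined criterion).
#' @param brain optional closed brain [trimesh] for a strict inside test.
#' @return the selected rows of `results` (possibly fewer than `k`).
#' @export
select_components <- function(results, grid, k = 12, brain = NULL) {
  pos <- as.matrix(results[, c("x", "y", "z")])
  inb <- if (!is.null(brain)) {
    inside_mesh(pos, brain)
  } else {
    vapply(seq_len(nrow(pos)), function(i)
      !quantize_source(pos[i, ], grid)$outside_hull, TRUE)
  }
  if (!any(inb)) {
    warning("no fitted dipoles inside the brain volume")
    return(results[integer(0), , drop = FALSE])
  }
  sel <- results[inb, , drop = FALSE]
  sel <- sel[order(sel$rv, sel$component), , drop = FALSE]
  utils::head(sel, k)
}

#' Evaluate component maps against the forward model
#'
#' The full evaluation pipeline for a set of component maps: scalp-only single
#' dipole fit, quantization to the source grid, modeled map from the quantized
#' node, residual variance, group-wise correlations and (when a recording and
#' mixing model are given) PVAF.
#'
#' @param maps list of [component_map]s (all electrodes, grouped).
#' @param lfm a [leadfield] covering the maps' electrodes.
#' @param recording,mixing optional [recording] and [mixing_model] for PVAF.
#' @return data.frame with one row per component: `component`, `rv`, `pvaf`,
#'   `C_left_ear`, `C_scalp`, `C_right_ear`, `x`, `y`, `z`, `quant_node`,
#'   `quant_distance`, `on_hull`.
#' @export
evaluate_components <- function(maps, lfm, recording = NULL, mixing = NULL) {
  scalp_labels <- maps[[1]]$labels[maps[[1]]$groups == "scalp"]
  fitter <- dipole_fitter(lfm, scalp_labels)
  rows <- lapply(maps, function(map) {
    fit <- fit_dipole(restrict_map(map, "scalp"), fitter)
    qz <- quantize_source(fit$position, lfm$grid)
    fmap <- modeled_map(map, lfm, qz$node)
    cg <- correlation_by_group(map, fmap)
    data.frame(component = map$component,
               rv = fit$rv,
               pvaf = if (!is.null(recording) && !is.null(mixing))
                 pvaf(recording, mixing, map$component) else NA_real_,
               C_left_ear = group_val(cg, "left-ear"),
               C_scalp = group_val(cg, "scalp"),
               C_right_ear = group_val(cg, "right-ear"),
               x = fit$position[1], y = fit$position[2], z = fit$position[3],
               quant_node = qz$node, quant_distance = qz$distance,
               on_hull = fit$on_hull)
  })
  do.call(rbind, rows)
}

group_val <- function(v, nm) if (nm %in% names(v)) unname(v[nm]) else NA_real_
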