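#' Lead field sensitivity of an electrode pair
#'
#' Per source node, the sensitivity vector `s` is the lead-field row of
#' electrode A minus that of electrode B (a 3-vector, V per A*m). By the
#' reciprocity theorem its direction is the dipole orientation producing the
#' largest potential difference between the two electrodes, and `|s|` is that
#' maximal sensitivity.
#'
#' @param lfm a [leadfield].
#' @param elec_a,elec_b electrode labels.
#' @return object of class `sensitivity_map`: `s` (n x 3), `magnitude`,
#'   `orientation` (unit rows; NA where `|s| = 0`, flagged in `zero`), `grid`,
#'   `config`.
#' @export
pair_sensitivity <- function(lfm, elec_a, elec_b) {
  s <- leadfield_row(lfm, elec_a) - leadfield_row(lfm, elec_b)
  new_sensitivity_map(s, lfm$grid, config = paste0(elec_a, "-", elec_b),
                      electrodes = electrode_positions(lfm, c(elec_a, elec_b)))
}

#' Lead field sensitivity of a single electrode against infinity
#'
#' The raw (unreferenced, deflated) BEM potential row of one electrode; a
#' physical reference electrode would subtract a row, which this configuration
#' deliberately excludes, so the LFM must still carry the `"raw"` reference.
#'
#' @param lfm a [leadfield] with reference `"raw"`.
#' @param elec electrode label.
#' @return a `sensitivity_map`.
#' @export
single_sensitivity <- function(lfm, elec) {
  if (!identical(lfm$reference, "raw"))
    stop("LFM is re-referenced ('", lfm$reference,
         "'): the infinite reference is unrecoverable")
  new_sensitivity_map(leadfield_row(lfm, elec), lfm$grid,
                      config = paste0(elec, "-infinity"),
                      electrodes = electrode_positions(lfm, elec))
}

electrode_positions <- function(lfm, labels) {
  as.matrix(lfm$electrodes[match(labels, lfm$electrodes$label),
                           c("x", "y", "z"), drop = FALSE])
}

new_sensitivity_map <- function(s, grid, config, electrodes) {
  mag <- sqrt(rowSums(s^2))
  ori <- s / ifelse(mag > 0, mag, NA)
  structure(list(s = s, magnitude = mag, orientation = ori,
                 zero = mag == 0, grid = grid, config = config,
                 electrodes = electrodes, db = NULL, db_reference = NULL),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("sensitivity_map [%s]: %d nodes, |s| in [%.3g, %.3g] V/(A*m)%s\n",
              x$config, length(x$magnitude), min(x$magnitude), max(x$magnitude),
              if (!is.null(x$db)) sprintf(", dB re %.3g", x$db_reference) else ""))
  invisible(x)
}

#' Convert a sensitivity map to decibels
#'
#' `dB = 20 log10(|s| / reference)`; zero-magnitude nodes map to `-Inf`.
#'
#' @param map a `sensitivity_map`.
#' @param reference `"max"` (default; the map maximum becomes 0 dB) or a
#'   positive value in V per A*m.
#' @return the map with `db` and `db_reference` filled in.
#' @export
to_db <- function(map, reference = "max") {
  ref <- if (identical(reference, "max")) max(map$magnitude) else as.numeric(reference)
  if (!is.finite(ref) || ref <= 0) stop("dB reference must be positive")
  map$db <- ifelse(map$magnitude > 0, 20 * log10(map$magnitude / ref), -Inf)
  map$db_reference <- ref
  map
}

#' Compare the sensitivity of two electrode configurations
#'
#' Per-node sensitivity-magnitude ratio in dB between two electrode pairs
#' (e.g. a between-ears pair vs a within-ear pair), with summary quantiles and
#' the decay slope of each configuration's sensitivity (dB) against
#' log10-distance from its electrode centroid.
#'
#' @param lfm a [leadfield].
#' @param pair_a,pair_b character vectors `c(elecA1, elecA2)`; a single label
#'   is treated as electrode-vs-infinity.
#' @param grid optional [source_grid] (default: the LFM's grid).
#' @return list with `db_difference` (per node; NA where either magnitude is
#'   zero), `median`, `quartiles`, `n_excluded`, `slope_a`, `slope_b`
#'   (dB per decade of distance) and the two `sensitivity_map`s.
#' @export
compare_configurations <- function(lfm, pair_a, pair_b, grid = lfm$grid) {
  mk <- function(p) {
    if (length(p) == 2) pair_sensitivity(lfm, p[1], p[2])
    else single_sensitivity(lfm, p)
  }
  sa <- mk(pair_a)
  sb <- mk(pair_b)
  ok <- sa$magnitude > 0 & sb$magnitude > 0
  dd <- rep(NA_real_, length(ok))
  dd[ok] <- 20 * log10(sa$magnitude[ok] / sb$magnitude[ok])
  slope <- function(sm) {
    cen <- colMeans(sm$electrodes)
    d <- sqrt(colSums((t(grid$nodes) - cen)^2))
    sel <- sm$magnitude > 0 & d > 1e-6
    stats::coef(stats::lm(20 * log10(sm$magnitude[sel]) ~ log10(d[sel])))[2]
  }
  list(db_difference = dd,
       median = median(dd, na.rm = TRUE),
       quartiles = quantile(dd, c(0.25, 0.75), na.rm = TRUE, names = FALSE),
       n_excluded = sum(!ok),
       slope_a = unname(slope(sa)), slope_b = unname(slope(sb)),
       map_a = sa, map_b = sb)
}

#' Export a sensitivity map as a node table
#'
#' Tab-separated text: `x y z |s| sx sy sz dB` per source node.
#'
#' @param map a `sensitivity_map` (run [to_db()] first to fill the dB column).
#' @param path output file.
#' @export
write_sensitivity <- function(map, path) {
  db <- if (is.null(map$db)) rep(NA_real_, length(map$magnitude)) else map$db
  tab <- data.frame(x = map$grid$nodes[, 1], y = map$grid$nodes[, 2],
                    z = map$grid$nodes[, 3], s = map$magnitude,
                    sx = map$orientation[, 1], sy = map$orientation[, 2],
                    sz = map$orientation[, 3], db = db)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a slice of a sensitivity map
#'
#' Simple base-graphics image of the dB (or magnitude) values on the lattice
#' slice nearest `z`.
#'
#' @param x a `sensitivity_map`.
#' @param z slice height (mm); default the electrode centroid height.
#' @param ... ignored.
#' @export
plot.sensitivity_map <- function(x, z = NULL, ...) {
  val <- if (!is.null(x$db)) x$db else 20 * log10(pmax(x$magnitude, 1e-300))
  nodes <- x$grid$nodes
  if (is.null(z)) z <- mean(x$electrodes[, 3])
  zs <- sort(unique(nodes[, 3]))
  z0 <- zs[which.min(abs(zs - z))]
  sel <- nodes[, 3] == z0
  xs <- sort(unique(nodes[sel, 1]))
  ys <- sort(unique(nodes[sel, 2]))
  img <- matrix(NA_real_, length(xs), length(ys))
  img[cbind(match(nodes[sel, 1], xs), match(nodes[sel, 2], ys))] <- val[sel]
  graphics::image(xs, ys, img, xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s, z = %g mm (dB)", x$config, z0),
                  useRaster = TRUE)
  invisible(x)
}
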