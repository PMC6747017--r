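#' Write a lead field matrix to a binary container with a text sidecar
#'
#' The values (electrodes x sources x 3, V per A*m) are stored as little-
#' endian doubles in `<path>.bin`; `<path>.txt` holds the dimensions,
#' electrode labels/positions/groups, grid spacing, reference tag and units.
#'
#' @param lfm a [leadfield].
#' @param path basename (without extension).
#' @return invisibly, `path`.
#' @export
write_leadfield <- function(lfm, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(lfm$values), con, size = 8L, endian = "little")
  close(con)
  d <- dim(lfm$values)
  el <- lfm$electrodes
  side <- c(sprintf("dims %d %d %d", d[1], d[2], d[3]),
            sprintf("spacing_mm %g", lfm$grid$spacing),
            sprintf("reference %s", lfm$reference),
            "units V_per_Am",
            sprintf("electrode %s %.9g %.9g %.9g %s", el$label, el$x, el$y,
                    el$z, if (!is.null(el$group)) el$group else "scalp"),
            sprintf("node %.9g %.9g %.9g %d", lfm$grid$nodes[, 1],
                    lfm$grid$nodes[, 2], lfm$grid$nodes[, 3],
                    as.integer(lfm$grid$near_boundary)))
  writeLines(side, paste0(path, ".txt"))
  invisible(path)
}

#' Read a lead field matrix written by [write_leadfield()]
#' @param path basename (without extension).
#' @return a [leadfield].
#' @export
read_leadfield <- function(path) {
  side <- readLines(paste0(path, ".txt"))
  fields <- strsplit(side, "\\s+")
  key <- vapply(fields, `[`, "", 1L)
  d <- as.integer(fields[[which(key == "dims")[1]]][2:4])
  spacing <- as.numeric(fields[[which(key == "spacing_mm")[1]]][2])
  reference <- fields[[which(key == "reference")[1]]][2]
  els <- fields[key == "electrode"]
  electrodes <- data.frame(label = vapply(els, `[`, "", 2L),
                           x = as.numeric(vapply(els, `[`, "", 3L)),
                           y = as.numeric(vapply(els, `[`, "", 4L)),
                           z = as.numeric(vapply(els, `[`, "", 5L)),
                           group = vapply(els, `[`, "", 6L),
                           stringsAsFactors = FALSE)
  nds <- fields[key == "node"]
  nodes <- cbind(as.numeric(vapply(nds, `[`, "", 2L)),
                 as.numeric(vapply(nds, `[`, "", 3L)),
                 as.numeric(vapply(nds, `[`, "", 4L)))
  near <- as.logical(as.integer(vapply(nds, `[`, "", 5L)))
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
  close(con)
  grid <- structure(list(nodes = nodes, near_boundary = near,
                         spacing = spacing,
                         ijk = round(sweep(nodes, 2, spacing, `/`))),
                    class = "source_grid")
  structure(list(values = array(vals, d), electrodes = electrodes,
                 grid = grid, reference = reference),
            class = "leadfield")
}

#' Write a component evaluation table
#'
#' Tab-separated per-component results (component, RV, PVAF, group
#' correlations, fitted location, quantization distance) as produced by
#' [evaluate_components()].
#'
#' @param results data.frame from [evaluate_components()].
#' @param path output file.
#' @export
write_eval_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
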