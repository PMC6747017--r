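#' Multichannel recording container
#'
#' @param data channels x samples matrix (V).
#' @param rate sampling rate (Hz).
#' @param labels channel labels (length = rows of `data`).
#' @param triggers integer sample indices of trigger events (increasing).
#' @return object of class `recording`.
#' @export
recording <- function(data, rate, labels, triggers = integer(0)) {
  data <- as.matrix(data)
  stopifnot(rate > 0, length(labels) == nrow(data))
  if (length(triggers) && any(diff(triggers) <= 0))
    stop("trigger indices must be strictly increasing")
  structure(list(data = data, rate = rate, labels = as.character(labels),
                 triggers = as.integer(triggers)), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz (%d triggers)\n",
              nrow(x$data), ncol(x$data), x$rate, length(x$triggers)))
  invisible(x)
}

#' Ground-truth mixing model
#'
#' Inverse mixing matrix (electrodes x components; column m is the component
#' map of component m) and component timecourses, as produced by an external
#' ICA or by [simulate_sources()]. Back-projections are
#' `y_mn(t) = (W^-1)_nm * u_m(t)`.
#'
#' @param inv_mixing electrodes x components matrix.
#' @param timecourses components x samples matrix.
#' @param labels electrode labels.
#' @return object of class `mixing_model`.
#' @export
mixing_model <- function(inv_mixing, timecourses, labels = NULL) {
  inv_mixing <- as.matrix(inv_mixing)
  timecourses <- as.matrix(timecourses)
  stopifnot(ncol(inv_mixing) == nrow(timecourses))
  structure(list(inv_mixing = inv_mixing, timecourses = timecourses,
                 labels = labels), class = "mixing_model")
}

#' Simulate a multichannel recording from grid sources
#'
#' Projects dipole sources at source-grid nodes through a lead field and adds
#' white sensor noise: `x_n(t) = sum_m f_mn u_m(t) + noise`. The ground-truth
#' inverse mixing matrix has the lead-field projections `f_m` as columns.
#'
#' @param lfm a [leadfield].
#' @param sources list of source specs: each a list with `node` (grid node
#'   index), `moment` (3-vector, A*m; default a random unit moment times
#'   1e-8), and either `freq` (Hz; sinusoidal timecourse with seeded random
#'   phase) or `timecourse` (numeric vector, length = samples).
#' @param noise_sd sensor noise standard deviation (V).
#' @param duration seconds.
#' @param rate sampling rate (Hz).
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @return list with `recording` (a [recording]) and `mixing` (a
#'   [mixing_model] of the ground truth).
#' @export
simulate_sources <- function(lfm, sources, noise_sd = 0, duration = 2,
                             rate = 500, seed = 1) {
  stopifnot(duration > 0, rate > 0)
  nt <- round(duration * rate)
  tt <- seq_len(nt) / rate
  ne <- dim(lfm$values)[1]
  set.seed(seed)
  W <- matrix(0, ne, length(sources))
  U <- matrix(0, length(sources), nt)
  for (m in seq_along(sources)) {
    s <- sources[[m]]
    if (is.null(s$node)) stop("source ", m, " lacks a grid node index")
    if (s$node < 1 || s$node > dim(lfm$values)[2])
      stop("source node out of range")
    mom <- s$moment
    if (is.null(mom)) {
      mom <- rnorm(3)
      mom <- mom / sqrt(sum(mom^2)) * 1e-8
    }
    W[, m] <- lfm$values[, s$node, ] %*% mom
    U[m, ] <- if (!is.null(s$timecourse)) {
      stopifnot(length(s$timecourse) == nt)
      s$timecourse
    } else {
      amp <- if (is.null(s$amp)) 1 else s$amp
      amp * sin(2 * pi * (s$freq %||0% 10) * tt + runif(1, 0, 2 * pi))
    }
  }
  x <- W %*% U
  if (noise_sd > 0) x <- x + matrix(rnorm(ne * nt, sd = noise_sd), ne, nt)
  list(recording = recording(x, rate, lfm$electrodes$label),
       mixing = mixing_model(W, U, lfm$electrodes$label))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a
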