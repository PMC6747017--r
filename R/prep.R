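#' Trigger track of an amplifier
#'
#' @param indices strictly increasing sample indices of trigger events.
#' @param rate nominal sampling rate (Hz).
#' @return object of class `trigger_track`.
#' @export
trigger_track <- function(indices, rate) {
  indices <- as.integer(indices)
  if (length(indices) < 2) stop("need at least 2 trigger events")
  if (any(diff(indices) <= 0)) stop("trigger indices must be strictly increasing")
  structure(list(indices = indices, rate = rate), class = "trigger_track")
}

#' True sampling-rate ratio between two amplifiers
#'
#' Both amplifiers record the same trigger events, so the ratio of their true
#' sampling rates equals the ratio of the sample counts between the first and
#' last trigger.
#'
#' @param a,b [trigger_track]s (or [recording]s carrying triggers) with the
#'   same number of events.
#' @return `rate_a / rate_b` (true rates).
#' @export
estimate_rate_ratio <- function(a, b) {
  ia <- track_indices(a)
  ib <- track_indices(b)
  if (length(ia) < 2 || length(ib) < 2) stop("need at least 2 trigger events")
  if (length(ia) != length(ib))
    stop("trigger event counts differ (", length(ia), " vs ", length(ib), ")")
  (ia[length(ia)] - ia[1]) / (ib[length(ib)] - ib[1])
}

track_indices <- function(x) {
  if (inherits(x, "trigger_track")) x$indices
  else if (inherits(x, "recording")) x$triggers
  else as.integer(x)
}

# FFT-based resampling of one signal to n_new samples (band-limited sinc
# interpolation; acts as the anti-alias filter for downsampling)
resample_fft <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- fft(x)
  Y <- complex(real = numeric(n_new), imaginary = numeric(n_new))
  N <- min(n, n_new)
  if (N %% 2 == 1) {
    hp <- (N + 1) %/% 2 # DC + positive bins
    Y[seq_len(hp)] <- X[seq_len(hp)]
    if (hp > 1)
      Y[n_new - seq_len(hp - 1) + 1] <- X[n - seq_len(hp - 1) + 1]
  } else {
    h <- N %/% 2
    Y[seq_len(h)] <- X[seq_len(h)]
    if (h > 1)
      Y[n_new - seq_len(h - 1) + 1] <- X[n - seq_len(h - 1) + 1]
    if (n_new < n) { # fold both +/- Nyquist-frequency bins of the input
      Y[h + 1] <- X[h + 1] + X[n - h + 1]
    } else {         # split the input Nyquist bin
      Y[h + 1] <- X[h + 1] / 2
      Y[n_new - h + 1] <- Conj(X[h + 1] / 2)
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Merge multi-amplifier recordings onto a common clock and reference
#'
#' Corrects each amplifier's sampling-rate drift from the shared trigger
#' events, resamples everything to `target_rate` (FFT band-limited
#' resampling), aligns the first triggers to within one sample, re-references
#' every amplifier's channels to its `ref_label` channel, and stacks the
#' channels into one joint recording.
#'
#' @param recs list of [recording]s, each carrying the shared triggers.
#' @param target_rate common output rate (Hz), default 500.
#' @param ref_label common reference channel present in every recording
#'   (default `"FPz"`).
#' @return a joint [recording] (reference channels are all-zero rows).
#' @export
merge_recordings <- function(recs, target_rate = 500, ref_label = "FPz") {
  stopifnot(length(recs) >= 1)
  for (r in recs)
    if (!ref_label %in% r$labels)
      stop("recording lacks the reference channel ", ref_label)
  if (any(vapply(recs, function(r) length(r$triggers), 1L) < 2) &&
      length(recs) > 1)
    stop("recordings must share at least 2 trigger events for alignment")
  ref <- recs[[1]]
  span_target <- if (length(ref$triggers) >= 2) {
    (ref$triggers[length(ref$triggers)] - ref$triggers[1]) /
      ref$rate * target_rate
  } else NA
  pieces <- lapply(recs, function(r) {
    n <- ncol(r$data)
    f <- if (length(r$triggers) >= 2 && !is.na(span_target)) {
      span_target / (r$triggers[length(r$triggers)] - r$triggers[1])
    } else target_rate / r$rate
    n_new <- max(2L, round(n * f))
    d <- t(apply(r$data, 1, resample_fft, n_new = n_new))
    trig <- if (length(r$triggers)) pmax(1L, round((r$triggers - 1) * f) + 1L)
            else integer(0)
    first <- if (length(trig)) trig[1] else 1L
    list(data = d, trig = trig, first = first, labels = r$labels)
  })
  # align first triggers: crop every piece to start there
  aligned <- lapply(pieces, function(p) {
    sel <- p$first:ncol(p$data)
    list(data = p$data[, sel, drop = FALSE],
         trig = p$trig - p$first + 1L, labels = p$labels)
  })
  len <- min(vapply(aligned, function(p) ncol(p$data), 1L))
  out <- do.call(rbind, lapply(aligned, function(p) {
    d <- p$data[, seq_len(len), drop = FALSE]
    sweep(d, 2, d[match(ref_label, p$labels), ]) # re-reference
  }))
  labels <- unlist(lapply(seq_along(aligned), function(i) {
    l <- aligned[[i]]$labels
    if (i > 1) l[l == ref_label] <- paste0(ref_label, ".", i)
    l
  }))
  recording(out, target_rate, labels,
            triggers = aligned[[1]]$trig[aligned[[1]]$trig <= len])
}

#' Concatenate recordings in time (cascaded stimulus segments)
#'
#' @param recs list of [recording]s with identical labels and rate.
#' @return one [recording]; trigger indices are offset per segment.
#' @export
concat_recordings <- function(recs) {
  stopifnot(length(recs) >= 1)
  lab <- recs[[1]]$labels
  rate <- recs[[1]]$rate
  for (r in recs)
    if (!identical(r$labels, lab) || r$rate != rate)
      stop("recordings must share labels and rate to be cascaded")
  offs <- cumsum(c(0L, vapply(recs, function(r) ncol(r$data), 1L)))
  trig <- unlist(lapply(seq_along(recs), function(i) recs[[i]]$triggers + offs[i]))
  recording(do.call(cbind, lapply(recs, `[[`, "data")), rate, lab,
            triggers = as.integer(trig))
}

# --- zero-phase IIR filtering (biquad cascades, RBJ designs) ----------------

biquad_highpass <- function(fc, rate, Q) {
  w0 <- 2 * pi * fc / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c((1 + cos(w0)) / 2, -(1 + cos(w0)), (1 + cos(w0)) / 2)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

biquad_notch <- function(f0, rate, Q) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_biquad <- function(x, bq) {
  n <- length(x)
  xb <- bq$b[1] * x + bq$b[2] * c(0, x[-n]) + bq$b[3] * c(0, 0, x[-c(n - 1, n)])
  as.numeric(stats::filter(xb, -bq$a[2:3], method = "recursive"))
}

filtfilt_biquad <- function(x, bq) {
  n <- length(x)
  pad <- min(max(30L, 12L), n - 1)
  # odd reflection padding
  xp <- c(2 * x[1] - x[pad:2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- apply_biquad(xp, bq)
  y <- rev(apply_biquad(rev(y), bq))
  y[pad + seq_len(n)]
}

#' Standard filtering chain for joint data-sets
#'
#' Average reference, zero-phase high-pass (cascaded biquads, Butterworth
#' alignment) at `hp_cutoff`, and zero-phase 4th-order notch filters at the
#' power-line harmonics. Notch frequencies above Nyquist are dropped with a
#' warning.
#'
#' @param rec a [recording].
#' @param hp_cutoff high-pass cutoff (Hz), default 1.
#' @param notches notch center frequencies (Hz), default 50/100/150/200.
#' @param notch_bw notch bandwidth (Hz) per second-order section.
#' @return the filtered [recording].
#' @export
filter_chain <- function(rec, hp_cutoff = 1, notches = c(50, 100, 150, 200),
                         notch_bw = 2) {
  x <- rec$data
  x <- sweep(x, 2, colMeans(x)) # average reference (across channels)
  nyq <- rec$rate / 2
  drop <- notches >= nyq * 0.99
  if (any(drop)) {
    warning("notch frequencies at/above Nyquist dropped: ",
            paste(notches[drop], collapse = ", "))
    notches <- notches[!drop]
  }
  # 4th-order Butterworth high-pass: two biquads with Q = 0.5412, 1.3066
  hps <- list(biquad_highpass(hp_cutoff, rec$rate, 1 / (2 * cos(pi / 8))),
              biquad_highpass(hp_cutoff, rec$rate, 1 / (2 * cos(3 * pi / 8))))
  bqs <- c(hps, unlist(lapply(notches, function(f0)
    list(biquad_notch(f0, rec$rate, f0 / notch_bw),
         biquad_notch(f0, rec$rate, f0 / notch_bw))), recursive = FALSE))
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    for (bq in bqs) v <- filtfilt_biquad(v, bq)
    x[ch, ] <- v
  }
  out <- rec
  out$data <- x
  out
}

#' Flag saturated channels
#'
#' A channel is flagged when it dwells within 1 percent of either rail for at
#' least `dwell` consecutive samples.
#'
#' @param rec a [recording].
#' @param rail amplifier rail (V), > 0.
#' @param dwell consecutive-sample threshold.
#' @return data.frame `label`, `keep`, `reason` (a `ChannelMask`).
#' @export
drop_saturated <- function(rec, rail, dwell = 10) {
  stopifnot(rail > 0)
  sat <- vapply(seq_len(nrow(rec$data)), function(ch) {
    at_rail <- abs(rec$data[ch, ]) >= 0.99 * rail
    if (!any(at_rail)) return(FALSE)
    r <- rle(at_rail)
    any(r$lengths[r$values] >= dwell)
  }, TRUE)
  data.frame(label = rec$labels, keep = !sat,
             reason = ifelse(sat, "saturated", ""),
             stringsAsFactors = FALSE)
}

# single-frequency DFT power of an epoch-averaged signal
dft_power <- function(x, freqs, rate) {
  tt <- (seq_along(x) - 1) / rate
  vapply(freqs, function(f) {
    z <- sum(x * exp(-2i * pi * f * tt))
    Mod(z)^2
  }, 1)
}

#' Spectral F-test for an auditory steady-state response
#'
#' Epochs time-locked to the trigger events (one trigger period per epoch)
#' are averaged; the F statistic is the power at `f_mod` divided by the mean
#' power in `K` neighbouring frequency bins (excluding the 2 adjacent bins on
#' each side), referred to an F(2, 2K) distribution.
#'
#' @param x numeric signal.
#' @param triggers epoch-start sample indices.
#' @param rate sampling rate (Hz).
#' @param f_mod target (modulation) frequency (Hz).
#' @param K number of neighbour bins.
#' @return list with `F`, `p`, `power`, `noise_power`.
#' @export
assr_ftest <- function(x, triggers, rate, f_mod, K = 12) {
  if (f_mod >= rate / 2) stop("modulation frequency above Nyquist")
  ep_len <- min(diff(triggers))
  starts <- triggers[triggers + ep_len - 1 <= length(x)]
  if (length(starts) < 2) stop("not enough epochs for the ASSR F-test")
  idx <- outer(seq_len(ep_len) - 1L, starts, `+`)
  avg <- rowMeans(matrix(x[idx], nrow = ep_len))
  df_ <- rate / ep_len # bin spacing of the epoch
  side <- ceiling(K / 2)
  nb <- c(f_mod - (2 + seq_len(side)) * df_, f_mod + (2 + seq_len(side)) * df_)
  nb <- nb[nb > 0 & nb < rate / 2]
  nb <- nb[seq_len(min(K, length(nb)))]
  p0 <- dft_power(avg, f_mod, rate)
  pn <- dft_power(avg, nb, rate)
  Fstat <- p0 / mean(pn)
  list(F = Fstat, p = pf(Fstat, 2, 2 * length(nb), lower.tail = FALSE),
       power = p0, noise_power = mean(pn))
}

#' Discard channels without a detectable steady-state response
#'
#' For every unordered channel pair within each group, the bipolar signal's
#' ASSR is tested with the spectral F-test; a channel is kept when any of its
#' pairs reaches `p < alpha` in any group it belongs to (groups may overlap,
#' e.g. central scalp channels evaluated with both hemiscalp groups).
#'
#' @param rec a [recording] with stimulation-locked trigger events (the
#'   epoch clock, e.g. an 8 Hz trigger).
#' @param groups named list of channel-label vectors.
#' @param f_mod modulation frequency (Hz), default 40.
#' @param alpha significance level, default 0.05.
#' @param K neighbour bins of the F-test.
#' @return data.frame `label`, `keep`, `reason` (a `ChannelMask`).
#' @export
assr_discard <- function(rec, groups, f_mod = 40, alpha = 0.05, K = 12) {
  if (length(rec$triggers) < 3) stop("recording lacks stimulation triggers")
  keep <- stats::setNames(rep(FALSE, nrow(rec$data)), rec$labels)
  tested <- stats::setNames(rep(FALSE, nrow(rec$data)), rec$labels)
  for (g in names(groups)) {
    chs <- match(groups[[g]], rec$labels)
    if (anyNA(chs)) stop("group ", g, " has unknown channels")
    if (length(chs) < 2) stop("group ", g, " has fewer than 2 channels")
    tested[chs] <- TRUE
    for (i in seq_along(chs)[-length(chs)]) {
      for (j in (i + 1):length(chs)) {
        if (keep[chs[i]] && keep[chs[j]]) next
        bip <- rec$data[chs[i], ] - rec$data[chs[j], ]
        ft <- assr_ftest(bip, rec$triggers, rec$rate, f_mod, K)
        if (ft$p < alpha) keep[chs[i]] <- keep[chs[j]] <- TRUE
      }
    }
  }
  keep[!tested] <- TRUE # channels outside all groups are not judged
  data.frame(label = rec$labels, keep = unname(keep),
             reason = ifelse(keep | !tested, "", "assr-nonsignificant"),
             stringsAsFactors = FALSE)
}
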