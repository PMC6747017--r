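test_that("sampling-rate ratio is recovered from shared triggers", {
  a <- trigger_track(c(100, 600, 1100, 1600), 2000)
  expect_equal(estimate_rate_ratio(a, a), 1)
  # the same events seen by a 2000 Hz and a 2048 Hz amplifier
  times <- c(0.05, 0.55, 1.05, 1.55, 2.05)
  ta <- trigger_track(round(times * 2000), 2000)
  tb <- trigger_track(round(times * 2048), 2048)
  expect_equal(estimate_rate_ratio(ta, tb), 2000 / 2048, tolerance = 1e-6)
  expect_error(trigger_track(c(100), 2000), "at least 2")
  expect_error(estimate_rate_ratio(a, trigger_track(c(1, 2, 3), 500)),
               "counts differ")
})

test_that("merging aligns, resamples and re-references multi-amp recordings", {
  # 10 Hz sine at 2000 Hz resampled to 500 Hz preserves amplitude within 1%
  t1 <- seq(1 / 2000, 4, by = 1 / 2000)
  r1 <- recording(rbind(sin(2 * pi * 10 * t1), cos(2 * pi * 7 * t1),
                        0 * t1),
                  2000, c("C3", "C4", "FPz"),
                  triggers = round(c(0.5, 1.5, 2.5, 3.5) * 2000))
  t2 <- seq(1 / 1024, 4, by = 1 / 1024)
  r2 <- recording(rbind(sin(2 * pi * 5 * t2), 0 * t2), 1024, c("E1", "FPz"),
                  triggers = round(c(0.5, 1.5, 2.5, 3.5) * 1024))
  joint <- merge_recordings(list(r1, r2), target_rate = 500, ref_label = "FPz")
  expect_equal(joint$rate, 500)
  expect_equal(nrow(joint$data), 5)
  # reference rows are exactly zero
  iref <- grep("FPz", joint$labels)
  expect_true(all(joint$data[iref, ] == 0))
  # amplitude preserved through the resampling
  seg <- joint$data[1, 100:800]
  expect_equal(max(abs(seg)), 1, tolerance = 0.01)
  # first triggers aligned within one sample: both sines keep their phase
  # relation at the (shared) trigger instants
  expect_equal(joint$triggers[1], 1)
  # single input already at rate/reference is passed through losslessly
  r3raw <- rbind(rnorm(1000), rnorm(1000))
  r3 <- recording(sweep(r3raw, 2, r3raw[2, ]), 500, c("a", "FPz"),
                  triggers = c(10, 900))
  j3 <- merge_recordings(list(r3), target_rate = 500, ref_label = "FPz")
  expect_equal(j3$data[, 1:(1000 - 9)], r3$data[, 10:1000], tolerance = 1e-9)
  expect_error(merge_recordings(list(r1), ref_label = "Cz"), "reference")
})

test_that("cascading concatenates segments with offset triggers", {
  a <- recording(matrix(rnorm(20), 2), 500, c("a", "b"), triggers = c(2, 8))
  b <- recording(matrix(rnorm(20), 2), 500, c("a", "b"), triggers = c(3, 9))
  ab <- concat_recordings(list(a, b))
  expect_equal(ncol(ab$data), 20)
  expect_equal(ab$triggers, c(2L, 8L, 13L, 19L))
  expect_error(concat_recordings(list(a, recording(matrix(0, 2, 4), 250,
                                                   c("a", "b")))),
               "share labels")
})

test_that("filter chain: average reference, DC removal, notch attenuation", {
  tt <- seq(1 / 500, 6, by = 1 / 500)
  x <- rbind(2 + sin(2 * pi * 50 * tt) + 0.3 * sin(2 * pi * 9 * tt),
             -1 + 0.2 * sin(2 * pi * 13 * tt),
             0.5 + 0.1 * cos(2 * pi * 17 * tt))
  rec <- recording(x, 500, c("a", "b", "c"))
  out <- filter_chain(rec)
  mid <- 500:2500
  # 50 Hz line component attenuated by at least 40 dB
  ref50 <- sqrt(mean(sin(2 * pi * 50 * tt[mid])^2))
  resid50 <- 2 * abs(mean(out$data[1, mid] * exp(-2i * pi * 50 * tt[mid])))
  expect_lt(20 * log10(resid50 / ref50), -40)
  # the 9 Hz signal survives (amplitude 0.3 times 2/3 after average reference)
  resid9 <- 2 * abs(mean(out$data[1, mid] * exp(-2i * pi * 9 * tt[mid])))
  expect_equal(resid9, 0.2, tolerance = 0.05)
  # DC offsets removed: pure-offset channels go to numerical zero once the
  # high-pass transient has decayed
  dc <- rbind(rep(2, length(tt)), rep(-1, length(tt)), rep(0.5, length(tt)))
  dout <- filter_chain(recording(dc, 500, c("a", "b", "c")))
  expect_true(all(abs(rowMeans(dout$data[, 2400:2900])) < 1e-6 * 2))
  # across-channel mean is zero at every sample (average reference)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # notches above Nyquist are dropped with a warning
  expect_warning(filter_chain(recording(x[, 1:500], 300, rec$labels)),
                 "Nyquist")
})

test_that("saturated channels are flagged by rail dwell", {
  tt <- seq(1 / 500, 2, by = 1 / 500)
  clean <- 0.5 * sin(2 * pi * 5 * tt)
  clipped <- pmin(pmax(3 * sin(2 * pi * 5 * tt), -1), 1) # dwells at the rail
  spike <- clean
  spike[500] <- 1
  rec <- recording(rbind(clean, clipped, spike), 500, c("ok", "sat", "spike"))
  mask <- drop_saturated(rec, rail = 1, dwell = 10)
  expect_equal(mask$keep, c(TRUE, FALSE, TRUE))
  expect_equal(mask$reason[2], "saturated")
})

test_that("ASSR discard keeps responsive channels under the any-pair rule", {
  set.seed(42)
  rate <- 500
  n <- 10000
  trig <- as.integer(round(seq(1, n - 70, by = rate / 8)))
  tt <- seq_len(n) / rate
  assr <- sin(2 * pi * 40 * tt)
  x <- rbind(assr + rnorm(n), 0.8 * assr + rnorm(n), 1.2 * assr + rnorm(n),
             rnorm(n), rnorm(n))
  rec <- recording(x, rate, paste0("ch", 1:5), triggers = trig)
  mask <- assr_discard(rec, groups = list(g = paste0("ch", 1:5)))
  expect_true(all(mask$keep[1:3]))
  # invariant to channel order within the group
  mask2 <- assr_discard(rec, groups = list(g = paste0("ch", c(4, 2, 5, 1, 3))))
  expect_equal(mask2$keep, mask$keep)
  # a group with no responsive channel at all is discarded entirely
  mask_noise <- assr_discard(rec, groups = list(g = c("ch4", "ch5")))
  expect_false(any(mask_noise$keep[4:5]))
  expect_equal(unique(mask_noise$reason[4:5]), "assr-nonsignificant")
  # overlap: a channel kept if significant in either group it belongs to
  mask3 <- assr_discard(rec, groups = list(left = c("ch1", "ch4"),
                                           right = c("ch4", "ch5")))
  expect_true(mask3$keep[match("ch4", mask3$label)]) # pairs with ch1's ASSR
  expect_error(assr_discard(rec, groups = list(g = "ch1")), "fewer than 2")
  expect_error(assr_discard(rec, groups = list(g = c("ch1", "zz"))), "unknown")
})
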