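test_that("pair sensitivity: identity, antisymmetry, reference invariance", {
  lfm <- fx_ear_lfm()$lfm
  z <- pair_sensitivity(lfm, "EL01", "EL01")
  expect_true(all(z$magnitude == 0))
  ab <- pair_sensitivity(lfm, "EL01", "ER01")
  ba <- pair_sensitivity(lfm, "ER01", "EL01")
  expect_equal(ab$magnitude, ba$magnitude, tolerance = 1e-12)
  expect_equal(ab$s, -ba$s, tolerance = 1e-12)
  # pair sensitivities are invariant to LFM re-referencing
  avg <- rereference(lfm, "average")
  ab2 <- pair_sensitivity(avg, "EL01", "ER01")
  expect_equal(ab$s, ab2$s, tolerance = 1e-10 * max(ab$magnitude))
  expect_error(pair_sensitivity(lfm, "EL01", "nope"), "unknown")
})

test_that("orientation sweep oracle confirms magnitude and orientation", {
  lfm <- fx_ear_lfm()$lfm
  sm <- pair_sensitivity(lfm, "EL15", "ER15")
  dirs <- unit_sphere_dirs(10000)
  set.seed(21)
  nodes <- sample(which(sm$magnitude > 0), 30)
  proj <- abs(dirs %*% t(sm$s[nodes, , drop = FALSE])) # 10000 x 30
  best <- apply(proj, 2, which.max)
  maxv <- proj[cbind(best, seq_along(nodes))]
  expect_true(all(abs(maxv - sm$magnitude[nodes]) / sm$magnitude[nodes] < 1e-3))
  dots <- abs(rowSums(dirs[best, , drop = FALSE] * sm$orientation[nodes, , drop = FALSE]))
  expect_true(all(dots > 0.999))
})

test_that("single-electrode sensitivity requires the raw reference", {
  lfm <- fx_ear_lfm()$lfm
  s1 <- single_sensitivity(lfm, "EL15")
  expect_equal(s1$s, lfm$values[match("EL15", lfm$electrodes$label), , ],
               tolerance = 1e-15)
  expect_error(single_sensitivity(rereference(lfm, "average"), "EL15"),
               "unrecoverable")
  # magnitude decays with distance from the electrode beyond 10 mm depth
  ep <- as.numeric(lfm$electrodes[match("EL15", lfm$electrodes$label),
                                  c("x", "y", "z")])
  d <- sqrt(colSums((t(lfm$grid$nodes) - ep)^2))
  far <- d > 10
  fit <- stats::coef(stats::lm(log(s1$magnitude[far]) ~ log(d[far])))
  expect_lt(fit[2], -0.5) # decreasing trend in the far field
})

test_that("dB conversion round-trips and shifts correctly", {
  lfm <- fx_ear_lfm()$lfm
  sm <- pair_sensitivity(lfm, "EL15", "ER15")
  db <- to_db(sm)
  expect_equal(max(db$db), 0)
  half <- sm
  half$magnitude <- sm$magnitude / 2
  db2 <- to_db(half, reference = db$db_reference)
  expect_equal(db2$db, db$db - 20 * log10(2), tolerance = 1e-9)
  back <- db$db_reference * 10^(db$db / 20)
  expect_equal(back, sm$magnitude, tolerance = 1e-9 * max(sm$magnitude))
  expect_error(to_db(sm, reference = -1), "positive")
})

test_that("configuration comparison: identity and within/between-ear contrast", {
  lfm <- fx_ear_lfm()$lfm
  same <- compare_configurations(lfm, c("EL01", "ER01"), c("EL01", "ER01"))
  expect_true(all(abs(same$db_difference) < 1e-9, na.rm = TRUE))
  cmp <- compare_configurations(lfm, c("EL15", "ER15"), c("EL05", "EL11"))
  expect_gt(cmp$median, 10)          # between-ears is >= 10 dB stronger
  expect_lt(cmp$slope_b, cmp$slope_a) # within-ear decays faster with distance
})
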