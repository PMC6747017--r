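test_that("rigid fit recovers constructed transforms and is equivariant", {
  set.seed(5)
  pts <- matrix(rnorm(15, sd = 30), 5, 3)
  rownames(pts) <- paste0("P", 1:5)
  # identity
  r0 <- fit_rigid(pts, pts)
  expect_lt(max(abs(r0$transform$rotation - diag(3))), 1e-12)
  expect_lt(r0$rmse, 1e-12)
  # constructed rotation + translation recovered to 1e-9
  R <- rot_about(c(1, 2, -0.5), 30 * pi / 180)
  t_ <- c(4, -7, 12)
  tgt <- pts %*% t(R) + rep(1, 5) %o% t_
  r1 <- fit_rigid(pts, tgt)
  expect_lt(max(abs(r1$transform$rotation - R)), 1e-9)
  expect_lt(max(abs(r1$transform$translation - t_)), 1e-9)
  expect_lt(r1$rmse, 1e-9)
  # equivariance: pre-rotating both sets leaves rmse unchanged
  Q <- rot_about(c(0, 0, 1), 1.1)
  noisy <- tgt + matrix(rnorm(15, sd = 0.5), 5, 3)
  rmse1 <- fit_rigid(pts, noisy)$rmse
  rmse2 <- fit_rigid(pts %*% t(Q), noisy %*% t(Q))$rmse
  expect_equal(rmse1, rmse2, tolerance = 1e-9)
  # forward then backward composes to the identity
  fwd <- fit_rigid(pts, noisy)$transform
  bwd <- fit_rigid(noisy, pts)$transform
  comp <- compose_transform(bwd, fwd)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(comp$translation)), 1e-9)
  expect_error(fit_rigid(pts[1:2, ], tgt[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid(line, line %*% t(R)), "collinear")
})

test_that("noisy fiducial fits stay within the expected rmse", {
  set.seed(0)
  pts <- matrix(rnorm(15, sd = 30), 5, 3)
  R <- rot_about(c(1, 0, 1), 0.7)
  t_ <- c(10, 5, -3)
  rmses <- vapply(0:99, function(seed) {
    set.seed(seed)
    tgt <- pts %*% t(R) + rep(1, 5) %o% t_ + matrix(rnorm(15, sd = 0.5), 5, 3)
    fit_rigid(pts, tgt)$rmse
  }, numeric(1))
  expect_lte(max(rmses), 1.5)
})

test_that("head-coordinate alignment handles landmarks and mirror defects", {
  lm <- data.frame(label = c("nasion", "lpa", "rpa"),
                   x = c(0, -75, 75), y = c(95, 0, 0), z = c(0, 0, 0))
  tr <- align_head_coordinates(lm, lm)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-9)
  # known transform recovered
  R <- rot_about(c(0.2, 1, 0), 0.5)
  dig <- lm
  dig[, 2:4] <- as.matrix(lm[, 2:4]) %*% t(R) + rep(1, 3) %o% c(3, -2, 8)
  tr2 <- align_head_coordinates(dig, lm)
  back <- apply_transform(as.matrix(dig[, 2:4]), tr2)
  expect_lt(max(abs(back - as.matrix(lm[, 2:4]))), 1e-9)
  # swapped left/right pre-auricular labels make a mirror image
  swapped <- lm
  swapped$label <- c("nasion", "rpa", "lpa")
  expect_error(align_head_coordinates(swapped, lm), "mirror")
  expect_error(align_head_coordinates(lm[1:2, ], lm), "missing landmark")
})

test_that("earpiece placement carries mesh and electrodes by the fiducial fit", {
  set.seed(2)
  fid <- data.frame(label = paste0("P", 1:5),
                    x = c(0, 8, 0, -6, 3), y = c(0, 2, 9, 4, -5),
                    z = c(0, 6, 2, 7, 9))
  elec <- data.frame(label = paste0("E", 1:4),
                     x = rnorm(4, sd = 5), y = rnorm(4, sd = 5),
                     z = rnorm(4, sd = 5))
  imp <- icosphere(6, 2, center = c(1, 2, 3))
  # identity when digitized == CAD
  p0 <- place_earpiece(imp, fid, fid, elec)
  expect_lt(p0$rmse, 1e-12)
  expect_lt(max(abs(p0$electrodes$x - elec$x)), 1e-12)
  # known transform: electrodes land at the transformed CAD positions
  R <- rot_about(c(1, 1, 1), 0.9)
  t_ <- c(80, 5, -4)
  dig <- fid
  dig[, 2:4] <- as.matrix(fid[, 2:4]) %*% t(R) + rep(1, 5) %o% t_
  p1 <- place_earpiece(imp, fid, dig, elec)
  expected <- as.matrix(elec[, 2:4]) %*% t(R) + rep(1, 4) %o% t_
  expect_lt(max(abs(as.matrix(p1$electrodes[, 2:4]) - expected)), 1e-9)
  expect_lt(max(abs(p1$mesh$vertices -
                      (imp$vertices %*% t(R) + rep(1, nrow(imp$vertices)) %o% t_))),
            1e-9)
  # 0.5 mm digitizer noise: mean electrode placement error within 2 mm
  errs <- vapply(0:99, function(seed) {
    set.seed(seed)
    dign <- dig
    dign[, 2:4] <- as.matrix(dig[, 2:4]) + matrix(rnorm(15, sd = 0.5), 5, 3)
    p <- place_earpiece(imp, fid, dign, elec)
    mean(sqrt(rowSums((as.matrix(p$electrodes[, 2:4]) - expected)^2)))
  }, numeric(1))
  expect_lte(mean(errs), 2)
  # coplanar fiducials warn
  flat <- fid
  flat$z <- 0
  flat_dig <- flat
  expect_warning(place_earpiece(imp, flat, flat_dig, elec), "coplanar")
})
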