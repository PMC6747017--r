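test_that("sphere head meets nesting, spacing and face-count requests", {
  spec <- sphere_spec(faces = 2000)
  hm <- make_sphere_head(spec)
  rep_ <- check_nesting(hm)
  expect_true(all(rep_$nested & rep_$distance_ok))
  for (k in 1:4)
    expect_lt(abs(nrow(hm$surfaces[[k]]$faces) - 2000) / 2000, 0.1)
  # adjacent shell distances equal the radius gaps (up to mesh chord error)
  expect_lt(max(abs(rep_$distance - c(6, 6, 2))), 0.4)
  expect_error(sphere_spec(radii = c(78, 78.5, 86, 92)), "1 mm")
})

test_that("ear head is deterministic and electrodes sit on the surface", {
  eh <- fx_ear()
  eh2 <- make_ear_head(seed = 1)
  expect_identical(eh$electrodes, eh2$electrodes)
  expect_identical(eh$model$surfaces$scalp$vertices,
                   eh2$model$surfaces$scalp$vertices)
  # all electrodes within 0.1 mm of the carved scalp surface
  d <- point_surface_distance(as.matrix(eh$electrodes[, c("x", "y", "z")]),
                              eh$model$surfaces$scalp)$distance
  expect_lt(max(d), 0.1)
  # in-ear sets span a volume (smallest singular value above 1 mm)
  for (g in c("left-ear", "right-ear")) {
    p <- as.matrix(eh$electrodes[eh$electrodes$group == g, c("x", "y", "z")])
    expect_equal(nrow(p), 15)
    expect_gt(svd(sweep(p, 2, colMeans(p)))$d[3], 1)
  }
  expect_equal(sum(eh$electrodes$group == "periauricular"), 10)
  expect_equal(sum(eh$electrodes$group == "scalp"), 128)
  # the carved scalp is closed, genus 0, and labels the ear region
  v <- validate_mesh(eh$model$surfaces$scalp)
  expect_true(v$closed)
  expect_equal(v$euler, 2)
  expect_gt(sum(eh$model$surfaces$scalp$labels == "ear", na.rm = TRUE), 50)
  expect_error(make_ear_head(ears = ear_spec(concha_depth = 10, canal_depth = 10)),
               "budget")
})

test_that("analytic multilayer series reduces to the homogeneous closed form", {
  spec1 <- sphere_spec(conductivities = c(scalp = 0.33, skull = 0.33,
                                          csf = 0.33, brain = 0.33))
  pts <- icosphere(92, 2)$vertices
  pos <- c(25, -35, 20) # ecc ~0.6
  mom <- c(1e-8, 2e-8, -5e-9)
  vs <- analytic_sphere_potential(pos, mom, pts, spec1, max_degree = 200)
  vc <- homogeneous_sphere_potential(pos, mom, pts, 92, 0.33)
  expect_lt(max(abs(vs - vc)) / max(abs(vc)), 1e-10)
  # dipole at the center
  vs0 <- analytic_sphere_potential(c(0, 0, 0), mom, pts, spec1, 100)
  vc0 <- homogeneous_sphere_potential(c(0, 0, 0), mom, pts, 92)
  expect_lt(max(abs(vs0 - vc0)) / max(abs(vc0)), 1e-12)
})

test_that("series truncation converges and symmetry holds", {
  spec <- sphere_spec()
  pts <- icosphere(92, 2)$vertices
  pos <- c(0, 62.4 * sin(0.4), 62.4 * cos(0.4)) # ecc 0.8
  mom <- c(3e-9, -1e-8, 7e-9)
  v100 <- analytic_sphere_potential(pos, mom, pts, spec, 100)
  v200 <- analytic_sphere_potential(pos, mom, pts, spec, 200)
  expect_lt(max(abs(v100 - v200)) / max(abs(v200)), 1e-8)
  # tangential dipole at the center: antisymmetric under reflection through
  # the plane normal to the moment
  pm <- rbind(c(40, 20, 55), c(40, 20, -55))
  v <- analytic_sphere_potential(c(0, 0, 0), c(0, 0, 1e-8), pm, spec, 100)
  expect_equal(v[1], -v[2], tolerance = 1e-12)
  expect_error(analytic_sphere_potential(c(0, 0, 80), mom, pts, spec),
               "eccentricity")
})

test_that("simulated recordings follow the ground-truth mixing model", {
  fx <- fx_sphere()
  deep <- which(!fx$grid$near_boundary)
  # single noiseless source: rank-1 data
  sim1 <- simulate_sources(fx$lfm, list(list(node = deep[5], freq = 11)),
                           noise_sd = 0, duration = 0.5, rate = 200, seed = 7)
  sv <- svd(sim1$recording$data)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # ground-truth component PVAF on its own noiseless data is 100 %
  expect_equal(pvaf(sim1$recording, sim1$mixing, 1), 100, tolerance = 1e-9)
  # determinism per seed
  sim1b <- simulate_sources(fx$lfm, list(list(node = deep[5], freq = 11)),
                            noise_sd = 0, duration = 0.5, rate = 200, seed = 7)
  expect_identical(sim1$recording$data, sim1b$recording$data)
  # noise-only recording: PVAF of a unit component stays near zero
  pv <- vapply(1:100, function(seed) {
    set.seed(seed)
    ne <- dim(fx$lfm$values)[1]
    noise <- matrix(rnorm(ne * 100, sd = 1e-6), ne, 100)
    rec <- recording(noise, 200, fx$elec$label)
    u <- sin(2 * pi * 11 * seq_len(100) / 200)
    W <- fx$lfm$values[, deep[5], ] %*% c(1e-8, 0, 0)
    mix <- mixing_model(W / sqrt(sum(W^2)) * 1e-30, rbind(u), fx$elec$label)
    pvaf(rec, mix, 1)
  }, numeric(1))
  expect_true(all(abs(pv) < 5))
})
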