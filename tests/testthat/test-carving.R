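test_that("boolean carve volume matches the sphere-minus-lens closed form", {
  A <- icosphere(92, 4) # dense enough that mesh volume ~ analytic sphere
  B <- icosphere(15, 3, center = c(92, 0, 0))
  carved <- carve_ears(A, B, voxel = 1)
  expect_true(validate_mesh(carved)$closed)
  # lens (intersection of spheres R, r at center distance d) volume
  R <- 92; r <- 15; d <- 92
  lens <- pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
  expected <- mesh_volume(A) - lens
  expect_lt(abs(mesh_volume(carved) - expected) / expected, 0.02)
  expect_true(any(carved$labels == "ear", na.rm = TRUE))
})

test_that("impression outside the scalp leaves it unchanged", {
  A <- icosphere(92, 3)
  B <- icosphere(10, 2, center = c(150, 0, 0))
  expect_warning(out <- carve_ears(A, B), "outside")
  expect_identical(out$vertices, A$vertices)
})

test_that("check_nesting reports pair-wise nesting and distance failures", {
  hm <- make_sphere_head(sphere_spec(faces = 1280))
  rep1 <- check_nesting(hm)
  expect_true(all(rep1$nested))
  expect_true(all(rep1$distance_ok))
  # swapped inner/outer skull: nesting failure names the pair
  bad <- hm
  bad$surfaces$outer_skull <- hm$surfaces$inner_skull
  bad$surfaces$inner_skull <- hm$surfaces$outer_skull
  rep2 <- check_nesting(bad)
  expect_false(all(rep2$nested))
  expect_false(rep2$nested[rep2$pair == "scalp-outer_skull"] &&
                 rep2$nested[rep2$pair == "outer_skull-inner_skull"])
  # sub-dmin gap is reported with its distance
  s1 <- icosphere(90, 3)
  s2 <- icosphere(89.1, 3)
  hm2 <- head_model(icosphere(92, 3), s1, s2, icosphere(80, 3), check = FALSE)
  rep3 <- check_nesting(hm2, dmin = 1)
  i <- rep3$pair == "outer_skull-inner_skull"
  expect_false(rep3$distance_ok[i])
  expect_equal(rep3$distance[i], 0.9, tolerance = 0.05)
})

test_that("enforce_min_distance restores the 1 mm rule and is idempotent", {
  ok <- make_sphere_head(sphere_spec(faces = 1280))
  out0 <- enforce_min_distance(ok, dmin = 1)
  expect_identical(out0$surfaces$brain$vertices, ok$surfaces$brain$vertices)
  # concentric shells with a 0.5 mm gap get pushed to >= 1 mm
  hm <- head_model(icosphere(92, 3), icosphere(86, 3), icosphere(85.5, 3),
                   icosphere(78, 3), check = FALSE)
  fixed <- enforce_min_distance(hm, dmin = 1)
  rep_ <- check_nesting(fixed, 1)
  expect_true(all(rep_$nested))
  expect_true(all(rep_$distance >= 1))
  # idempotent: a second application returns the fixed model unchanged
  fixed2 <- enforce_min_distance(fixed, dmin = 1)
  expect_identical(fixed2$surfaces$inner_skull$vertices,
                   fixed$surfaces$inner_skull$vertices)
  # outer surfaces are never modified by carving or enforcement
  expect_identical(fixed$surfaces$scalp$vertices, hm$surfaces$scalp$vertices)
})

test_that("deep ear carve keeps the model nested after enforcement", {
  eh <- fx_ear()
  rep_ <- check_nesting(eh$model, 1)
  expect_true(all(rep_$nested))
  expect_true(all(rep_$distance >= 1))
  # independent nesting oracle: total solid angle of the outer surface at
  # inner-surface vertices is 4*pi (winding-number inside test)
  for (k in 1:3) {
    outer <- eh$model$surfaces[[k]]
    inner <- eh$model$surfaces[[k + 1]]
    idx <- round(seq(1, nrow(inner$vertices), length.out = 40))
    sa <- earfield:::cpp_solid_angle(inner$vertices[idx, , drop = FALSE],
                                     outer$vertices, outer$faces - 1L)
    expect_true(all(abs(sa - 4 * pi) < 1e-6))
  }
  # a nontrivial carve strictly reduces the scalp volume
  intact <- make_sphere_head(sphere_spec())$surfaces$scalp
  expect_lt(mesh_volume(eh$model$surfaces$scalp), mesh_volume(intact))
})
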