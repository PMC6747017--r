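test_that("icosphere geometry and validation invariants", {
  s <- icosphere(1, 3)
  expect_equal(nrow(s$faces), 20 * 4^3) # 1280
  v <- validate_mesh(s)
  expect_true(v$closed)
  expect_true(v$oriented)
  expect_equal(v$euler, 2)
  # volume converges to the sphere from below (inscribed polyhedron)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi) / (4 / 3 * pi), 0.01)
})

test_that("mesh file round-trips (STL ascii+binary, PLY, OFF)", {
  s <- icosphere(10, 2)
  for (fmt in c("ply", "off")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_mesh(s, f)
    s2 <- read_mesh(f)
    expect_equal(s2$faces, s$faces)
    expect_lt(max(abs(s2$vertices - s$vertices)), 1e-6)
  }
  # binary STL: float32, welded soup; signed volume preserved to f32 precision
  f <- tempfile(fileext = ".stl")
  write_mesh(s, f, binary = TRUE)
  s3 <- read_mesh(f)
  expect_equal(nrow(s3$faces), nrow(s$faces))
  expect_lt(abs(mesh_volume(s3) - mesh_volume(s)) / mesh_volume(s), 1e-5)
  # ascii STL
  f2 <- tempfile(fileext = ".stl")
  write_mesh(s, f2, binary = FALSE)
  s4 <- read_mesh(f2)
  expect_equal(nrow(s4$faces), nrow(s$faces))
  expect_lt(abs(mesh_volume(s4) - mesh_volume(s)) / mesh_volume(s), 1e-6)
})

test_that("defective STL (missing facet) reports the boundary edges", {
  s <- icosphere(10, 1)
  open_mesh <- trimesh(s$vertices, s$faces[-1, , drop = FALSE], validate = FALSE)
  f <- tempfile(fileext = ".stl")
  write_mesh(open_mesh, f, binary = FALSE)
  err <- tryCatch(read_mesh(f), error = function(e) conditionMessage(e))
  expect_match(err, "not closed")
  expect_match(err, "3 boundary edge")
})

test_that("unparseable mesh files raise located format errors", {
  f <- tempfile(fileext = ".stl")
  writeLines(c("solid junk", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0", "    endloop", "  endfacet",
               "endsolid junk"), f)
  expect_error(read_mesh(f), "line|byte")
  f2 <- tempfile(fileext = ".ply")
  writeLines("not a ply", f2)
  expect_error(read_mesh(f2), "magic|ply")
  expect_error(read_mesh(tempfile(fileext = ".off")), "exist")
})

test_that("solid angle: Gauss identity and octant triangle", {
  s <- icosphere(10, 3)
  # inside -> 4*pi, outside -> 0 (to 1e-9), over several deterministic points
  dirs <- unit_sphere_dirs(12)
  for (i in seq_len(nrow(dirs))) {
    expect_lt(abs(solid_angle(dirs[i, ] * 5, s) - 4 * pi), 1e-9)
    expect_lt(abs(solid_angle(dirs[i, ] * 15, s)), 1e-9)
  }
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(solid_angle(c(0, 0, 0), tri), pi / 2, tolerance = 1e-12)
  expect_warning(solid_angle(c(10, 0, 0.0001), s), "near-singular")
})

test_that("surface distance: concentric, identical, and sampling oracle", {
  s10 <- icosphere(10, 3)
  s8 <- icosphere(8, 3)
  expect_equal(surface_distance(s10, s8)$distance, 2, tolerance = 0.02)
  expect_lt(surface_distance(s10, s10)$distance, 1e-12)
  # brute-force oracle: min pairwise distance over dense surface samples
  set.seed(11)
  a <- icosphere(5, 2, center = c(0, 0, 0))
  b <- icosphere(3, 2, center = c(9.5, 1, 0.5))
  sample_surface <- function(m, n) {
    fa <- face_areas(m)
    fi <- sample(nrow(m$faces), n, replace = TRUE, prob = fa$area)
    u <- runif(n); v <- runif(n)
    sw <- u + v > 1
    u[sw] <- 1 - u[sw]; v[sw] <- 1 - v[sw]
    m$vertices[m$faces[fi, 1], ] * (1 - u - v) +
      m$vertices[m$faces[fi, 2], ] * u + m$vertices[m$faces[fi, 3], ] * v
  }
  pa <- sample_surface(a, 4000)
  pb <- sample_surface(b, 4000)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  oracle <- sqrt(max(min(d2), 0))
  d <- surface_distance(a, b)$distance
  expect_lt(d, oracle + 1e-9)     # exact min cannot exceed any sampled pair
  expect_lt(oracle - d, 0.3)      # and the sampling resolves it closely
})

test_that("remesh hits target, preserves volume, and densifies labeled regions", {
  s <- icosphere(92, 3)
  r <- remesh(s, 10000)
  expect_gt(nrow(r$faces), 9000)
  expect_lt(nrow(r$faces), 11000)
  expect_true(validate_mesh(r)$closed)
  expect_lt(abs(mesh_volume(r) - mesh_volume(s)) / mesh_volume(s), 0.01)
  # uniform sizing reduces area spread for an irregular input
  irr <- revolve_solid(c(0, 2, 4, 10, 18), c(6, 7, 7, 3, 1), c(0, 0, 1),
                       c(0, 0, 0), n_seg = 48)
  cv <- function(m) { a <- face_areas(m)$area; sd(a) / mean(a) }
  r2 <- remesh(irr, 2000)
  expect_lt(cv(r2), cv(irr))
  expect_lt(abs(mesh_volume(r2) - mesh_volume(irr)) / mesh_volume(irr), 0.01)
  # dense region: label an octant, demand a 4x area contrast
  s2 <- icosphere(92, 3)
  cen <- face_areas(s2)$centroid
  s2$labels <- ifelse(cen[, 1] > 60, "ear", NA)
  r3 <- remesh(s2, 4000, dense_region = "ear", density_ratio = 4)
  expect_true(validate_mesh(r3)$closed)
  a3 <- face_areas(r3)
  expect_gt(sum(!is.na(r3$labels) & r3$labels == "ear"), 10)
  # judge the contrast geometrically, away from the region boundary
  core <- a3$centroid[, 1] > 64
  far <- a3$centroid[, 1] < 55
  expect_lt(mean(a3$area[core]), mean(a3$area[far]) / 4)
})

test_that("trimesh merges duplicate vertices and drops degenerate faces", {
  s <- icosphere(1, 1)
  V <- rbind(s$vertices, s$vertices[1, ] + 1e-6) # near-duplicate of vertex 1
  F <- s$faces
  F[1, 1] <- nrow(V) # reroute one face through the duplicate
  m <- trimesh(V, F)
  expect_equal(nrow(m$vertices), nrow(s$vertices))
  expect_true(validate_mesh(m)$closed)
})
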