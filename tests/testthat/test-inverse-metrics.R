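# Formula oracles implemented independently (plain sums) against the package's
# metric operations.
oracle_pearson <- function(a, b) {
  n <- length(a)
  ca <- a - sum(a) / n
  cb <- b - sum(b) / n
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}
oracle_rv <- function(c_, f_) {
  d <- c_ - f_
  n <- length(c_)
  vd <- sum((d - sum(d) / n)^2) / (n - 1)
  vc <- sum((c_ - sum(c_) / n)^2) / (n - 1)
  100 * vd / vc
}

test_that("group-wise correlation matches the covariance formula", {
  set.seed(31)
  labels <- sprintf("e%02d", 1:45)
  groups <- rep(c("left-ear", "scalp", "right-ear"), each = 15)
  cvals <- rnorm(45)
  fvals <- rnorm(45)
  cm <- component_map(cvals, labels, groups)
  fm <- component_map(fvals, labels, groups)
  cg <- correlation_by_group(cm, fm)
  for (g in unique(groups)) {
    sel <- groups == g
    expect_equal(unname(cg[g]), oracle_pearson(cvals[sel], fvals[sel]),
                 tolerance = 1e-12)
  }
  # affine relation within a group gives +1 / -1
  fm2 <- component_map(ifelse(groups == "scalp", 2 * cvals + 3, -cvals),
                       labels, groups)
  cg2 <- correlation_by_group(cm, fm2)
  expect_equal(unname(cg2["scalp"]), 1, tolerance = 1e-12)
  expect_equal(unname(cg2["left-ear"]), -1, tolerance = 1e-12)
  # zero variance is reported as NA with a reason
  fm3 <- component_map(rep(1, 45), labels, groups)
  cg3 <- correlation_by_group(cm, fm3)
  expect_true(all(is.na(cg3)))
  expect_match(attr(cg3, "reason")[1], "zero variance")
})

test_that("residual variance matches its formula and the stated limits", {
  set.seed(32)
  c_ <- rnorm(20)
  f_ <- rnorm(20)
  expect_equal(residual_variance(c_, f_), oracle_rv(c_, f_), tolerance = 1e-12)
  expect_equal(residual_variance(c_, c_), 0)
  expect_equal(residual_variance(c_, rep(0, 20)), 100, tolerance = 1e-12)
  expect_error(residual_variance(rep(2, 20), f_), "zero variance")
  # C is scale-invariant, RV is not
  cm <- component_map(c_, sprintf("e%d", 1:20))
  fm <- component_map(f_, sprintf("e%d", 1:20))
  fms <- component_map(3 * f_ + 1, sprintf("e%d", 1:20))
  expect_equal(correlation_by_group(cm, fm)[["scalp"]],
               correlation_by_group(cm, fms)[["scalp"]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(residual_variance(cm, fm),
                                residual_variance(cm, fms))))
})

test_that("PVAF matches a per-channel brute-force computation", {
  set.seed(33)
  W <- matrix(rnorm(6), 3, 2)
  U <- matrix(rnorm(2 * 200), 2, 200)
  x <- W %*% U + matrix(rnorm(600, sd = 0.1), 3, 200)
  rec <- recording(x, 500, c("a", "b", "c"))
  mix <- mixing_model(W, U, rec$labels)
  for (m in 1:2) {
    y <- outer(W[, m], U[m, ])
    frac <- vapply(1:3, function(n) {
      r <- x[n, ] - y[n, ]
      sum((r - mean(r))^2) / sum((x[n, ] - mean(x[n, ]))^2)
    }, numeric(1))
    expect_equal(pvaf(rec, mix, m), 100 - 100 * mean(frac), tolerance = 1e-12)
  }
  # exact back-projection -> 100 %
  rec2 <- recording(outer(W[, 1], U[1, ]), 500, rec$labels)
  expect_equal(pvaf(rec2, mix, 1), 100, tolerance = 1e-12)
  # zero timecourse component on nonzero data -> 0 %
  mix0 <- mixing_model(W, rbind(rep(0, 200), U[2, ]), rec$labels)
  expect_equal(pvaf(rec, mix0, 1), 0, tolerance = 1e-12)
  # silent channel excluded with a warning
  x3 <- x
  x3[2, ] <- 0
  expect_warning(p <- pvaf(recording(x3, 500, rec$labels), mix, 1), "silent")
  expect_true(is.finite(p))
})

test_that("source quantization: exact node, lattice bound, brute force", {
  fx <- fx_sphere()
  grid <- fx$grid
  q <- quantize_source(grid$nodes[100, ], grid)
  expect_equal(q$node, 100)
  expect_equal(q$distance, 0)
  set.seed(34)
  for (i in 1:25) {
    loc <- runif(3, -40, 40)
    q <- quantize_source(loc, grid)
    # brute-force oracle
    d2 <- rowSums(sweep(grid$nodes, 2, loc)^2)
    expect_equal(q$node, which.min(d2))
    expect_equal(q$distance, sqrt(min(d2)), tolerance = 1e-12)
    expect_lte(q$distance, sqrt(3) / 2 * grid$spacing + 1e-9) # inside hull
  }
  far <- quantize_source(c(200, 0, 0), grid)
  expect_true(far$outside_hull)
})

test_that("component selection keeps the 12 lowest-RV in-brain components", {
  fx <- fx_sphere()
  set.seed(35)
  res <- data.frame(component = 1:25, rv = runif(25, 1, 40),
                    x = c(runif(20, -30, 30), rep(150, 5)),
                    y = runif(25, -30, 30), z = runif(25, -30, 30))
  sel <- select_components(res, fx$grid, k = 12)
  expect_equal(nrow(sel), 12)
  expect_true(all(sel$component <= 20)) # the 5 far dipoles are out-of-brain
  inb <- res[res$component <= 20, ]
  expect_lte(max(sel$rv), min(inb$rv[!inb$component %in% sel$component]))
  # deterministic tie-break by component index
  res2 <- res
  res2$rv <- 5
  sel2 <- select_components(res2, fx$grid, k = 12)
  expect_equal(sel2$component, 1:12)
  # all dipoles outside the brain: empty with a warning
  res3 <- res
  res3$x <- 200
  expect_warning(sel3 <- select_components(res3, fx$grid), "no fitted dipoles")
  expect_equal(nrow(sel3), 0)
  # strict inside test via the brain surface agrees here
  sel4 <- select_components(res, fx$grid, k = 12,
                            brain = fx$head$surfaces$brain)
  expect_equal(sel4$component, sel$component)
})

test_that("dipole fitting recovers sources and degrades monotonically", {
  fx <- fx_sphere()
  fitter <- dipole_fitter(fx$lfm)
  grid <- fx$grid
  deep <- which(!grid$near_boundary & sqrt(rowSums(grid$nodes^2)) < 0.8 * 78)
  set.seed(36)
  # noiseless: exact recovery
  node <- deep[77]
  mom <- c(1, -0.5, 2) * 1e-8
  cvec <- as.numeric(fx$lfm$values[, node, ] %*% mom)
  fit <- fit_dipole(cvec, fitter)
  expect_lt(sqrt(sum((fit$position - grid$nodes[node, ])^2)), 4)
  expect_lt(fit$rv, 1)
  expect_false(fit$on_hull)
  # two antipodal symmetric dipoles fit worse than any single source
  node2 <- quantize_source(-grid$nodes[node, ], grid)$node
  c2 <- cvec + as.numeric(fx$lfm$values[, node2, ] %*% (mom * c(-1, 1, -1)))
  fit2 <- fit_dipole(c2, fitter)
  expect_gt(fit2$rv, fit$rv)
  # monotone degradation: median scalp correlation non-increasing with noise
  sds <- c(0, 0.05, 0.3)
  med <- vapply(sds, function(s) {
    cors <- vapply(1:50, function(seed) {
      set.seed(seed)
      nd <- sample(deep, 1)
      cv <- as.numeric(fx$lfm$values[, nd, ] %*% (rnorm(3) * 1e-8))
      cv <- cv + rnorm(length(cv), sd = s * sd(cv))
      f <- fit_dipole(cv, fitter, refine = FALSE)
      qz <- quantize_source(f$position, grid)
      fv <- as.numeric(fx$lfm$values[, qz$node, ] %*% rep(1e-8, 3))
      cm <- component_map(cv, fx$elec$label)
      fmod <- modeled_map(cm, fx$lfm, qz$node, fit_labels = fx$elec$label)
      oracle_pearson(cv, fmod$values)
    }, numeric(1))
    median(cors)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
  expect_error(fit_dipole(rep(0, 128), fitter), "all-zero")
})

test_that("end-to-end recovery through simulation and evaluation", {
  fx <- fx_sphere()
  grid <- fx$grid
  deep <- which(!grid$near_boundary & sqrt(rowSums(grid$nodes^2)) < 0.7 * 78)
  sim <- simulate_sources(fx$lfm,
                          list(list(node = deep[10], freq = 10),
                               list(node = deep[200], freq = 23)),
                          noise_sd = 0, duration = 1, rate = 250, seed = 4)
  maps <- lapply(1:2, function(m)
    component_map(sim$mixing$inv_mixing[, m], fx$elec$label, fx$elec$group, m))
  ev <- evaluate_components(maps, fx$lfm, sim$recording, sim$mixing)
  expect_true(all(ev$rv < 1))
  expect_true(all(abs(ev$C_scalp - 1) < 1e-6))
  expect_equal(ev$quant_node, c(deep[10], deep[200]))
  expect_true(all(ev$pvaf > 0))
})
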