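# Shared, lazily-built fixtures (BEM systems are expensive; build once per run)
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# quasi-uniform spherical cap of n electrodes on a sphere of given radius
cap_electrodes <- function(n = 128, radius = 92, zmin = -0.3) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * (1 - zmin)
  th <- golden * i
  data.frame(label = sprintf("S%03d", i),
             x = sqrt(pmax(1 - z^2, 0)) * cos(th) * radius,
             y = sqrt(pmax(1 - z^2, 0)) * sin(th) * radius,
             z = z * radius, group = "scalp", stringsAsFactors = FALSE)
}

# 4-shell sphere head with the standard conductivities, assembled BEM system,
# 4 mm source grid and a 128-channel cap lead field (IPA)
fx_sphere <- function() fx_get("sphere", function() {
  spec <- sphere_spec(faces = 3000)
  head <- make_sphere_head(spec)
  sys <- bem_assemble(head)
  grid <- build_source_grid(head$surfaces$brain, spacing = 4)
  elec <- cap_electrodes(128, 92)
  lfm <- compute_leadfield(sys, grid, elec, use_ipa = TRUE)
  list(spec = spec, head = head, sys = sys, grid = grid, elec = elec,
       lfm = lfm)
})

# synthetic ear-augmented head (default stated-world spec, seed 1)
fx_ear <- function() fx_get("ear", function() make_ear_head(seed = 1))

# lead field of the ear head over all its electrodes (IPA, 4 mm grid)
fx_ear_lfm <- function() fx_get("ear_lfm", function() {
  eh <- fx_ear()
  sys <- bem_assemble(eh$model)
  grid <- build_source_grid(eh$model$surfaces$brain, spacing = 4)
  lfm <- compute_leadfield(sys, grid, eh$electrodes, use_ipa = TRUE)
  list(sys = sys, grid = grid, lfm = lfm)
})

# deterministic unit vectors (Fibonacci sphere)
unit_sphere_dirs <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  th <- pi * (3 - sqrt(5)) * i
  cbind(sqrt(pmax(1 - z^2, 0)) * cos(th), sqrt(pmax(1 - z^2, 0)) * sin(th), z)
}

center <- function(x) x - mean(x)

rot_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
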