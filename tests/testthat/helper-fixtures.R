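# Shared fixtures: phantoms are expensive, so they are built once per test
# run and cached. "small" is a coarse 64 x 64 x 32 grid (4 x 4 x 5 mm) over
# the same physical FOV as the default phantom; "full" is the default
# 128 x 128 x 64 grid at 2 x 2 x 2.5 mm used for study-condition checks.

.fixture_cache <- new.env(parent = emptyenv())

small_phantom <- function(site = "prostate_like", seed = 3L) {
  key <- paste("small", site, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_phantom(
      phantom_config(site, size = c(64L, 64L, 32L), spacing = c(4, 4, 5), seed = seed))
  .fixture_cache[[key]]
}

full_phantom <- function(site = "prostate_like", seed = 3L) {
  key <- paste("full", site, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_phantom(phantom_config(site, seed = seed))
  .fixture_cache[[key]]
}

small_cfg <- function(site = "prostate_like", seed = 3L) {
  phantom_config(site, size = c(64L, 64L, 32L), spacing = c(4, 4, 5), seed = seed)
}

# smooth, strictly positive seeded dose pair on a 48^3 grid for gamma tests
seeded_dose_pair <- function(seed, n = 48L, spacing = 2, noise = 0.04) {
  g <- volume_grid(rep(n, 3), rep(spacing, 3))
  set.seed(seed)
  base <- array(stats::rnorm(n^3), dim = rep(n, 3))
  base <- dosewarpqa:::cpp_gauss_smooth(base, g$size, g$spacing, 8)
  base <- (base - min(base)) / (max(base) - min(base)) * 60
  pert <- array(stats::rnorm(n^3), dim = rep(n, 3))
  pert <- dosewarpqa:::cpp_gauss_smooth(pert, g$size, g$spacing, 10)
  ev <- pmax(base * (1 + noise * pert / stats::sd(pert)), 0)
  list(reference = scalar_volume(base, g, "Gy"),
       evaluated = scalar_volume(ev, g, "Gy"))
}
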