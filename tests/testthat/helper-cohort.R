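# Session-cached synthetic cohorts shared across test files.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- subshape::simulate_cohort(config, meshes = FALSE)
  }
  .cohort_cache[[key]]
}

atrophy_config <- function(delta = 0.9, noise_sd = 0.3, n = 30L,
                           grid_dims = c(30L, 40L), seed = 21L) {
  subshape::simulation_config(
    structure_kind = "hippocampus_like",
    n_per_group = c(HC = n, PD = n),
    effect_regions = list(
      list(u = c(0.3, 0.7), v = c(0.8, 2.8), delta = delta, sign = "atrophy"),
      list(u = c(0.3, 0.7), v = c(0.8, 2.8) + pi, delta = delta, sign = "atrophy")),
    noise_sd = noise_sd, grid_dims = grid_dims, seed = seed)
}
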