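test_that("template surfaces are closed, deterministic and analytic grids match", {
  for (kind in c("hippocampus_like", "amygdala_like")) {
    tpl <- make_template_surface(kind, c(30L, 40L), seed = 1)
    expect_equal(euler_characteristic(tpl$mesh), 2L)
    expect_true(all(tpl$grid$lambda > 0))
    again <- make_template_surface(kind, c(30L, 40L), seed = 1)
    expect_identical(again$mesh$vertices, tpl$mesh$vertices)
    expect_identical(again$grid$positions, tpl$grid$positions)
  }
  expect_error(make_template_surface("hippocampus_like", c(3L, 40L)),
               class = "bad_argument")
})

test_that("cohort size, determinism and seed-independent truth masks", {
  cfg <- atrophy_config(seed = 77L, n = 3L, grid_dims = c(20L, 30L))
  co <- simulate_cohort(cfg, meshes = FALSE)
  expect_length(co$grids, 6L)
  expect_equal(as.vector(table(co$labels)), c(3L, 3L))
  co2 <- simulate_cohort(cfg, meshes = FALSE)
  expect_identical(co2$grids[[4]]$positions, co$grids[[4]]$positions)
  cfg_b <- atrophy_config(seed = 78L, n = 3L, grid_dims = c(20L, 30L))
  co_b <- simulate_cohort(cfg_b, meshes = FALSE)
  expect_identical(co_b$truth$effect_mask, co$truth$effect_mask)
  expect_false(identical(co_b$grids[[4]]$positions, co$grids[[4]]$positions))
})

test_that("null cohorts show no systematic group difference in radius", {
  cfg <- simulation_config(n_per_group = c(HC = 20L, PD = 20L),
                           effect_regions = list(), noise_sd = 0.3,
                           grid_dims = c(20L, 30L), seed = 5L)
  co <- simulate_cohort(cfg, meshes = FALSE)
  rd <- stack_features(lapply(co$grids, radial_distance), "RD")
  g1 <- co$labels == "HC"
  md <- colMeans(rd[g1, , 1]) - colMeans(rd[!g1, , 1])
  sem <- sqrt(apply(rd[g1, , 1], 2, var) / 20 + apply(rd[!g1, , 1], 2, var) / 20)
  # ~0.3% of nodes are expected beyond 3 SEM by chance alone
  expect_lt(mean(abs(md) > 3 * sem), 0.02)
  expect_lt(max(abs(md) / sem), 6)
})

test_that("noise-free atrophy shifts the radius by exactly delta at the core", {
  cfg <- simulation_config(n_per_group = c(HC = 2L, PD = 2L),
    effect_regions = list(list(u = c(0.35, 0.65), v = c(1, 2.5),
                               delta = 1.0, sign = "atrophy")),
    noise_sd = 0, grid_dims = c(30L, 40L), seed = 3L)
  co <- simulate_cohort(cfg, meshes = FALSE)
  core <- co$truth$true_delta == -1
  expect_gt(sum(core), 0)
  rd_hc <- radial_distance(co$grids[[1]])
  rd_pd <- radial_distance(co$grids[[3]])
  # antisymmetric ring-centroid shift is absent only radially per node:
  # compare raw radii through the generator geometry instead
  geom <- subshape:::template_geometry("hippocampus_like", 3L)
  ev0 <- subshape:::eval_radial_surface(geom, 30L, 40L)
  ev1 <- subshape:::eval_radial_surface(geom, 30L, 40L, co$truth$true_delta)
  expect_equal(unname((ev1$radius - ev0$radius)[core]), rep(-1, sum(core)),
               tolerance = 1e-12)
})

test_that("scores attain the configured correlation with realized deformation", {
  cfg <- simulation_config(n_per_group = c(HC = 100L, PD = 100L),
    effect_regions = list(list(u = c(0.3, 0.7), v = c(0.8, 2.8),
                               delta = 0.8, sign = "atrophy")),
    noise_sd = 0.3, grid_dims = c(20L, 30L), seed = 9L,
    score_spec = list(list(name = "moca", mean = 27, sd = 2, rho = 0.6)))
  co <- simulate_cohort(cfg, meshes = FALSE)
  r <- cor(co$scores$moca, co$truth$deformation)
  expect_lt(abs(r - 0.6), 0.15)
})

test_that("offsets through the medial axis are rejected", {
  cfg <- simulation_config(n_per_group = c(HC = 2L, PD = 2L),
    effect_regions = list(list(u = c(0.05, 0.95), v = c(0, 6.28),
                               delta = 20, sign = "atrophy")),
    noise_sd = 0, grid_dims = c(20L, 30L), seed = 1L)
  expect_error(simulate_cohort(cfg), class = "self_intersection")
})

test_that("cohorts serialize to PLY + JSON truth + TSV scores", {
  cfg <- simulation_config(n_per_group = c(HC = 2L, PD = 2L),
    effect_regions = list(list(u = c(0.4, 0.6), v = c(1, 2),
                               delta = 0.5, sign = "expansion")),
    noise_sd = 0.1, grid_dims = c(16L, 24L), seed = 2L,
    score_spec = list(list(name = "updrs", mean = 20, sd = 5, rho = 0.4)))
  co <- simulate_cohort(cfg, meshes = TRUE)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_length(list.files(d, pattern = "\\.ply$"), 4L)
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  mask <- rep(truth$effect_mask$values, truth$effect_mask$lengths)
  expect_identical(matrix(mask, 16, 24), unname(co$truth$effect_mask))
  sc <- read.table(file.path(d, "scores.tsv"), header = TRUE, sep = "\t")
  expect_equal(sc$updrs, co$scores$updrs, tolerance = 1e-12)
  back <- read_mesh(file.path(d, "subject_001.ply"))
  expect_equal(euler_characteristic(back), 2L)
})
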