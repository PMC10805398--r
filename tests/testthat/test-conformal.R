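test_that("a straight cylinder has a rotationally constant conformal factor", {
  cyl <- cylinder_mesh(r = 1, L = 4, n_ring = 48, n_len = 40)
  g <- conformal_parameterize(cyl, dims = c(30L, 45L))
  rel <- apply(g$lambda, 1, function(row) (max(row) - min(row)) / mean(row))
  expect_lt(max(rel), 0.01)
  expect_equal(g$metadata$flipped_param_triangles, 0L)
  # radius of resampled positions stays on the barrel
  rr <- sqrt(g$positions[, , 1]^2 + g$positions[, , 2]^2)
  expect_true(all(abs(rr - 1) < 0.01))
})

test_that("the conformal factor integrates to the surface area", {
  ell <- icosphere_mesh(4)
  ell$vertices <- ell$vertices %*% diag(c(3, 1, 1))
  g <- conformal_parameterize(ell, dims = c(40L, 60L))
  expect_lt(abs(grid_area(g) / mesh_area(ell) - 1), 0.01)
  expect_true(all(g$lambda > 0))
})

test_that("parameterization is deterministic and genus-checked", {
  tpl <- make_template_surface("hippocampus_like", c(24L, 36L), seed = 4)
  g1 <- conformal_parameterize(tpl$mesh, dims = c(20L, 30L))
  g2 <- conformal_parameterize(tpl$mesh, dims = c(20L, 30L))
  expect_identical(g1$positions, g2$positions)
  expect_identical(g1$lambda, g2$lambda)
  expect_error(conformal_parameterize(torus_mesh(), dims = c(20L, 30L)),
               class = "mesh_not_genus0")
})

test_that("conformal representation standardizes both channels", {
  tpl <- make_template_surface("amygdala_like", c(24L, 36L), seed = 2)
  rep <- conformal_representation(tpl$grid)
  expect_equal(mean(rep$lambda), 0, tolerance = 1e-12)
  expect_equal(stats::sd(rep$lambda), 1, tolerance = 1e-12)
  expect_equal(mean(rep$H), 0, tolerance = 1e-12)
  expect_equal(stats::sd(rep$H), 1, tolerance = 1e-12)
  expect_identical(conformal_representation(tpl$grid), rep)
  # near-spherical input: H nearly constant before standardization
  sph <- icosphere_mesh(3)
  gs <- conformal_parameterize(sph, dims = c(20L, 30L))
  expect_lt(diff(range(gs$H)) / mean(gs$H), 0.1)
})

test_that("scaling the mesh halves H and quadruples lambda", {
  tpl <- make_template_surface("hippocampus_like", c(24L, 36L), seed = 3)
  g1 <- conformal_parameterize(tpl$mesh, dims = c(20L, 30L))
  scaled <- triangle_mesh(2 * tpl$mesh$vertices, tpl$mesh$faces)
  g2 <- conformal_parameterize(scaled, dims = c(20L, 30L))
  expect_equal(g2$H, g1$H / 2, tolerance = 5e-2)
  expect_equal(g2$lambda, 4 * g1$lambda, tolerance = 5e-2)
})
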