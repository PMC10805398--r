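test_that("mean curvature matches 1/r on spheres", {
  H1 <- mean_curvature(icosphere_mesh(3))
  expect_true(all(abs(H1 - 1) < 0.02))
  H2 <- mean_curvature(icosphere_mesh(3, radius = 2))
  expect_true(all(abs(H2 - 0.5) < 0.01))
})

test_that("mean curvature matches 1/(2r) on a cylinder barrel", {
  cyl <- cylinder_mesh(r = 1, L = 4, n_ring = 48, n_len = 40)
  H <- mean_curvature(cyl)
  on_barrel <- abs(sqrt(cyl$vertices[, 1]^2 + cyl$vertices[, 2]^2) - 1) < 1e-9
  interior <- on_barrel & abs(cyl$vertices[, 3]) < 1.2
  expect_true(all(abs(H[interior] - 0.5) < 0.02))
})

test_that("mean curvature is invariant under rigid motion", {
  ico <- icosphere_mesh(2)
  H0 <- mean_curvature(ico)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- triangle_mesh(ico$vertices %*% t(R) + rep(c(5, -2, 3), each = nrow(ico$vertices)),
                         ico$faces)
  expect_equal(mean_curvature(moved), H0, tolerance = 1e-8,
               ignore_attr = TRUE)
})
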