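test_that("Loop subdivision obeys the face-count arithmetic and stays closed", {
  oct <- octahedron_mesh()
  expect_identical(loop_subdivide(oct, 0), oct)
  s3 <- loop_subdivide(oct, 3)
  expect_equal(nrow(s3$faces), 8L * 4L^3)
  expect_equal(euler_characteristic(s3), 2L)
})

test_that("Loop subdivision contracts control vertices toward their limit points", {
  ico <- icosahedron_mesh()
  # original vertices keep their indices across levels; their per-level
  # displacement must contract geometrically toward the limit surface
  pos <- lapply(0:4, function(lv) loop_subdivide(ico, lv)$vertices[1:12, ])
  step <- sapply(1:4, function(l) max(sqrt(rowSums((pos[[l + 1]] - pos[[l]])^2))))
  expect_true(all(diff(step) < 0))
  expect_true(all(step[-1] / step[-4] < 0.6))   # geometric contraction
  expect_lt(step[4], 5e-3)
})

test_that("quadric simplification hits its face budget on an icosphere", {
  ico4 <- icosphere_mesh(4)             # 5120 faces on the unit sphere
  simp <- simplify_mesh(ico4, 1280L)
  expect_lte(abs(nrow(simp$faces) - 1280L), 2L)
  expect_equal(euler_characteristic(simp), 2L)
  dev <- abs(sqrt(rowSums(simp$vertices^2)) - 1)
  expect_lt(max(dev), 0.01)
})

test_that("simplification edge cases behave", {
  ico <- icosphere_mesh(2)
  expect_identical(simplify_mesh(ico, nrow(ico$faces)), ico)
  expect_error(simplify_mesh(ico, 50L), class = "bad_argument")
  simp <- simplify_mesh(icosphere_mesh(3), 320L)
  resub <- loop_subdivide(simp, 1)
  expect_equal(nrow(resub$faces), 4L * nrow(simp$faces))
})
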