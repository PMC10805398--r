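test_that("closed primitive meshes satisfy the genus-zero contract", {
  oct <- octahedron_mesh()
  expect_equal(euler_characteristic(oct), 2L)
  expect_equal(mesh_area(oct), 8 * sqrt(3) / 2, tolerance = 1e-12)
  expect_gt(subshape:::mesh_signed_volume(oct), 0)

  tor <- torus_mesh()
  expect_equal(euler_characteristic(tor), 0L)
  expect_error(validate_mesh(tor), class = "mesh_not_genus0")
})

test_that("validation repairs orientation and merges duplicate vertices", {
  oct <- octahedron_mesh()
  flipped <- oct
  flipped$faces[3, ] <- flipped$faces[3, c(1, 3, 2)]   # one inconsistent face
  fixed <- validate_mesh(flipped)
  expect_gt(subshape:::mesh_signed_volume(fixed), 0)
  key <- function(f) sort(apply(f, 1, function(r) paste(sort(r), collapse = "-")))
  expect_identical(key(fixed$faces), key(oct$faces))

  dup <- oct
  dup$vertices <- rbind(dup$vertices, dup$vertices[1, ])   # unreferenced twin
  dup$faces[dup$faces == 1L][1] <- 7L                      # reference the twin
  merged <- validate_mesh(triangle_mesh(dup$vertices, dup$faces))
  expect_equal(nrow(merged$vertices), 6L)
  expect_equal(euler_characteristic(merged), 2L)
})

test_that("open meshes fail the watertightness check", {
  oct <- octahedron_mesh()
  open_mesh <- triangle_mesh(oct$vertices, oct$faces[-1, ])
  expect_error(validate_mesh(open_mesh), class = "mesh_not_watertight")
})

test_that("PLY round-trips preserve vertices and faces exactly", {
  ico <- icosphere_mesh(2)
  for (binary in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_mesh(ico, f, binary = binary)
    back <- read_mesh(f)
    expect_identical(back$vertices, ico$vertices)
    expect_identical(back$faces, ico$faces)
  }
})

test_that("VTK PolyData round-trips and carries point data", {
  ico <- icosphere_mesh(1)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(ico, f, point_data = list(H = mean_curvature(ico)))
  back <- read_mesh(f)
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-15)
  expect_identical(back$faces, ico$faces)
  expect_true(any(grepl("SCALARS H", readLines(f))))
})

test_that("unsupported formats raise structured errors", {
  expect_error(read_mesh("foo.obj"), class = "mesh_io")
  expect_error(write_mesh(octahedron_mesh(), "foo.stl"), class = "mesh_io")
})
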