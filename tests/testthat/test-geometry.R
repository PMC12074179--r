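test_that("biplanar mesh has the stated structure and area", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 4)
  expect_equal(nrow(mesh$faces), 2 * 2 * 9)          # 18 triangles per plane
  expect_equal(sum(mesh$plane_side == 1), 16)

  mesh14 <- build_biplanar_mesh(1.4, 1.4, 33)
  expect_equal(mesh_area(mesh14), 2 * 1.4^2, tolerance = 1e-12)
  expect_setequal(unique(mesh14$vertices[, 3]), c(0.7, -0.7))
  expect_equal(nrow(mesh14$faces), 2 * 2 * 32^2)
})

test_that("mesh construction is deterministic and z-mirror symmetric", {
  a <- build_biplanar_mesh(1.2, 0.9, 15)
  b <- build_biplanar_mesh(1.2, 0.9, 15)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  # reflecting z -> -z maps the vertex set onto itself
  mirrored <- a$vertices
  mirrored[, 3] <- -mirrored[, 3]
  key <- function(v) paste(round(v[, 1], 12), round(v[, 2], 12),
                           round(v[, 3], 12))
  expect_setequal(key(mirrored), key(a$vertices))
})

test_that("invalid mesh dimensions are rejected", {
  expect_error(build_biplanar_mesh(-1, 1), "invalid geometry")
  expect_error(build_biplanar_mesh(1, 0), "invalid geometry")
  expect_error(build_biplanar_mesh(1, 1, resolution = 3), "invalid geometry")
})

test_that("target-sphere sampling includes the center, stays inside, and is seeded", {
  expect_equal(sample_target_sphere(1), matrix(0, 1, 3))
  p <- sample_target_sphere(200, radius = 0.25, seed = 0)
  expect_equal(p[1, ], c(0, 0, 0))
  expect_true(all(sqrt(rowSums(p^2)) <= 0.25 + 1e-12))
  expect_identical(p, sample_target_sphere(200, radius = 0.25, seed = 0))
  expect_false(identical(p, sample_target_sphere(200, radius = 0.25,
                                                 seed = 1)))
})

test_that("axis probe lines match the measurement grid", {
  z <- axis_probe_line("z", -0.15, 0.15, 0.05)
  expect_equal(nrow(z), 7)
  expect_equal(z[, 3], seq(-0.15, 0.15, 0.05))
  expect_true(all(z[, 1:2] == 0))
  x <- axis_probe_line("x", -0.1, 0.1, 0.1)
  expect_equal(x[, 1], c(-0.1, 0, 0.1))
  expect_error(axis_probe_line("z", 0, 0, 0.05), "empty probe range")
  expect_error(axis_probe_line("z", -0.1, 0.1, -0.05), "step")
})

test_that("OBJ export and import round-trip a mesh", {
  mesh <- build_biplanar_mesh(0.8, 0.6, 5)
  f <- tempfile(fileext = ".obj")
  write_obj(mesh, f)
  back <- read_obj(f)
  expect_equal(back$vertices, unname(mesh$vertices), tolerance = 1e-8)
  expect_equal(back$faces, unname(mesh$faces))
})
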