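# PLY round-trips, sidecar labels and landmarks.

test_that("PLY round-trip is identity for ASCII and binary, labels included", {
  set.seed(7)
  fx <- generate_arch_mesh(arch_cfg(edge = 1.2), seed = 3)  # coarse arch, real labels
  mesh <- fx$mesh
  for (fmt in c("ascii", "binary_little_endian")) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_ply_mesh(mesh, f, format = fmt)
    back <- read_ply_mesh(f)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
    expect_identical(back$faces, mesh$faces)
    expect_identical(back$colors, mesh$colors)
    expect_identical(back$labels, mesh$labels)
  }
})

test_that("a minimal all-white PLY reads back verbatim, order preserved", {
  mesh <- square_mesh()
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply_mesh(mesh, f)
  back <- read_ply_mesh(f)
  expect_equal(nrow(back$vertices), 4)
  expect_equal(nrow(back$faces), 2)
  expect_true(all(back$colors == 255L))
  expect_identical(back$faces, mesh$faces)      # no reordering
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
})

test_that("PLY without color properties raises a 'no vertex colors' error", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 3",
    "property float x", "property float y", "property float z",
    "element face 1", "property list uchar int vertex_indices", "end_header",
    "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), f)
  expect_error(read_ply_mesh(f), "no vertex colors")
})

test_that("non-triangular faces are rejected with the face index", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "element face 2", "property list uchar int vertex_indices", "end_header",
    "0 0 0 255 255 255", "1 0 0 255 255 255", "0 1 0 255 255 255", "1 1 0 255 255 255",
    "3 0 1 2", "4 0 1 2 3"), f)
  expect_error(read_ply_mesh(f), "face 2")
})

test_that("mesh invariants are enforced at construction", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(colored_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(colored_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(colored_mesh(v, rbind(c(1, 2, 3)), colors = matrix(0L, 2, 3)),
               "one row per vertex")
  expect_error(colored_mesh(v, rbind(c(1, 2, 3)), labels = c(31L, 99L, 0L)),
               "invalid FDI")
})

test_that("label sidecar ranges, per-vertex arrays and errors behave as documented", {
  mesh <- colored_mesh(matrix(rnorm(600), 200, 3), rbind(c(1, 2, 3)),
                       colors = matrix(255L, 200, 3))
  f <- withr::local_tempfile(fileext = ".json")

  jsonlite::write_json(list("31" = list(c(0, 99))), f)
  lab <- read_tooth_labels(mesh, f)$labels
  expect_identical(lab, c(rep(31L, 100), rep(0L, 100)))

  jsonlite::write_json(setNames(list(), character()), f)
  expect_identical(read_tooth_labels(mesh, f)$labels, rep(0L, 200))

  jsonlite::write_json(list("31" = list(c(150, 250))), f)
  expect_error(read_tooth_labels(mesh, f), "out of vertex range")

  jsonlite::write_json(list("99" = list(c(0, 9))), f)
  expect_error(read_tooth_labels(mesh, f), "invalid FDI")

  jsonlite::write_json(list(per_vertex = c(rep(41L, 50), rep(0L, 150))), f)
  expect_identical(read_tooth_labels(mesh, f)$labels, c(rep(41L, 50), rep(0L, 150)))
})

test_that("landmark JSON round-trips and validates", {
  lm <- landmark_set(c(0, 0, 0), c(-40, 25, 0), c(-40, -25, 0),
                     superior_ref = c(0, 0, 30))
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(back$incisor_midpoint, lm$incisor_midpoint)
  expect_equal(back$db_cusp_left, lm$db_cusp_left)
  expect_equal(back$superior_ref, c(0, 0, 30))

  jsonlite::write_json(list(incisor_midpoint = c(0, 0, 0)), f)
  expect_error(read_landmarks(f), "lacks")
  expect_error(landmark_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})
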