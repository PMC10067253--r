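# Color classification, patch extraction, areas, OCA/OCN.

test_that("color classification follows the configured rule exactly", {
  mesh <- square_mesh()
  expect_false(any(classify_marked_vertices(mesh, mark_color())))

  cols <- matrix(255L, 4, 3); cols[2, ] <- c(255L, 0L, 0L)
  mesh <- square_mesh(cols)
  expect_identical(classify_marked_vertices(mesh, mark_color()),
                   c(FALSE, TRUE, FALSE, FALSE))
  expect_error(classify_marked_vertices(colored_mesh(mesh$vertices, mesh$faces)),
               "no vertex colors")
})

test_that("classification mask equals an independent per-vertex rule", {
  sim <- shared_sim()
  mesh <- sim$fixture$mesh
  cfg <- mark_color()
  mask <- classify_marked_vertices(mesh, cfg)
  # oracle: scripted scalar loop, one vertex at a time
  oracle <- vapply(seq_len(nrow(mesh$vertices)), function(i) {
    hsv <- grDevices::rgb2hsv(mesh$colors[i, 1], mesh$colors[i, 2], mesh$colors[i, 3],
                              maxColorValue = 255)
    dh <- abs(((hsv[1] * 360 - cfg$hue_center_deg + 180) %% 360) - 180)
    dh <= cfg$hue_halfwidth_deg && hsv[2] >= cfg$min_saturation
  }, logical(1))
  expect_identical(mask, oracle)
  expect_identical(sum(mask), sum(sim$truth$n_vertices))  # exactly the painted set
})

test_that("patch extraction equals brute-force connected components", {
  sim <- shared_sim()
  mesh <- sim$fixture$mesh
  mask <- classify_marked_vertices(mesh)
  patches <- extract_patches(mesh, mask, min_area_mm2 = 0.05)
  comps <- brute_components(mesh, mask)
  expect_equal(nrow(patches), length(comps))
  got <- lapply(patches$vertex_ids, sort)
  expect_setequal(
    vapply(got, paste, character(1), collapse = ","),
    vapply(comps, paste, character(1), collapse = ",")
  )
  # patch ids ordered by descending area
  expect_true(all(diff(patches$area_mm2) <= 1e-12))
})

test_that("separate painted discs give separate patches; small ones are discarded", {
  g <- flat_grid_mesh(12, 6, 0.2)
  g <- paint_disc(g, c(-3, 0, 0), 1)
  g <- paint_disc(g, c(3, 0, 0), 1)
  mask <- classify_marked_vertices(g)
  patches <- extract_patches(g, mask)
  expect_equal(nrow(patches), 2)

  # one disc of ~3 mm^2 against a 5 mm^2 floor: dropped but reported
  g2 <- flat_grid_mesh(8, 8, 0.2)
  g2 <- paint_disc(g2, c(0, 0, 0), sqrt(3 / pi))
  p2 <- extract_patches(g2, classify_marked_vertices(g2), min_area_mm2 = 5)
  expect_equal(nrow(p2), 0)
  expect_equal(nrow(attr(p2, "discarded")), 1)

  expect_equal(nrow(extract_patches(g2, rep(FALSE, nrow(g2$vertices)))), 0)
})

test_that("patch area uses fractional m/3 triangle weighting", {
  mesh <- square_mesh()
  expect_equal(patch_area(mesh, 1:4), 1.0)  # fully marked unit square

  tri <- colored_mesh(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.2, 0)),
                      rbind(c(1, 2, 3)), colors = matrix(255L, 3, 3))
  expect_equal(patch_area(tri, 1L), 0.03 / 3)  # one of three vertices marked
})

test_that("painted disc area approaches the analytic area under refinement", {
  errs <- vapply(c(0.4, 0.2), function(e) {
    g <- flat_grid_mesh(8, 8, e)
    g <- paint_disc(g, c(0, 0, 0), 1.5)
    abs(patch_area(g, attr(g, "painted")) - pi * 1.5^2) / (pi * 1.5^2)
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1])  # halving the edge shrinks the error
})

test_that("OCA is invariant under rigid motion of the mesh", {
  sim <- shared_sim()
  mesh <- sim$fixture$mesh
  patches <- extract_patches(mesh, classify_marked_vertices(mesh))
  set.seed(11)
  R <- random_rotation()
  moved <- colored_mesh(mesh$vertices %*% t(R) + matrix(c(5, -3, 2), nrow(mesh$vertices), 3, byrow = TRUE),
                        mesh$faces, mesh$colors, mesh$labels)
  patches2 <- extract_patches(moved, classify_marked_vertices(moved))
  expect_equal(sum(patches2$area_mm2), sum(patches$area_mm2), tolerance = 1e-9)
  expect_equal(nrow(patches2), nrow(patches))
})

test_that("occlusal metrics sum patches to totals, per tooth and per region", {
  patches <- tibble::tibble(
    patch_id = 1:3, tooth = c(31L, 36L, 36L), area_mm2 = c(2, 3, 5),
    n_vertices = c(5L, 5L, 5L), centroid_x = 0, centroid_y = 0, centroid_z = 0,
    vertex_ids = list(1:5, 6:10, 11:15)
  )
  m <- occlusal_metrics(patches)
  expect_equal(m$oca_mm2, 10)
  expect_equal(m$ocn, 3)
  expect_equal(m$per_tooth$oca_mm2[m$per_tooth$tooth == 36], 8)
  expect_equal(m$per_region$ocn[m$per_region$region == "molar"], 2)
  expect_equal(sum(m$per_tooth$oca_mm2), m$oca_mm2)

  m0 <- occlusal_metrics(patches[0, ])
  expect_equal(m0$oca_mm2, 0)
  expect_equal(m0$ocn, 0)
})

test_that("per-tooth OCA/OCN match the fixture painting plan", {
  sim <- shared_sim()
  patches <- extract_patches(sim$fixture$mesh,
                             classify_marked_vertices(sim$fixture$mesh))
  m <- occlusal_metrics(patches)
  plan_ocn <- table(sim$truth$tooth)
  got_ocn <- setNames(m$per_tooth$ocn, m$per_tooth$tooth)
  expect_equal(got_ocn[names(plan_ocn)], setNames(as.integer(plan_ocn), names(plan_ocn)))
  truth_area <- tapply(sim$truth$area_discretized_mm2, sim$truth$tooth, sum)
  got_area <- setNames(m$per_tooth$oca_mm2, m$per_tooth$tooth)
  expect_equal(unname(got_area[names(truth_area)]), as.numeric(truth_area),
               tolerance = 1e-9)
})
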