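# Synthetic arch generator, contact painting, film derivation.

test_that("default arch carries 14 labeled teeth and usable landmarks", {
  fx <- generate_arch_mesh(arch_cfg(edge = 0.5), seed = 1)
  teeth <- setdiff(unique(fx$mesh$labels), 0L)
  expect_length(teeth, 14)
  expect_setequal(teeth, c(31:37, 41:47))
  expect_s3_class(fx$landmarks, "landmark_set")
  expect_no_error(build_occlusal_frame(fx$landmarks))
})

test_that("the generator is deterministic per seed", {
  a <- generate_arch_mesh(arch_cfg(edge = 0.6), seed = 9)
  b <- generate_arch_mesh(arch_cfg(edge = 0.6), seed = 9)
  expect_identical(a$mesh, b$mesh)
  c <- generate_arch_mesh(arch_cfg(edge = 0.6), seed = 10)
  expect_false(identical(a$mesh$colors, c$mesh$colors))
})

test_that("halving the edge length roughly quadruples the vertex count", {
  n1 <- nrow(generate_arch_mesh(arch_cfg(edge = 0.8), seed = 1)$mesh$vertices)
  n2 <- nrow(generate_arch_mesh(arch_cfg(edge = 0.4), seed = 1)$mesh$vertices)
  expect_lt(abs(n2 / n1 - 4), 0.8)  # within 20%
  expect_error(arch_cfg(edge = -1), "positive")
})

test_that("two planned contacts on one tooth paint two components on that tooth", {
  fx <- generate_arch_mesh(arch_cfg(edge = 0.25), seed = 1)
  plan <- tibble::tibble(tooth = 36L, du = c(-0.8, 0.8), dv = 0,
                         radius_mm = 0.55, force_N = 40)
  fx <- paint_contacts(fx, plan)
  mask <- classify_marked_vertices(fx$mesh)
  comps <- brute_components(fx$mesh, mask)
  expect_length(comps, 2)
  for (comp in comps) {
    expect_true(all(fx$mesh$labels[comp] == 36L))
  }
})

test_that("unresolvable or off-tooth contacts are rejected", {
  fx <- generate_arch_mesh(arch_cfg(edge = 0.5), seed = 1)
  tiny <- tibble::tibble(tooth = 36L, du = 0, dv = 0, radius_mm = 0.1, force_N = 10)
  expect_error(paint_contacts(fx, tiny), "unresolvable")
  off <- tibble::tibble(tooth = 36L, du = 8, dv = 8, radius_mm = 1, force_N = 10)
  expect_error(paint_contacts(fx, off), "off that tooth")
  absent <- tibble::tibble(tooth = 38L, du = 0, dv = 0, radius_mm = 1, force_N = 10)
  expect_error(paint_contacts(fx, absent), "not present")
})

test_that("discretized painted area stays near the analytic disc area", {
  fx <- generate_arch_mesh(arch_cfg(edge = 0.2), seed = 1)
  plan <- tibble::tibble(tooth = c(36L, 46L), du = 0, dv = 0,
                         radius_mm = 1.2, force_N = 60)
  fx <- paint_contacts(fx, plan)
  rel <- abs(fx$truth$area_discretized_mm2 - fx$truth$area_target_mm2) /
    fx$truth$area_target_mm2
  expect_lt(max(rel), 0.05)
})

test_that("noiseless film points equal the projected truth under the identity", {
  sim <- shared_sim()
  frame <- sim$frame
  ctr <- to_frame(cbind(sim$truth$center_x, sim$truth$center_y, sim$truth$center_z),
                  frame)
  proj <- project_to_plane(ctr)
  pts <- tibble::as_tibble(sim$force_map)
  # film convention: u = y (patient-left), v = -x (posterior)
  expect_equal(pts$u_mm, unname(proj[, 2]), tolerance = 1e-9)
  expect_equal(pts$v_mm, unname(-proj[, 1]), tolerance = 1e-9)
  expect_equal(pts$force_N, sim$truth$force_N)
  expect_equal(pts$area_mm2, sim$truth$area_discretized_mm2)
})

test_that("film derivation is seed-deterministic and strays are recoverable", {
  fx <- paint_contacts(generate_arch_mesh(arch_cfg(edge = 0.4), seed = 2))
  m1 <- derive_force_map(fx, sigma_pos_mm = 0.3, sigma_force_rel = 0.05,
                         n_stray = 3, seed = 5)
  m2 <- derive_force_map(fx, sigma_pos_mm = 0.3, sigma_force_rel = 0.05,
                         n_stray = 3, seed = 5)
  expect_identical(tibble::as_tibble(m1), tibble::as_tibble(m2))

  m3 <- derive_force_map(fx, n_stray = 3, stray_offset_mm = 15, seed = 5)
  cleaned <- remove_stray_points(m3)
  expect_setequal(cleaned$id, attr(m3, "truth_ids"))
  expect_setequal(attr(cleaned, "removed")$id, attr(m3, "stray_ids"))
})

test_that("a single master seed reproduces the whole simulated study", {
  s1 <- simulate_occlusion(arch_cfg(edge = 0.5), sigma_pos_mm = 0.2, n_stray = 2,
                           seed = 7)
  s2 <- simulate_occlusion(arch_cfg(edge = 0.5), sigma_pos_mm = 0.2, n_stray = 2,
                           seed = 7)
  expect_identical(s1$fixture$mesh, s2$fixture$mesh)
  expect_identical(tibble::as_tibble(s1$force_map), tibble::as_tibble(s2$force_map))
  expect_identical(s1$truth$vertex_ids, s2$truth$vertex_ids)
})
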