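# Plane fitting, force vectorization, decomposition, aggregation, projection.

test_that("coplanar points give an exact plane through the centroid", {
  set.seed(1)
  xy <- matrix(runif(40, -2, 2), ncol = 2)
  pts <- cbind(xy, 2)
  pl <- fit_contact_plane(pts)
  expect_equal(unname(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(pl$center), c(colMeans(xy), 2), tolerance = 1e-12)
  expect_lt(pl$rms_residual_mm, 1e-12)
})

test_that("a tilted generating normal is recovered exactly without noise", {
  set.seed(2)
  n_true <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  u <- occlusal3d:::unitize(occlusal3d:::cross3(n_true, c(0, 1, 0)))
  v <- occlusal3d:::cross3(n_true, u)
  ab <- matrix(runif(60, -1.5, 1.5), ncol = 2)
  pts <- ab %*% rbind(u, v) + matrix(c(1, 2, 3), 30, 3, byrow = TRUE)
  pl <- fit_contact_plane(pts)
  expect_lt(angle_between(pl$normal, n_true), 1e-6)
})

test_that("the eigen plane normal agrees with a brute-force sphere search", {
  set.seed(3)
  for (rep in 1:4) {
    n_true <- occlusal3d:::unitize(c(rnorm(2, 0, 0.3), 1))
    u <- occlusal3d:::unitize(occlusal3d:::cross3(n_true, c(0, 1, 0)))
    v <- occlusal3d:::cross3(n_true, u)
    k <- sample(6:12, 1)
    ab <- matrix(runif(2 * k, -1.5, 1.5), ncol = 2)
    pts <- ab %*% rbind(u, v) + matrix(rnorm(3 * k, 0, 0.05), ncol = 3)
    pl <- fit_contact_plane(pts)
    expect_lt(angle_between(pl$normal, brute_normal(pts)) * 180 / pi, 0.5)
  }
})

test_that("collinear or tiny patches are rejected", {
  expect_error(fit_contact_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_error(fit_contact_plane(line), "collinear")
})

test_that("near-vertical patches fall back to the supplied orientation hint", {
  set.seed(4)
  # patch in the x = 0 plane: normal (1,0,0), z-component ~ 0
  yz <- matrix(runif(40, -2, 2), ncol = 2)
  pts <- cbind(0, yz)
  pl <- fit_contact_plane(pts, fallback_normal = c(-1, 0, 0.01))
  expect_equal(unname(pl$normal), c(-1, 0, 0), tolerance = 1e-9)
  expect_match(pl$warning, "near-vertical")
})

test_that("force vectors follow the mandibular sign convention and closed forms", {
  flat <- fit_contact_plane(cbind(matrix(runif(20, -1, 1), ncol = 2), 0))
  fv <- force_vector(flat, 100)
  expect_equal(c(fv$Fx, fv$Fy, fv$Fz), c(0, 0, -100), tolerance = 1e-9)
  expect_equal(c(fv$tip_x - fv$base_x, fv$tip_y - fv$base_y, fv$tip_z - fv$base_z),
               c(0, 0, -100), tolerance = 1e-9)

  fv0 <- force_vector(flat, 0)
  expect_equal(c(fv0$Fx, fv0$Fy, fv0$Fz), c(0, 0, 0))

  # tilted 10 degrees toward +y
  th <- 10 * pi / 180
  n <- c(0, sin(th), cos(th))
  u <- occlusal3d:::unitize(occlusal3d:::cross3(n, c(1, 0, 0)))
  v <- occlusal3d:::cross3(n, u)
  ab <- matrix(runif(30, -1, 1), ncol = 2)
  pl <- fit_contact_plane(ab %*% rbind(u, v))
  fv50 <- force_vector(pl, 50)
  expect_equal(sqrt(fv50$Fx^2 + fv50$Fy^2 + fv50$Fz^2), 50, tolerance = 1e-9)
  expect_equal(fv50$Fy, -50 * sin(th), tolerance = 1e-9)
  expect_equal(fv50$Fz, -50 * cos(th), tolerance = 1e-9)

  expect_error(force_vector(pl, -1), ">= 0")
})

random_forces <- function(n, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    nrm <- occlusal3d:::unitize(c(rnorm(2, 0, 0.4), abs(rnorm(1, 1, 0.2)) + 0.2))
    u <- occlusal3d:::unitize(occlusal3d:::cross3(nrm, c(0, 1, 0)))
    v <- occlusal3d:::cross3(nrm, u)
    ab <- matrix(runif(16, -1, 1), ncol = 2)
    ctr <- rnorm(3, 0, 10)
    pl <- fit_contact_plane(ab %*% rbind(u, v) + matrix(ctr, 8, 3, byrow = TRUE))
    fv <- force_vector(pl, runif(1, 0, 200))
    fv$patch_id <- i
    fv$tooth <- sample(c(31:37, 41:47), 1)
    fv
  })
  dplyr::bind_rows(rows)
}

test_that("decomposition conserves the magnitude and is linear over partitions", {
  f <- random_forces(200, seed = 5)
  rel <- abs(f$Fx^2 + f$Fy^2 + f$Fz^2 - f$magnitude_N^2) / pmax(f$magnitude_N^2, 1e-30)
  expect_lt(max(rel), 1e-9)
  # linearity: any split of the rows sums to the total
  total <- colSums(f[, c("Fx", "Fy", "Fz")])
  split1 <- colSums(f[1:77, c("Fx", "Fy", "Fz")])
  split2 <- colSums(f[78:200, c("Fx", "Fy", "Fz")])
  expect_equal(split1 + split2, total, tolerance = 1e-12)
})

test_that("per-tooth aggregation distinguishes vector resultant from magnitude sum", {
  f <- tibble::tibble(
    patch_id = 1:2, tooth = 37L, point_id = 1:2, area_mm2 = 1,
    magnitude_N = c(50, 70), Fx = 0, Fy = 0, Fz = c(-50, -70),
    base_x = 0, base_y = 0, base_z = 0, tip_x = 0, tip_y = 0,
    tip_z = c(-50, -70), plane_rms_mm = 0
  )
  s <- aggregate_by_tooth(f)
  expect_equal(s$Fz, -120)
  expect_equal(s$resultant_N, 120)

  f2 <- f
  f2$Fx <- c(10, -10); f2$Fz <- c(-10, -10)
  f2$magnitude_N <- sqrt(200)
  s2 <- aggregate_by_tooth(f2)
  expect_equal(c(s2$Fx, s2$Fy, s2$Fz), c(0, 0, -20))
  expect_equal(s2$resultant_N, 20)
  expect_equal(s2$sum_of_magnitudes_N, 28.284, tolerance = 1e-4)
  expect_gte(s2$sum_of_magnitudes_N, s2$resultant_N)
})

test_that("directional projection is consistent with the x/y/z decomposition", {
  f <- random_forces(60, seed = 6)
  pz <- project_direction(f, c(0, 0, 1), by = "tooth")
  agg <- aggregate_by_tooth(f)
  expect_equal(pz$force_N[match(agg$tooth, pz$tooth)], agg$Fz, tolerance = 1e-9)

  one <- f[1, ]; one$Fx <- 3; one$Fy <- 4; one$Fz <- 0
  expect_equal(project_direction(one, c(0, 1, 0), by = "arch")$force_N, 4)

  # basis completeness: projections on x,y,z recombine to the component sums
  px <- project_direction(f, c(1, 0, 0), by = "arch")$force_N
  py <- project_direction(f, c(0, 1, 0), by = "arch")$force_N
  pz_arch <- project_direction(f, c(0, 0, 1), by = "arch")$force_N
  expect_equal(c(px, py, pz_arch), unname(colSums(f[, c("Fx", "Fy", "Fz")])),
               tolerance = 1e-9)

  expect_error(project_direction(f, c(1, 1, 0)), "unit")
})

test_that("rotating the frame rotates components; resultants are invariant", {
  f <- random_forces(40, seed = 7)
  set.seed(7)
  R <- random_rotation()
  comp <- as.matrix(f[, c("Fx", "Fy", "Fz")])
  rot <- comp %*% t(R)
  f2 <- f
  f2$Fx <- rot[, 1]; f2$Fy <- rot[, 2]; f2$Fz <- rot[, 3]
  a1 <- aggregate_by_tooth(f)
  a2 <- aggregate_by_tooth(f2)
  expect_equal(a2$resultant_N, a1$resultant_N, tolerance = 1e-9)
  expect_equal(unname(as.matrix(a2[, c("Fx", "Fy", "Fz")])),
               unname(as.matrix(a1[, c("Fx", "Fy", "Fz")]) %*% t(R)),
               tolerance = 1e-9)
})

test_that("regional report evaluates the strict ordering and fills empty regions", {
  f <- random_forces(30, seed = 8)
  f$tooth <- 36L  # single region
  rep1 <- regional_comparison(f)
  expect_equal(rep1$regions$n_contacts[rep1$regions$region == "anterior"], 0L)
  expect_equal(rep1$regions$resultant_N[rep1$regions$region == "premolar"], 0)
  expect_false(any(rep1$ordering))

  # equal loading in all regions: strict ordering must be false
  f2 <- tibble::tibble(
    patch_id = 1:3, tooth = c(31L, 34L, 36L), point_id = 1:3, area_mm2 = 1,
    magnitude_N = 10, Fx = 1, Fy = 1, Fz = -sqrt(98),
    base_x = 0, base_y = 0, base_z = 0, tip_x = 1, tip_y = 1, tip_z = -sqrt(98),
    plane_rms_mm = 0
  )
  rep2 <- regional_comparison(f2)
  expect_false(any(rep2$ordering))
})
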