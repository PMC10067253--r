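# Ground-truthed synthetic fixtures: a mandibular-arch-like surface with
# paraboloid tooth crowns, planar wear facets at contact sites, painted
# articulating-paper marks of known area/normal, and a matched 2D film force
# record under a known planar similarity transform. Anatomical realism is a
# non-goal; closed-form ground truth is the point.

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Flat rectangular grid mesh
#'
#' A flat triangulated grid in the z = 0 plane, near-white base color.
#' Useful as a controlled substrate for area-measurement checks (painted
#' discs of known analytic area).
#'
#' @param width,height Extents in mm (x and y).
#' @param edge Target edge length in mm.
#' @param origin Length-2 lower-left corner (default centered at 0).
#' @return A [colored_mesh()].
#' @export
flat_grid_mesh <- function(width = 8, height = 8, edge = 0.2,
                           origin = c(-width / 2, -height / 2)) {
  if (width <= 0 || height <= 0 || edge <= 0) abort("sizes must be positive")
  nx <- max(2L, as.integer(round(width / edge)) + 1L)
  ny <- max(2L, as.integer(round(height / edge)) + 1L)
  xs <- seq(origin[1], origin[1] + width, length.out = nx)
  ys <- seq(origin[2], origin[2] + height, length.out = ny)
  g <- expand.grid(y = ys, x = xs)  # y fastest: index = (ix-1)*ny + iy
  verts <- cbind(g$x, g$y, 0)
  faces <- grid_faces(nx, ny)
  colored_mesh(verts, faces, colors = matrix(243L, nrow(verts), 3))
}

# Triangulation of an nx x ny vertex grid (second index fastest).
grid_faces <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1L), each = ny - 1L)
  iy <- rep(seq_len(ny - 1L), times = nx - 1L)
  v00 <- (ix - 1L) * ny + iy
  v01 <- v00 + 1L
  v10 <- v00 + ny
  v11 <- v10 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Paint a disc-shaped mark on a mesh
#'
#' Recolors all vertices within Euclidean distance `radius` of `center`
#' (3D). On locally flat or gently curved surfaces this approximates a
#' geodesic disc of area `pi * radius^2`.
#'
#' @param mesh A [colored_mesh()].
#' @param center Length-3 point, mm.
#' @param radius Disc radius, mm.
#' @param color RGB triple for the mark.
#' @return The recolored mesh; attribute `"painted"` holds the vertex ids.
#' @export
paint_disc <- function(mesh, center, radius, color = c(205L, 30L, 45L)) {
  d2 <- (mesh$vertices[, 1] - center[1])^2 + (mesh$vertices[, 2] - center[2])^2 +
    (mesh$vertices[, 3] - center[3])^2
  ids <- which(d2 <= radius^2)
  cols <- mesh$colors
  cols[ids, ] <- matrix(as.integer(color), length(ids), 3, byrow = TRUE)
  out <- colored_mesh(mesh$vertices, mesh$faces, cols, mesh$labels)
  attr(out, "painted") <- ids
  out
}

#' Arch fixture configuration
#'
#' Geometry of the synthetic mandibular arch: tooth crowns are paraboloid
#' caps of height `crown_height` placed along a parabolic arch of
#' intermolar width `arch_width` and anteroposterior depth `arch_depth`,
#' each truncated near its apex by a planar wear facet (drop `facet_drop`
#' below the cusp level, tilted `facet_tilt_deg` from horizontal). Facets
#' make contact sites exactly planar, so their normals are known in closed
#' form. Mesh resolution is `edge` mm (scanner resolution is not
#' standardized; 0.2 mm is typical of intraoral-scan exports).
#'
#' @param arch_width Distance between left and right last-molar centers, mm.
#' @param arch_depth Anteroposterior arch depth, mm.
#' @param teeth_per_quadrant Teeth per side (default 7: FDI 31-37 / 41-47).
#' @param band_halfwidth Half-width of the meshed arch band, mm.
#' @param edge Mesh edge length, mm.
#' @param crown_height Cusp height above the gingival base plane, mm.
#' @param facet_drop Wear-facet depth below cusp level, mm.
#' @param facet_tilt_deg Facet tilt from horizontal, degrees.
#' @return A config list of class `arch_cfg`.
#' @export
arch_cfg <- function(arch_width = 52, arch_depth = 44, teeth_per_quadrant = 7,
                     band_halfwidth = 5.5, edge = 0.2, crown_height = 8,
                     facet_drop = 2, facet_tilt_deg = 8) {
  vals <- c(arch_width, arch_depth, teeth_per_quadrant, band_halfwidth, edge,
            crown_height, facet_drop)
  if (any(!is.finite(vals)) || any(vals <= 0)) abort("arch_cfg sizes must be positive")
  structure(list(arch_width = arch_width, arch_depth = arch_depth,
                 teeth_per_quadrant = as.integer(teeth_per_quadrant),
                 band_halfwidth = band_halfwidth, edge = edge,
                 crown_height = crown_height, facet_drop = facet_drop,
                 facet_tilt_deg = facet_tilt_deg), class = "arch_cfg")
}

# Tooth table for a config: FDI code, 2D center on the arch centerline,
# crown radius, facet plane (slope vector p = tan(tilt) * u, u the facet
# azimuth with equal |x| and |y| weight, y-sign by side).
arch_teeth <- function(cfg) {
  W <- cfg$arch_width; D <- cfg$arch_depth
  q <- cfg$teeth_per_quadrant
  yy <- seq(W / 2, -W / 2, length.out = 4001)
  xx <- -D * (2 * yy / W)^2
  seg <- sqrt(diff(xx)^2 + diff(yy)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n_teeth <- 2L * q
  s_t <- (seq_len(n_teeth) - 0.5) / n_teeth * L
  cx <- stats::approx(s, xx, xout = s_t)$y
  cy <- stats::approx(s, yy, xout = s_t)$y
  # left quadrant (3x: +y) comes first along the arc from +W/2
  fdi <- c(30L + rev(seq_len(q)), 40L + seq_len(q))
  side <- ifelse(fdi < 40L, 1, -1)  # +1 patient-left
  spacing <- L / n_teeth
  R <- rep(min(spacing / 2 * 0.95, cfg$band_halfwidth * 0.75), n_teeth)
  p_mag <- tan(cfg$facet_tilt_deg * pi / 180)
  u <- cbind(rep(sqrt(0.5), n_teeth), side * sqrt(0.5))
  tibble(
    tooth = fdi, cx = cx, cy = cy, radius = R,
    px = p_mag * u[, 1], py = p_mag * u[, 2]
  )
}

# Surface height and owning tooth at 2D points for a tooth table.
arch_surface <- function(xy, teeth, cfg) {
  H <- cfg$crown_height; delta <- cfg$facet_drop
  z <- numeric(nrow(xy))
  lab <- integer(nrow(xy))
  best <- rep(-Inf, nrow(xy))
  for (i in seq_len(nrow(teeth))) {
    dx <- xy[, 1] - teeth$cx[i]
    dy <- xy[, 2] - teeth$cy[i]
    rho2 <- dx^2 + dy^2
    cap <- H * (1 - rho2 / teeth$radius[i]^2)
    facet <- (H - delta) + teeth$px[i] * dx + teeth$py[i] * dy
    zi <- pmin(cap, facet)
    zi[cap <= 0] <- 0
    take <- zi > best & cap > 0
    z[take] <- zi[take]
    lab[take] <- teeth$tooth[i]
    best[take] <- zi[take]
  }
  z[z < 0] <- 0
  list(z = z, label = lab)
}

#' Generate a synthetic mandibular arch mesh with landmarks and labels
#'
#' Builds the arch surface of [arch_cfg()] as a regular band mesh along the
#' parabolic arch, with per-vertex FDI labels, a near-white speckled base
#' color (deterministic per `seed`), and analytic landmarks: the incisor
#' midpoint and the distobuccal cusp points of the last molars, all at cusp
#' level, so the occlusal plane of the generated arch is exactly the plane
#' through the cusp tips.
#'
#' @param cfg An [arch_cfg()].
#' @param seed Integer seed (controls only the base-color speckle).
#' @return A list of class `arch_fixture`: `mesh` ([colored_mesh()]),
#'   `landmarks` ([landmark_set()]), `teeth` (tooth table with facet
#'   geometry), `cfg`, `seed`, and empty `truth`.
#' @export
generate_arch_mesh <- function(cfg = arch_cfg(), seed = 1) {
  W <- cfg$arch_width; D <- cfg$arch_depth; h <- cfg$band_halfwidth
  # arc-length-uniform centerline sampling
  yy <- seq(W / 2, -W / 2, length.out = 4001)
  xx <- -D * (2 * yy / W)^2
  seg <- sqrt(diff(xx)^2 + diff(yy)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n_arc <- max(3L, as.integer(round(L / cfg$edge)) + 1L)
  s_u <- seq(0, L, length.out = n_arc)
  cx <- stats::approx(s, xx, xout = s_u)$y
  cy <- stats::approx(s, yy, xout = s_u)$y
  # unit tangent then normal (band offset direction)
  tx <- c(diff(cx), NA); ty <- c(diff(cy), NA)
  tx[n_arc] <- tx[n_arc - 1]; ty[n_arc] <- ty[n_arc - 1]
  tn <- sqrt(tx^2 + ty^2)
  tx <- tx / tn; ty <- ty / tn
  nx <- -ty; ny <- tx
  n_band <- max(3L, as.integer(round(2 * h / cfg$edge)) + 1L)
  offs <- seq(-h, h, length.out = n_band)
  px <- rep(cx, each = n_band) + rep(offs, times = n_arc) * rep(nx, each = n_band)
  py <- rep(cy, each = n_band) + rep(offs, times = n_arc) * rep(ny, each = n_band)
  teeth <- arch_teeth(cfg)
  surf <- arch_surface(cbind(px, py), teeth, cfg)
  verts <- cbind(px, py, surf$z)
  faces <- grid_faces(n_arc, n_band)
  cols <- local_seed(seed, {
    base <- matrix(c(243, 242, 238), nrow(verts), 3, byrow = TRUE)
    pmin(pmax(round(base + matrix(stats::rnorm(3 * nrow(verts), 0, 2), ncol = 3)), 0), 255)
  })
  mesh <- colored_mesh(verts, faces, colors = cols, labels = surf$label)
  H <- cfg$crown_height
  last_l <- teeth[teeth$tooth == max(teeth$tooth[teeth$tooth < 40L]), ]
  last_r <- teeth[teeth$tooth == max(teeth$tooth), ]
  # distobuccal cusp points: distal-buccal corner of the last molars, at cusp
  # level (analytic landmark input, mirroring manually picked points)
  db_off <- function(tt, side) {
    c(tt$cx - 0.35 * tt$radius, tt$cy + side * 0.35 * tt$radius, H)
  }
  landmarks <- landmark_set(
    incisor_midpoint = c(0, 0, H),
    db_cusp_left = db_off(last_l, +1),
    db_cusp_right = db_off(last_r, -1),
    superior_ref = c(0, 0, H + 20)
  )
  structure(list(mesh = mesh, landmarks = landmarks, teeth = teeth, cfg = cfg,
                 seed = seed, truth = NULL),
            class = "arch_fixture")
}

#' @export
print.arch_fixture <- function(x, ...) {
  cat(sprintf("<arch_fixture> %d teeth, %d vertices, edge %.3g mm, seed %d\n",
              nrow(x$teeth), nrow(x$mesh$vertices), x$cfg$edge, x$seed))
  if (!is.null(x$truth)) {
    cat(sprintf("  %d painted contacts, total force %.1f N\n",
                nrow(x$truth), sum(x$truth$force_N)))
  }
  invisible(x)
}

#' Contact plans for the arch fixture
#'
#' One row per intended contact: tooth, offset (`du`, `dv`, mm, in the
#' world x/y plane relative to the tooth's facet center), mark radius and
#' force. `default_contact_plan()` emulates physiologic loading (first molar
#' carries the greatest force; anterior < premolar < molar);
#' `bruxism_contact_plan()` puts the greatest force on the second molars,
#' as seen with parafunctional grinding.
#'
#' @param cfg An [arch_cfg()] (determines which teeth exist).
#' @return A tibble `tooth`, `du`, `dv`, `radius_mm`, `force_N`.
#' @export
default_contact_plan <- function(cfg = arch_cfg()) {
  q <- cfg$teeth_per_quadrant
  pos <- seq_len(q)
  force_by_pos <- c(8, 10, 12, 30, 40, 80, 60, 55)[pos]
  radius_by_pos <- c(0.8, 0.8, 0.8, 1.0, 1.0, 1.2, 1.2, 1.2)[pos]
  tibble(
    tooth = c(30L + pos, 40L + pos),
    du = 0, dv = 0,
    radius_mm = rep(radius_by_pos, 2),
    force_N = rep(force_by_pos, 2)
  )
}

#' @rdname default_contact_plan
#' @export
bruxism_contact_plan <- function(cfg = arch_cfg()) {
  plan <- default_contact_plan(cfg)
  q <- cfg$teeth_per_quadrant
  if (q >= 7) {
    second_molar <- c(37L, 47L)
    plan$force_N[plan$tooth %in% second_molar] <- 150
  }
  plan
}

#' Paint planned contacts onto an arch fixture
#'
#' Recolors all vertices within `radius_mm` (Euclidean) of each planned
#' contact center with the mark color (small deterministic hue/value jitter
#' emulates scan color noise) and records the ground truth: analytic facet
#' normal, target area `pi r^2`, the discretized painted area, the contact
#' center, and the planned force.
#'
#' @param fixture An [generate_arch_mesh()] result.
#' @param plan Contact plan tibble (see [default_contact_plan()]).
#' @param mark_rgb Mark color RGB.
#' @param seed Integer seed for the color jitter.
#' @return The fixture with painted `mesh` and a `truth` tibble: `contact_id`,
#'   `tooth`, `center_x/y/z`, `normal_x/y/z` (unit, upward), `radius_mm`,
#'   `area_target_mm2`, `area_discretized_mm2`, `force_N`, `n_vertices`,
#'   `vertex_ids` (list).
#' @export
paint_contacts <- function(fixture, plan = default_contact_plan(fixture$cfg),
                           mark_rgb = c(205L, 30L, 45L), seed = 1) {
  stopifnot(inherits(fixture, "arch_fixture"))
  cfg <- fixture$cfg
  teeth <- fixture$teeth
  mesh <- fixture$mesh
  H <- cfg$crown_height; delta <- cfg$facet_drop
  if (any(plan$radius_mm < cfg$edge / 2)) {
    abort("unresolvable contact: radius below half the mesh edge length")
  }
  truth_rows <- vector("list", nrow(plan))
  cols <- mesh$colors
  for (i in seq_len(nrow(plan))) {
    tt <- teeth[teeth$tooth == plan$tooth[i], ]
    if (nrow(tt) == 0) abort(sprintf("tooth %d not present in this arch", plan$tooth[i]))
    ctr_xy <- c(tt$cx + plan$du[i], tt$cy + plan$dv[i])
    d_all <- sqrt((teeth$cx - ctr_xy[1])^2 + (teeth$cy - ctr_xy[2])^2)
    if (teeth$tooth[which.min(d_all)] != plan$tooth[i] || min(d_all) > tt$radius) {
      abort(sprintf("contact center for tooth %d lies off that tooth", plan$tooth[i]))
    }
    ctr_z <- (H - delta) + tt$px * plan$du[i] + tt$py * plan$dv[i]
    center <- c(ctr_xy, ctr_z)
    d2 <- (mesh$vertices[, 1] - center[1])^2 + (mesh$vertices[, 2] - center[2])^2 +
      (mesh$vertices[, 3] - center[3])^2
    ids <- which(d2 <= plan$radius_mm[i]^2)
    if (length(ids) < 3) {
      abort(sprintf("unresolvable contact on tooth %d: only %d mesh vertices in radius",
                    plan$tooth[i], length(ids)))
    }
    normal <- unitize(c(-tt$px, -tt$py, 1))
    truth_rows[[i]] <- tibble(
      contact_id = i, tooth = plan$tooth[i],
      center_x = center[1], center_y = center[2], center_z = center[3],
      normal_x = normal[1], normal_y = normal[2], normal_z = normal[3],
      radius_mm = plan$radius_mm[i],
      area_target_mm2 = pi * plan$radius_mm[i]^2,
      force_N = plan$force_N[i],
      n_vertices = length(ids), vertex_ids = list(ids)
    )
    cols[ids, ] <- matrix(as.integer(mark_rgb), length(ids), 3, byrow = TRUE)
  }
  # deterministic color jitter on marks only (stays inside the HSV window)
  truth <- dplyr::bind_rows(truth_rows)
  all_ids <- unique(unlist(truth$vertex_ids))
  cols[all_ids, ] <- local_seed(seed, {
    jit <- matrix(stats::rnorm(3 * length(all_ids), 0, 4), ncol = 3)
    pmin(pmax(round(cols[all_ids, , drop = FALSE] + jit), 0L), 255L)
  })
  painted <- colored_mesh(mesh$vertices, mesh$faces, cols, mesh$labels)
  truth$area_discretized_mm2 <- purrr::map_dbl(truth$vertex_ids,
                                               ~ patch_area(painted, .x))
  fixture$mesh <- painted
  fixture$truth <- truth
  fixture
}

#' Derive the matched 2D film force record from fixture truth
#'
#' Emulates the pressure-film record for a painted fixture. Contact centers
#' are expressed in occlusal-frame coordinates, projected onto the occlusal
#' plane, mapped into native film axes (`u` toward patient-left, `v`
#' posterior: a -90 degree rotation of the plane coordinates, so the arch
#' reads as `v = f(u)`), transformed by the generating similarity, and
#' perturbed by optional Gaussian position jitter and multiplicative force
#' noise. Optional stray points (film-handling artifacts well off the arch)
#' can be appended for stray-removal testing.
#'
#' @param fixture A painted [paint_contacts()] fixture.
#' @param transform Generating [similarity2d()] applied on top of the film
#'   axis convention (identity by default).
#' @param sigma_pos_mm SD of film-position jitter, mm.
#' @param sigma_force_rel SD of multiplicative force noise.
#' @param n_stray Number of stray points to append.
#' @param stray_offset_mm How far off the arch stray points sit (default 15).
#' @param seed Integer seed.
#' @return A [force_map()]; attributes `"truth_ids"` (point id of each truth
#'   contact, in truth order) and `"stray_ids"`.
#' @export
derive_force_map <- function(fixture, transform = similarity2d(),
                             sigma_pos_mm = 0, sigma_force_rel = 0,
                             n_stray = 0, stray_offset_mm = 15, seed = 1) {
  stopifnot(inherits(fixture, "arch_fixture"))
  if (is.null(fixture$truth)) abort("fixture has no painted contacts (run paint_contacts first)")
  truth <- fixture$truth
  frame <- build_occlusal_frame(fixture$landmarks)
  ctr <- to_frame(cbind(truth$center_x, truth$center_y, truth$center_z), frame)
  proj <- project_to_plane(ctr)
  film0 <- cbind(proj[, 2], -proj[, 1])  # film axes: u = y, v = -x
  film <- apply_similarity(film0, transform)
  local_seed(seed, {
    if (sigma_pos_mm > 0) {
      film <- film + matrix(stats::rnorm(length(film), 0, sigma_pos_mm), ncol = 2)
    }
    force <- truth$force_N * (1 + if (sigma_force_rel > 0) {
      stats::rnorm(nrow(truth), 0, sigma_force_rel)
    } else 0)
    force <- pmax(force, 0)
    pts <- tibble(
      id = seq_len(nrow(truth)),
      u_mm = film[, 1], v_mm = film[, 2],
      area_mm2 = truth$area_discretized_mm2,
      force_N = force
    )
    stray_ids <- integer(0)
    if (n_stray > 0) {
      pick <- sample.int(nrow(pts), n_stray, replace = TRUE)
      ang <- stats::runif(n_stray, 0, 2 * pi)
      stray <- tibble(
        id = nrow(pts) + seq_len(n_stray),
        u_mm = pts$u_mm[pick] + stray_offset_mm * cos(ang),
        v_mm = pts$v_mm[pick] + stray_offset_mm * sin(ang),
        area_mm2 = stats::runif(n_stray, 0.2, 1),
        force_N = stats::runif(n_stray, 1, 5)
      )
      stray_ids <- stray$id
      pts <- dplyr::bind_rows(pts, stray)
    }
    out <- force_map(pts, film_size = "M", subject = "synthetic",
                     session = sprintf("seed%d", seed))
    attr(out, "truth_ids") <- seq_len(nrow(truth))
    attr(out, "stray_ids") <- stray_ids
    out
  })
}

#' One-call synthetic occlusion study
#'
#' Generates the arch, paints a contact plan, and derives the matched film
#' record; the single `seed` drives every random element.
#'
#' @param cfg An [arch_cfg()].
#' @param preset `"normal"` (first molar loaded most) or `"bruxism"`
#'   (second molar loaded most).
#' @param plan Optional explicit contact plan (overrides `preset`).
#' @param transform Generating film [similarity2d()].
#' @param sigma_pos_mm,sigma_force_rel,n_stray Noise settings for
#'   [derive_force_map()].
#' @param seed Integer master seed.
#' @return A list of class `occlusion_sim`: `fixture`, `truth`, `force_map`,
#'   `frame`, `transform`, `seed`.
#' @export
simulate_occlusion <- function(cfg = arch_cfg(), preset = c("normal", "bruxism"),
                               plan = NULL, transform = similarity2d(),
                               sigma_pos_mm = 0, sigma_force_rel = 0,
                               n_stray = 0, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(plan)) {
    plan <- if (preset == "bruxism") bruxism_contact_plan(cfg) else default_contact_plan(cfg)
  }
  fixture <- generate_arch_mesh(cfg, seed = seed)
  fixture <- paint_contacts(fixture, plan, seed = seed + 1L)
  fmap <- derive_force_map(fixture, transform = transform,
                           sigma_pos_mm = sigma_pos_mm,
                           sigma_force_rel = sigma_force_rel,
                           n_stray = n_stray, seed = seed + 2L)
  structure(list(fixture = fixture, truth = fixture$truth, force_map = fmap,
                 frame = build_occlusal_frame(fixture$landmarks),
                 transform = transform, seed = seed),
            class = "occlusion_sim")
}

#' @export
print.occlusion_sim <- function(x, ...) {
  print(x$fixture)
  cat(sprintf("  film record: %d points\n", nrow(x$force_map)))
  invisible(x)
}
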