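# Core force model: per-contact total-least-squares plane fit, force
# vectorization opposite the fitted normal, x/y/z decomposition, per-tooth
# and per-region aggregation, and projection onto arbitrary directions.

#' Total-least-squares plane fit to a contact patch
#'
#' Fits a plane to the patch's vertex positions (in occlusal-frame
#' coordinates) by total least squares: the plane passes through the
#' centroid with normal the eigenvector of the point covariance with
#' smallest eigenvalue. The normal is oriented into the upper (+z)
#' hemisphere so "opposite the normal" is well defined for a mandibular
#' contact. For near-vertical patches (|normal . z| < 0.05) that orientation
#' is ambiguous; the sign then follows `fallback_normal` (typically the mean
#' mesh vertex normal of the patch) and a warning is recorded.
#'
#' @param points n x 3 matrix of patch vertex positions, frame mm (n >= 3,
#'   non-collinear).
#' @param fallback_normal Optional length-3 orientation hint.
#' @return An object of class `plane_fit`: `center` (length-3), `normal`
#'   (unit length-3, `normal[3] >= 0` unless the fallback decided
#'   otherwise), `rms_residual_mm`, and `warning` (`NA` or a message).
#' @export
fit_contact_plane <- function(points, fallback_normal = NULL) {
  p <- as_matrix3(points, "points")
  if (nrow(p) < 3) abort("plane fit needs at least 3 points")
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  cov <- crossprod(pc) / nrow(p)
  eg <- eigen(cov, symmetric = TRUE)
  ev <- eg$values  # decreasing
  if (ev[2] < 1e-12) abort("degenerate patch: points are collinear (or coincident)")
  normal <- eg$vectors[, 3]
  warning_msg <- NA_character_
  if (abs(normal[3]) < 0.05) {
    if (!is.null(fallback_normal)) {
      if (sum(normal * fallback_normal) < 0) normal <- -normal
      warning_msg <- "near-vertical patch: normal oriented by mesh vertex normals"
    } else {
      if (normal[3] < 0) normal <- -normal
      warning_msg <- "near-vertical patch and no fallback normal: +z orientation is unreliable"
    }
  } else if (normal[3] < 0) {
    normal <- -normal
  }
  structure(
    list(center = ctr, normal = normal / sqrt(sum(normal^2)),
         rms_residual_mm = sqrt(max(ev[3], 0)), warning = warning_msg),
    class = "plane_fit"
  )
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> center (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f), RMS %.4g mm\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3], x$rms_residual_mm))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Occlusal force vector at one contact
#'
#' The force acts opposite the fitted plane normal (into the mandibular
#' tooth). The force indicator segment runs from the plane center (base) to
#' `base + magnitude * direction` (tip), using the glyph scale 1 N = 1 mm.
#' Components are the force vector's coordinates, `tip - base`, in newtons;
#' for an upward-oriented normal the vertical component `Fz` is negative.
#'
#' @param plane A [fit_contact_plane()] result.
#' @param magnitude_N Non-negative force magnitude in newtons.
#' @return One-row tibble: `magnitude_N`, `Fx`, `Fy`, `Fz`, `base_x/y/z`,
#'   `tip_x/y/z`, `plane_rms_mm`.
#' @export
force_vector <- function(plane, magnitude_N) {
  stopifnot(inherits(plane, "plane_fit"))
  if (!is.finite(magnitude_N) || magnitude_N < 0) abort("force magnitude must be >= 0")
  dir <- -plane$normal
  comp <- magnitude_N * dir
  tip <- plane$center + comp  # 1 N per mm glyph scale
  tibble(
    magnitude_N = magnitude_N,
    Fx = comp[1], Fy = comp[2], Fz = comp[3],
    base_x = plane$center[1], base_y = plane$center[2], base_z = plane$center[3],
    tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
    plane_rms_mm = plane$rms_residual_mm
  )
}

#' Per-contact force table for matched contacts
#'
#' For every matched patch/film-point pair: fit the contact plane to the
#' patch vertices in frame coordinates, take the film force magnitude, and
#' build the force vector. Patches fit with fewer than 3 vertices are
#' reported with `NA` components.
#'
#' @param mesh A labeled [colored_mesh()] (world coordinates).
#' @param patches Patch tibble from [extract_patches()].
#' @param matching A [match_contacts()] result.
#' @param map The (cleaned, transformed or original) [force_map()] whose
#'   `force_N` values supply magnitudes.
#' @param frame The [build_occlusal_frame()] frame.
#' @return Tibble, one row per matched contact: `patch_id`, `tooth`,
#'   `point_id`, `area_mm2`, `magnitude_N`, `Fx/Fy/Fz`, segment endpoints,
#'   `plane_rms_mm`, `plane_warning`.
#' @export
contact_forces <- function(mesh, patches, matching, map, frame) {
  stopifnot(inherits(matching, "contact_matching"))
  pts <- as_tibble(map)
  vn_world <- vertex_normals(mesh)
  vfr <- to_frame(mesh$vertices, frame)
  rows <- purrr::pmap(matching$pairs, function(patch_id, point_id, residual_mm) {
    patch <- patches[patches$patch_id == patch_id, ]
    vids <- patch$vertex_ids[[1]]
    magnitude <- pts$force_N[pts$id == point_id]
    fallback <- colMeans(vn_world[vids, , drop = FALSE]) %*% t(frame$axes)
    pl <- fit_contact_plane(vfr[vids, , drop = FALSE], fallback_normal = as.numeric(fallback))
    fv <- force_vector(pl, magnitude)
    dplyr::bind_cols(
      tibble(patch_id = patch_id, tooth = patch$tooth, point_id = point_id,
             area_mm2 = patch$area_mm2),
      fv,
      tibble(plane_warning = pl$warning)
    )
  })
  dplyr::bind_rows(rows)
}

#' Aggregate contact forces per tooth
#'
#' Vector-sums the x/y/z components of every contact on each tooth. Two
#' summaries are reported side by side: `resultant_N`, the norm of the
#' vector sum (opposing components cancel), and `sum_of_magnitudes_N`, the
#' scalar sum of contact force magnitudes (always >= resultant).
#'
#' @param forces Per-contact tibble from [contact_forces()] (needs `tooth`,
#'   `magnitude_N`, `Fx`, `Fy`, `Fz`; `area_mm2` optional).
#' @return Tibble, one row per tooth: `tooth`, `region`, `n_contacts`,
#'   `Fx`, `Fy`, `Fz`, `resultant_N`, `sum_of_magnitudes_N`, and `oca_mm2`
#'   when areas are available. Tooth 0 groups unassigned contacts.
#' @export
aggregate_by_tooth <- function(forces) {
  out <- forces |>
    dplyr::group_by(tooth = .data$tooth) |>
    dplyr::summarise(
      n_contacts = dplyr::n(),
      Fx = sum(.data$Fx), Fy = sum(.data$Fy), Fz = sum(.data$Fz),
      sum_of_magnitudes_N = sum(.data$magnitude_N),
      oca_mm2 = if ("area_mm2" %in% names(forces)) sum(.data$area_mm2) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      region = fdi_region(.data$tooth), .after = "tooth"
    ) |>
    dplyr::mutate(resultant_N = sqrt(.data$Fx^2 + .data$Fy^2 + .data$Fz^2),
                  .before = "sum_of_magnitudes_N") |>
    dplyr::arrange(.data$tooth)
  out
}

#' Project contact forces onto an arbitrary direction
#'
#' Scalar force along any clinical direction of interest (proximal-distal,
#' buccolingual, or any other unit direction in frame coordinates):
#' per-contact `dot((Fx, Fy, Fz), d)`, summed per group.
#'
#' @param forces Per-contact tibble from [contact_forces()].
#' @param direction Unit length-3 direction in frame coordinates (checked to
#'   1e-6; no silent normalization).
#' @param by Grouping: `"tooth"`, `"region"` or `"arch"`.
#' @return Tibble with the grouping column and `force_N` (signed sum).
#' @export
project_direction <- function(forces, direction, by = c("tooth", "region", "arch")) {
  by <- match.arg(by)
  d <- as.numeric(direction)
  if (length(d) != 3 || abs(sqrt(sum(d^2)) - 1) > 1e-6) {
    abort("direction must be a unit length-3 vector (no silent normalization)")
  }
  f <- dplyr::mutate(forces,
                     proj_N = .data$Fx * d[1] + .data$Fy * d[2] + .data$Fz * d[3],
                     region = fdi_region(.data$tooth))
  switch(by,
    tooth = f |> dplyr::group_by(tooth = .data$tooth) |>
      dplyr::summarise(force_N = sum(.data$proj_N), .groups = "drop"),
    region = f |> dplyr::group_by(region = .data$region) |>
      dplyr::summarise(force_N = sum(.data$proj_N), .groups = "drop"),
    arch = tibble(group = "arch", force_N = sum(f$proj_N))
  )
}

#' Regional force report with ordering evaluation
#'
#' Rolls tooth summaries up to anterior / premolar / molar regions and
#' evaluates the clinically expected loading gradient anterior < premolar <
#' molar (strict), on the regional resultant (norm of the regional vector
#' sum) and per axis on the summed unsigned components (left/right
#' components of opposite sign would otherwise cancel in a signed regional
#' sum).
#'
#' @param forces Per-contact tibble from [contact_forces()].
#' @return A list of class `regional_report`: `regions` (tibble `region`,
#'   `n_contacts`, `Fx`, `Fy`, `Fz` signed sums, `abs_Fx/abs_Fy/abs_Fz`
#'   unsigned sums, `resultant_N`, `sum_of_magnitudes_N`) and `ordering`
#'   (named logical: `resultant`, `x`, `y`, `z`).
#' @export
regional_comparison <- function(forces) {
  f <- dplyr::mutate(forces, region = fdi_region(.data$tooth))
  regions <- f |>
    dplyr::group_by(region = factor(.data$region, levels = region_levels())) |>
    dplyr::summarise(
      n_contacts = dplyr::n(),
      abs_Fx = sum(abs(.data$Fx)), abs_Fy = sum(abs(.data$Fy)),
      abs_Fz = sum(abs(.data$Fz)),
      Fx = sum(.data$Fx), Fy = sum(.data$Fy), Fz = sum(.data$Fz),
      sum_of_magnitudes_N = sum(.data$magnitude_N),
      .groups = "drop"
    ) |>
    tidyr::complete(region, fill = list(n_contacts = 0L, Fx = 0, Fy = 0, Fz = 0,
                                        abs_Fx = 0, abs_Fy = 0, abs_Fz = 0,
                                        sum_of_magnitudes_N = 0)) |>
    dplyr::mutate(resultant_N = sqrt(.data$Fx^2 + .data$Fy^2 + .data$Fz^2),
                  region = as.character(.data$region)) |>
    dplyr::filter(.data$region != "unassigned" | .data$n_contacts > 0)
  val <- function(col) {
    v <- regions[[col]][match(c("anterior", "premolar", "molar"), regions$region)]
    v[is.na(v)] <- 0
    v
  }
  inc <- function(v) v[1] < v[2] && v[2] < v[3]
  ordering <- c(resultant = inc(val("resultant_N")),
                x = inc(val("abs_Fx")), y = inc(val("abs_Fy")), z = inc(val("abs_Fz")))
  structure(list(regions = regions, ordering = ordering), class = "regional_report")
}

#' @export
print.regional_report <- function(x, ...) {
  cat("<regional_report>\n")
  print(x$regions)
  cat("anterior < premolar < molar:",
      paste(sprintf("%s=%s", names(x$ordering), x$ordering), collapse = ", "), "\n")
  invisible(x)
}

#' Export force indicator segments as OBJ line elements
#'
#' Writes one `l` (line) record per contact, base to tip, viewable in
#' standard mesh tools; glyph scale 1 N = 1 mm (configurable).
#'
#' @param forces Per-contact tibble from [contact_forces()].
#' @param path Output `.obj` path.
#' @param glyph_scale_mm_per_N Segment length per newton (default 1).
#' @return `path`, invisibly.
#' @export
write_force_glyphs <- function(forces, path, glyph_scale_mm_per_N = 1) {
  lines <- c("# occlusal force indicator segments (base -> tip), mm")
  if (nrow(forces) == 0) {
    writeLines(lines, path)
    return(invisible(path))
  }
  for (i in seq_len(nrow(forces))) {
    b <- c(forces$base_x[i], forces$base_y[i], forces$base_z[i])
    tip <- b + glyph_scale_mm_per_N *
      c(forces$Fx[i], forces$Fy[i], forces$Fz[i])
    lines <- c(lines,
               sprintf("v %.6f %.6f %.6f", b[1], b[2], b[3]),
               sprintf("v %.6f %.6f %.6f", tip[1], tip[2], tip[3]))
  }
  lines <- c(lines, sprintf("l %d %d", seq(1, 2 * nrow(forces), 2),
                            seq(2, 2 * nrow(forces), 2)))
  writeLines(lines, path)
  invisible(path)
}
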