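# Articulating-paper mark segmentation: color classification, connected
# contact patches, OCA/OCN metrics.

#' Mark-color configuration
#'
#' Describes which vertex colors count as articulating-paper marks. Two modes:
#' `"hsv"` keeps vertices whose hue falls within `hue_halfwidth_deg` of
#' `hue_center_deg` (circular) with saturation at least `min_saturation` —
#' robust against exposure differences because tooth base color is
#' near-achromatic; `"rgb_distance"` keeps vertices within `max_distance`
#' (Euclidean, 0-255 scale) of `rgb_ref`. Defaults describe red articulating
#' paper.
#'
#' @param mode `"hsv"` or `"rgb_distance"`.
#' @param hue_center_deg Mark hue center in degrees (red = 0).
#' @param hue_halfwidth_deg Accepted hue half-window, degrees.
#' @param min_saturation Minimum HSV saturation in \[0, 1\].
#' @param rgb_ref Reference RGB triple (0-255) for `"rgb_distance"`.
#' @param max_distance Maximum Euclidean RGB distance for `"rgb_distance"`.
#' @return A `mark_color` configuration list.
#' @export
mark_color <- function(mode = c("hsv", "rgb_distance"),
                       hue_center_deg = 0, hue_halfwidth_deg = 20,
                       min_saturation = 0.3,
                       rgb_ref = c(255, 0, 0), max_distance = 60) {
  mode <- match.arg(mode)
  structure(list(mode = mode, hue_center_deg = hue_center_deg,
                 hue_halfwidth_deg = hue_halfwidth_deg,
                 min_saturation = min_saturation,
                 rgb_ref = as.numeric(rgb_ref), max_distance = max_distance),
            class = "mark_color")
}

#' Classify articulating-paper-marked vertices by color
#'
#' Applies the configured color rule to every vertex and returns a logical
#' mask (`TRUE` = marked). Deterministic.
#'
#' @param mesh A [colored_mesh()] with colors.
#' @param color_cfg A [mark_color()] configuration.
#' @return Logical vector, one entry per vertex.
#' @export
classify_marked_vertices <- function(mesh, color_cfg = mark_color()) {
  if (is.null(mesh$colors)) abort("mesh has no vertex colors to classify")
  rgb <- mesh$colors
  if (color_cfg$mode == "hsv") {
    hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
    hue_deg <- hsv[1, ] * 360
    sat <- hsv[2, ]
    dh <- abs(((hue_deg - color_cfg$hue_center_deg + 180) %% 360) - 180)
    unname(dh <= color_cfg$hue_halfwidth_deg & sat >= color_cfg$min_saturation)
  } else {
    d2 <- (rgb[, 1] - color_cfg$rgb_ref[1])^2 + (rgb[, 2] - color_cfg$rgb_ref[2])^2 +
      (rgb[, 3] - color_cfg$rgb_ref[3])^2
    unname(d2 <= color_cfg$max_distance^2)
  }
}

#' Surface area of a vertex set on the mesh
#'
#' Area of a (partially) marked region using fractional triangle weighting:
#' each triangle contributes `area * m/3` where `m` is the number of its
#' vertices belonging to the set. A smooth estimator that converges to the
#' true region area under mesh refinement; triangle areas use the
#' cross-product formula.
#'
#' @param mesh A [colored_mesh()].
#' @param vertex_ids Integer vector of 1-based vertex indices.
#' @return Area in mm^2.
#' @export
patch_area <- function(mesh, vertex_ids) {
  member <- logical(nrow(mesh$vertices))
  member[vertex_ids] <- TRUE
  f <- mesh$faces
  m <- member[f[, 1]] + member[f[, 2]] + member[f[, 3]]
  touched <- m > 0
  if (!any(touched)) return(0)
  f <- f[touched, , drop = FALSE]
  v <- mesh$vertices
  areas <- triangle_areas(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                          v[f[, 3], , drop = FALSE])
  sum(areas * m[touched] / 3)
}

# Area-weighted centroid consistent with the m/3 area rule: each marked
# vertex is weighted by one third of the area of its incident triangles.
patch_centroid <- function(mesh, vertex_ids) {
  member <- logical(nrow(mesh$vertices))
  member[vertex_ids] <- TRUE
  f <- mesh$faces
  v <- mesh$vertices
  m <- member[f[, 1]] + member[f[, 2]] + member[f[, 3]]
  touched <- which(m > 0)
  w <- numeric(nrow(v))
  if (length(touched)) {
    ft <- f[touched, , drop = FALSE]
    areas <- triangle_areas(v[ft[, 1], , drop = FALSE], v[ft[, 2], , drop = FALSE],
                            v[ft[, 3], , drop = FALSE])
    for (k in 1:3) {
      idx <- ft[, k]
      keep <- member[idx]
      acc <- tapply(areas[keep] / 3, idx[keep], sum)
      ii <- as.integer(names(acc))
      w[ii] <- w[ii] + acc
    }
  }
  if (sum(w) == 0) return(colMeans(v[vertex_ids, , drop = FALSE]))
  colSums(v * w) / sum(w)
}

#' Extract connected contact patches from a marked-vertex mask
#'
#' Connected components of marked vertices under mesh vertex adjacency
#' (vertices sharing an edge), each kept if its area reaches `min_area_mm2`;
#' smaller components are discarded and reported in the `"discarded"`
#' attribute. Patch ids are assigned in descending area order, ties broken by
#' smallest member vertex index, so outputs are reproducible.
#'
#' @param mesh A [colored_mesh()].
#' @param mask Logical per-vertex mask from [classify_marked_vertices()].
#' @param min_area_mm2 Minimum patch area (default 0.05 mm^2, suppresses
#'   single-vertex color noise).
#' @return A tibble with one row per patch: `patch_id`, `tooth` (majority FDI
#'   label of the patch's vertices, 0 if unlabeled), `area_mm2`,
#'   `n_vertices`, `centroid_x/y/z`, and a `vertex_ids` list-column.
#'   Attribute `"discarded"` is a tibble of sub-threshold components.
#' @export
extract_patches <- function(mesh, mask, min_area_mm2 = 0.05) {
  stopifnot(length(mask) == nrow(mesh$vertices))
  empty <- tibble(patch_id = integer(), tooth = integer(), area_mm2 = numeric(),
                  n_vertices = integer(), centroid_x = numeric(),
                  centroid_y = numeric(), centroid_z = numeric(),
                  vertex_ids = list())
  discarded_empty <- tibble(area_mm2 = numeric(), n_vertices = integer())
  marked <- which(mask)
  if (length(marked) == 0) {
    attr(empty, "discarded") <- discarded_empty
    return(empty)
  }
  e <- mesh_edges(mesh)
  keep <- mask[e[, 1]] & mask[e[, 2]]
  e <- e[keep, , drop = FALSE]
  # relabel marked vertices 1..k for igraph; keep isolated marked vertices
  rel <- integer(nrow(mesh$vertices))
  rel[marked] <- seq_along(marked)
  g <- igraph::make_empty_graph(n = length(marked), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(cbind(rel[e[, 1]], rel[e[, 2]])))
  comp <- igraph::components(g)$membership
  groups <- split(marked, comp)

  rows <- purrr::map(groups, function(vids) {
    vids <- sort(vids)
    list(vertex_ids = vids, n_vertices = length(vids),
         area_mm2 = patch_area(mesh, vids),
         centroid = patch_centroid(mesh, vids))
  })
  areas <- purrr::map_dbl(rows, "area_mm2")
  keep_patch <- areas >= min_area_mm2
  discarded <- tibble(
    area_mm2 = areas[!keep_patch],
    n_vertices = purrr::map_int(rows[!keep_patch], "n_vertices")
  )
  rows <- rows[keep_patch]
  if (length(rows) == 0) {
    attr(empty, "discarded") <- discarded
    return(empty)
  }
  ord <- order(-purrr::map_dbl(rows, "area_mm2"),
               purrr::map_dbl(rows, ~ .x$vertex_ids[1]))
  rows <- rows[ord]
  tooth <- purrr::map_int(rows, function(r) {
    if (is.null(mesh$labels)) return(0L)
    tab <- table(mesh$labels[r$vertex_ids])
    as.integer(names(tab)[which.max(tab)])
  })
  out <- tibble(
    patch_id = seq_along(rows),
    tooth = tooth,
    area_mm2 = purrr::map_dbl(rows, "area_mm2"),
    n_vertices = purrr::map_int(rows, "n_vertices"),
    centroid_x = purrr::map_dbl(rows, ~ .x$centroid[1]),
    centroid_y = purrr::map_dbl(rows, ~ .x$centroid[2]),
    centroid_z = purrr::map_dbl(rows, ~ .x$centroid[3]),
    vertex_ids = purrr::map(rows, "vertex_ids")
  )
  attr(out, "discarded") <- discarded
  out
}

#' Occlusal contact metrics (OCA and OCN)
#'
#' Totals and per-tooth / per-region breakdown of occlusal contact area
#' (OCA, mm^2) and occlusal contact number (OCN) from extracted patches.
#' Regions follow [fdi_region()]: anterior, premolar, molar.
#'
#' @param patches Patch tibble from [extract_patches()].
#' @return A list of class `occlusal_metrics` with elements `oca_mm2`, `ocn`,
#'   `per_tooth` (tibble `tooth`, `region`, `oca_mm2`, `ocn`) and
#'   `per_region` (tibble `region`, `oca_mm2`, `ocn`).
#' @export
occlusal_metrics <- function(patches) {
  per_tooth <- patches |>
    dplyr::group_by(tooth = .data$tooth) |>
    dplyr::summarise(oca_mm2 = sum(.data$area_mm2), ocn = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(region = fdi_region(.data$tooth), .after = "tooth") |>
    dplyr::arrange(.data$tooth)
  per_region <- per_tooth |>
    dplyr::group_by(region = factor(.data$region, levels = region_levels())) |>
    dplyr::summarise(oca_mm2 = sum(.data$oca_mm2), ocn = sum(.data$ocn),
                     .groups = "drop") |>
    tidyr::complete(region, fill = list(oca_mm2 = 0, ocn = 0L)) |>
    dplyr::mutate(region = as.character(.data$region))
  structure(
    list(oca_mm2 = sum(patches$area_mm2), ocn = nrow(patches),
         per_tooth = per_tooth, per_region = per_region),
    class = "occlusal_metrics"
  )
}

#' @export
print.occlusal_metrics <- function(x, ...) {
  cat(sprintf("<occlusal_metrics> OCA = %.3f mm^2, OCN = %d\n", x$oca_mm2, x$ocn))
  print(x$per_region)
  invisible(x)
}

#' Recolor a mesh so each contact patch gets a distinct color
#'
#' Visual QC export: patch vertices are recolored with evenly spaced hues;
#' all other vertices keep their original color.
#'
#' @param mesh A [colored_mesh()].
#' @param patches Patch tibble from [extract_patches()].
#' @return A recolored [colored_mesh()].
#' @export
recolor_patches <- function(mesh, patches) {
  cols <- mesh$colors
  if (nrow(patches) > 0) {
    hues <- (seq_len(nrow(patches)) - 1) / nrow(patches)
    pal <- t(grDevices::col2rgb(grDevices::hsv(hues, 1, 1)))
    for (i in seq_len(nrow(patches))) {
      cols[patches$vertex_ids[[i]], ] <- matrix(pal[i, ], nrow = length(patches$vertex_ids[[i]]),
                                                ncol = 3, byrow = TRUE)
    }
  }
  colored_mesh(mesh$vertices, mesh$faces, cols, mesh$labels)
}
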