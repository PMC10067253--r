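# 2D pressure-film force record: load/validate, stray-point cleanup along the
# dental arch, and summary totals. Forces in newtons are taken as given (film
# colorimetry-to-force calibration happens upstream in the vendor analyzer).

#' Construct a 2D pressure-film force map
#'
#' One row per occlusal contact point on the film plane: position (`u_mm`,
#' `v_mm`), contact area (`area_mm2`) and force (`force_N`).
#'
#' @param points Data frame with columns `id`, `u_mm`, `v_mm`, `area_mm2`,
#'   `force_N`.
#' @param film_size Film size code (`"S"`, `"M"`, `"L"`) or `NA`.
#' @param subject,session Optional metadata strings.
#' @return A tibble of class `force_map` with metadata attributes.
#' @export
force_map <- function(points, film_size = NA_character_, subject = NA_character_,
                      session = NA_character_) {
  pts <- as_tibble(points)
  need <- c("id", "u_mm", "v_mm", "area_mm2", "force_N")
  missing <- setdiff(need, names(pts))
  if (length(missing)) {
    abort(sprintf("force map lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  pts <- pts[need]
  pts$id <- as.integer(pts$id)
  if (anyDuplicated(pts$id)) {
    abort(sprintf("duplicate point id(s): %s",
                  paste(unique(pts$id[duplicated(pts$id)]), collapse = ", ")))
  }
  for (col in c("u_mm", "v_mm", "area_mm2", "force_N")) {
    if (any(!is.finite(pts[[col]]))) {
      abort(sprintf("non-finite %s in row %d", col, which(!is.finite(pts[[col]]))[1]))
    }
  }
  bad <- pts$force_N < 0 | pts$area_mm2 < 0
  if (any(bad)) {
    abort(sprintf("negative force or area in row %d (id %d)",
                  which(bad)[1], pts$id[which(bad)[1]]))
  }
  structure(pts, class = c("force_map", class(tibble())),
            film_size = film_size, subject = subject, session = session)
}

#' Read a force map from CSV or JSON
#'
#' CSV needs header `id,u_mm,v_mm,area_mm2,force_N` (comma-separated, decimal
#' point, UTF-8); JSON mirrors the schema as
#' `{"film_size": ..., "points": [{...}, ...]}` or a bare array of points.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A [force_map()].
#' @export
read_force_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(j)) return(force_map(j))
    force_map(as_tibble(j$points), film_size = j$film_size %||% NA_character_,
              subject = j$subject %||% NA_character_,
              session = j$session %||% NA_character_)
  } else {
    pts <- readr::read_csv(path, show_col_types = FALSE)
    force_map(pts)
  }
}

#' Write a force map to CSV
#' @param map A [force_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_map <- function(map, path) {
  readr::write_csv(as_tibble(map)[c("id", "u_mm", "v_mm", "area_mm2", "force_N")], path)
  invisible(path)
}

#' Remove stray film points that are significantly off the dental arch
#'
#' Stray dye points (handling artifacts, film creases) lie far from the
#' dental arch. A quadratic arch curve `v = a u^2 + b u + c` is fitted to the
#' point positions by least squares with one reweighting round: points whose
#' absolute residual exceeds twice the median absolute residual are dropped
#' from a refit. Points whose perpendicular distance to the final curve
#' (local linearization `|v - f(u)| / sqrt(1 + f'(u)^2)`) exceeds
#' `max_arch_distance_mm` are removed. Ids in `manual_exclude` are always
#' removed, mirroring a manual workflow. With fewer than 6 points the arch
#' cannot be fitted robustly and the map passes through with a warning.
#'
#' @param map A [force_map()].
#' @param max_arch_distance_mm Removal threshold in mm (default 5).
#' @param manual_exclude Integer ids to remove unconditionally.
#' @return The cleaned [force_map()]; removed points are attached as the
#'   `"removed"` attribute (tibble with a `reason` column).
#' @export
remove_stray_points <- function(map, max_arch_distance_mm = 5,
                                manual_exclude = integer()) {
  pts <- as_tibble(map)
  manual <- pts$id %in% manual_exclude
  pts_fit <- pts[!manual, , drop = FALSE]
  if (nrow(pts_fit) < 6) {
    if (nrow(pts_fit) > 0) {
      warn(sprintf("only %d points: arch fit skipped, no stray removal", nrow(pts_fit)))
    }
    stray <- rep(FALSE, nrow(pts_fit))
  } else {
    fit <- stats::lm(v_mm ~ u_mm + I(u_mm^2), data = pts_fit)
    res <- abs(stats::resid(fit))
    madr <- stats::median(res)
    w <- as.numeric(res <= 2 * madr)
    if (madr > 0 && any(w == 0) && sum(w) >= 3) {
      fit <- stats::lm(v_mm ~ u_mm + I(u_mm^2), data = pts_fit, weights = w)
    }
    cf <- stats::coef(fit)  # intercept, b, a
    fu <- cf[1] + cf[2] * pts_fit$u_mm + cf[3] * pts_fit$u_mm^2
    slope <- cf[2] + 2 * cf[3] * pts_fit$u_mm
    dist <- abs(pts_fit$v_mm - fu) / sqrt(1 + slope^2)
    stray <- dist > max_arch_distance_mm
  }
  removed <- dplyr::bind_rows(
    dplyr::mutate(pts[manual, , drop = FALSE], reason = "manual_exclude"),
    dplyr::mutate(pts_fit[stray, , drop = FALSE], reason = "off_arch")
  )
  kept <- pts_fit[!stray, , drop = FALSE]
  out <- force_map(kept, film_size = attr(map, "film_size"),
                   subject = attr(map, "subject"), session = attr(map, "session"))
  attr(out, "removed") <- removed
  out
}

#' Summary totals of a force map
#'
#' @param map A [force_map()].
#' @return A one-row tibble: `oca_mm2` (sum of contact areas), `ocn` (point
#'   count), `total_force_N` (sum of forces).
#' @export
map_totals <- function(map) {
  pts <- as_tibble(map)
  tibble(oca_mm2 = sum(pts$area_mm2), ocn = nrow(pts),
         total_force_N = sum(pts$force_N))
}
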