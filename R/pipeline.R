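# End-to-end orchestration: segment -> frame -> register -> match ->
# fit/force -> aggregate -> report, with a config object, a run log and
# deterministic report files.

#' Pipeline configuration
#'
#' Collects input paths (or in-memory objects), module settings and the
#' seed. Every threshold used anywhere in the pipeline surfaces here;
#' nothing is hard-coded downstream.
#'
#' @param mesh Path to a colored PLY mesh, or a [colored_mesh()].
#' @param landmarks Path to a landmarks JSON, or a [landmark_set()].
#' @param force_map Path to a film CSV/JSON, or a [force_map()].
#' @param labels Optional labels sidecar path (ignored when the mesh already
#'   carries labels).
#' @param correspondences Optional data frame / CSV / JSON with `patch_id`,
#'   `point_id` pairs used to estimate the film-to-plane transform.
#' @param transform Optional explicit [similarity2d()] mapping film
#'   coordinates to occlusal-plane coordinates (overrides estimation).
#' @param out_dir Output directory for report files (`NULL` = no files).
#' @param mark_color A [mark_color()] configuration.
#' @param min_area_mm2 Patch area threshold, mm^2.
#' @param max_arch_distance_mm Stray-point removal threshold, mm.
#' @param manual_exclude Film point ids to drop unconditionally.
#' @param max_match_distance_mm Contact-matching distance cutoff, mm.
#' @param glyph_scale_mm_per_N Force-glyph scale for the OBJ export.
#' @param seed Integer seed recorded in the run log.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mesh, landmarks, force_map, labels = NULL,
                            correspondences = NULL, transform = NULL,
                            out_dir = NULL,
                            mark_color = occlusal3d::mark_color(),
                            min_area_mm2 = 0.05,
                            max_arch_distance_mm = 5,
                            manual_exclude = integer(),
                            max_match_distance_mm = 2,
                            glyph_scale_mm_per_N = 1,
                            seed = 1L) {
  structure(list(mesh = mesh, landmarks = landmarks, force_map = force_map,
                 labels = labels, correspondences = correspondences,
                 transform = transform, out_dir = out_dir,
                 mark_color = mark_color, min_area_mm2 = min_area_mm2,
                 max_arch_distance_mm = max_arch_distance_mm,
                 manual_exclude = manual_exclude,
                 max_match_distance_mm = max_match_distance_mm,
                 glyph_scale_mm_per_N = glyph_scale_mm_per_N,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File keys mirror the [pipeline_config()] arguments; `mark_color` is a
#' nested map (`mode`, `hue_center_deg`, ...), `transform` a map with
#' `scale`, `theta_deg`, `t_mm`. Relative paths resolve against the config
#' file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  mc <- if (is.null(raw$mark_color)) mark_color() else {
    do.call(mark_color, raw$mark_color)
  }
  tf <- if (is.null(raw$transform)) NULL else {
    similarity2d(raw$transform$scale %||% 1, raw$transform$theta_deg %||% 0,
                 raw$transform$t_mm %||% c(0, 0))
  }
  pipeline_config(
    mesh = resolve(raw$mesh), landmarks = resolve(raw$landmarks),
    force_map = resolve(raw$force_map), labels = resolve(raw$labels),
    correspondences = resolve(raw$correspondences), transform = tf,
    out_dir = raw$out_dir,
    mark_color = mc,
    min_area_mm2 = raw$min_area_mm2 %||% 0.05,
    max_arch_distance_mm = raw$max_arch_distance_mm %||% 5,
    manual_exclude = raw$manual_exclude %||% integer(),
    max_match_distance_mm = raw$max_match_distance_mm %||% 2,
    glyph_scale_mm_per_N = raw$glyph_scale_mm_per_N %||% 1,
    seed = raw$seed %||% 1L
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full occlusal analysis pipeline
#'
#' Executes segmentation, frame construction, film registration, contact
#' matching, per-contact plane fitting and force vectorization, per-tooth
#' and regional aggregation; optionally writes the report bundle (CSV/JSON
#' tables, force-glyph OBJ, run log) to `config$out_dir`. Unmatched patches
#' and film points are listed in the matching report and excluded from force
#' sums, never silently dropped.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `occlusal_run`: `metrics` (SA occlusal metrics),
#'   `map_totals` (film totals after cleaning), `patches`, `frame`,
#'   `transform`, `matching`, `forces`, `per_tooth`, `regional`, `config`,
#'   and `paths` of any files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  mesh <- run_stage("mesh_io", {
    m <- if (is.character(config$mesh)) read_ply_mesh(config$mesh) else config$mesh
    if (!is.null(config$labels) && is.null(m$labels)) {
      m <- read_tooth_labels(m, config$labels)
    }
    m
  })
  landmarks <- run_stage("mesh_io", {
    if (is.character(config$landmarks)) read_landmarks(config$landmarks) else config$landmarks
  })
  frame <- run_stage("occlusal_frame", build_occlusal_frame(landmarks))
  patches <- run_stage("contact_segmentation", {
    mask <- classify_marked_vertices(mesh, config$mark_color)
    extract_patches(mesh, mask, min_area_mm2 = config$min_area_mm2)
  })
  metrics <- run_stage("contact_segmentation", occlusal_metrics(patches))
  fmap_raw <- run_stage("pressure_map", {
    if (is.character(config$force_map)) read_force_map(config$force_map) else config$force_map
  })

  # projected patch centroids in the occlusal plane
  proj <- run_stage("occlusal_frame", {
    xy <- project_to_plane(to_frame(
      cbind(patches$centroid_x, patches$centroid_y, patches$centroid_z), frame))
    tibble(patch_id = patches$patch_id, x = xy[, 1], y = xy[, 2])
  })
  transform <- run_stage("registration_matching", {
    if (!is.null(config$transform)) {
      config$transform
    } else if (!is.null(config$correspondences)) {
      co <- config$correspondences
      if (is.character(co)) {
        co <- if (grepl("\\.json$", co, ignore.case = TRUE)) {
          as_tibble(jsonlite::read_json(co, simplifyVector = TRUE))
        } else readr::read_csv(co, show_col_types = FALSE)
      }
      pts <- as_tibble(fmap_raw)
      src <- cbind(pts$u_mm[match(co$point_id, pts$id)],
                   pts$v_mm[match(co$point_id, pts$id)])
      dst <- cbind(proj$x[match(co$patch_id, proj$patch_id)],
                   proj$y[match(co$patch_id, proj$patch_id)])
      estimate_similarity(src, dst)
    } else {
      abort("either 'transform' or 'correspondences' must be provided")
    }
  })
  # Stray removal happens in arch-aligned occlusal-plane coordinates (u
  # toward patient-left, v posterior: there the arch reads as v = f(u)
  # regardless of how the film was oriented during scanning); the standalone
  # remove_stray_points() contract on native film coordinates is unchanged.
  fmap <- run_stage("pressure_map", {
    pts <- as_tibble(fmap_raw)
    xy <- apply_similarity(cbind(pts$u_mm, pts$v_mm), transform)
    aligned <- force_map(tibble(id = pts$id, u_mm = xy[, 2], v_mm = -xy[, 1],
                                area_mm2 = pts$area_mm2, force_N = pts$force_N))
    cleaned <- remove_stray_points(aligned,
                                   max_arch_distance_mm = config$max_arch_distance_mm,
                                   manual_exclude = config$manual_exclude)
    keep <- as_tibble(fmap_raw)[pts$id %in% cleaned$id, , drop = FALSE]
    out <- force_map(keep, film_size = attr(fmap_raw, "film_size"),
                     subject = attr(fmap_raw, "subject"),
                     session = attr(fmap_raw, "session"))
    attr(out, "removed") <- attr(cleaned, "removed")
    out
  })
  matching <- run_stage("registration_matching", {
    pts <- as_tibble(fmap)
    uv <- apply_similarity(cbind(pts$u_mm, pts$v_mm), transform)
    match_contacts(proj, tibble(point_id = pts$id, x = uv[, 1], y = uv[, 2]),
                   max_match_distance_mm = config$max_match_distance_mm)
  })
  forces <- run_stage("force_model", contact_forces(mesh, patches, matching, fmap, frame))
  per_tooth <- run_stage("force_model", aggregate_by_tooth(forces))
  regional <- run_stage("force_model", regional_comparison(forces))

  result <- structure(
    list(metrics = metrics, map_totals = map_totals(fmap), patches = patches,
         frame = frame, transform = transform, matching = matching,
         forces = forces, per_tooth = per_tooth, regional = regional,
         config = config, paths = character()),
    class = "occlusal_run"
  )
  if (!is.null(config$out_dir)) {
    result$paths <- run_stage("cli_reporting", write_report_bundle(result, config$out_dir))
  }
  result
}

#' @export
print.occlusal_run <- function(x, ...) {
  cat(sprintf("<occlusal_run> OCA %.3f mm^2, OCN %d, %d matched contacts, total force %.1f N\n",
              x$metrics$oca_mm2, x$metrics$ocn, nrow(x$forces), sum(x$forces$magnitude_N)))
  print(x$regional)
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write the report bundle of a pipeline run
#'
#' Writes per-contact and per-tooth CSV/JSON reports, the matching report
#' with unmatched lists, occlusal metrics JSON, the force-glyph OBJ and a
#' run log recording package version, seed, thresholds and the config hash.
#' All files are written deterministically (no timestamps), so identical
#' runs produce byte-identical bundles.
#'
#' @param run An [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    contacts = p("contact_forces.csv"), per_tooth = p("per_tooth.csv"),
    per_tooth_json = p("per_tooth.json"), regional = p("regional.json"),
    matching = p("matching.csv"), unmatched = p("unmatched.json"),
    metrics = p("occlusal_metrics.json"), patches = p("patches.csv"),
    glyphs = p("force_glyphs.obj"), log = p("run_log.txt")
  )
  readr::write_csv(dplyr::select(run$forces, -dplyr::any_of("plane_warning")) |>
                     dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 9))),
                   paths["contacts"])
  readr::write_csv(dplyr::mutate(run$per_tooth,
                                 dplyr::across(dplyr::where(is.numeric), ~ round(.x, 9))),
                   paths["per_tooth"])
  jsonlite::write_json(run$per_tooth, paths["per_tooth_json"], digits = 9, dataframe = "rows")
  jsonlite::write_json(list(regions = run$regional$regions,
                            ordering = as.list(run$regional$ordering)),
                       paths["regional"], digits = 9, auto_unbox = TRUE)
  readr::write_csv(run$matching$pairs, paths["matching"])
  jsonlite::write_json(list(unmatched_patches = run$matching$unmatched_patches,
                            unmatched_points = run$matching$unmatched_points),
                       paths["unmatched"])
  jsonlite::write_json(list(oca_mm2 = run$metrics$oca_mm2, ocn = run$metrics$ocn,
                            per_tooth = run$metrics$per_tooth,
                            per_region = run$metrics$per_region,
                            film = run$map_totals),
                       paths["metrics"], digits = 9, auto_unbox = TRUE)
  readr::write_csv(dplyr::select(run$patches, -"vertex_ids") |>
                     dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 9))),
                   paths["patches"])
  write_force_glyphs(run$forces, paths["glyphs"], run$config$glyph_scale_mm_per_N)
  cfg <- run$config
  log_lines <- c(
    sprintf("occlusal3d %s", as.character(utils::packageVersion("occlusal3d"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", rlang::hash(cfg[setdiff(names(cfg), "out_dir")])),
    sprintf("mark_color: mode=%s hue_center=%g halfwidth=%g min_sat=%g",
            cfg$mark_color$mode, cfg$mark_color$hue_center_deg,
            cfg$mark_color$hue_halfwidth_deg, cfg$mark_color$min_saturation),
    sprintf("min_area_mm2: %g", cfg$min_area_mm2),
    sprintf("max_arch_distance_mm: %g", cfg$max_arch_distance_mm),
    sprintf("max_match_distance_mm: %g", cfg$max_match_distance_mm),
    sprintf("glyph_scale_mm_per_N: %g", cfg$glyph_scale_mm_per_N),
    sprintf("transform: s=%s theta_deg=%s t=(%s, %s)",
            fmt_num(run$transform$scale), fmt_num(run$transform$theta * 180 / pi),
            fmt_num(run$transform$t[1]), fmt_num(run$transform$t[2])),
    sprintf("n_patches: %d  n_film_points: %d  n_matched: %d",
            nrow(run$patches), run$map_totals$ocn, nrow(run$matching$pairs))
  )
  writeLines(log_lines, paths["log"])
  invisible(paths)
}
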