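# Sidecar files: tooth-label JSON and anatomical landmark JSON. Labels live
# beside the scan export so third-party PLY files need no modification.

#' Attach FDI tooth labels from a sidecar JSON file
#'
#' The sidecar maps FDI tooth codes to inclusive 0-based vertex-index ranges,
#' `{"31": [[0, 99]], "32": [[100, 149], [180, 185]]}`, or carries a full
#' per-vertex array `{"per_vertex": [0, 31, 31, ...]}`. Unlisted vertices get
#' label 0 (non-tooth/unlabeled).
#'
#' @param mesh A [colored_mesh()].
#' @param path Path to the labels JSON sidecar.
#' @return The mesh with `labels` attached.
#' @export
read_tooth_labels <- function(mesh, path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- nrow(mesh$vertices)
  if (!is.null(spec$per_vertex)) {
    labels <- as.integer(spec$per_vertex)
    if (length(labels) != n) {
      abort(sprintf("per_vertex labels length %d does not match %d vertices",
                    length(labels), n))
    }
  } else {
    labels <- integer(n)
    for (code_chr in names(spec)) {
      code <- suppressWarnings(as.integer(code_chr))
      if (is.na(code) || !is_valid_fdi(code) || code == 0L) {
        abort(sprintf("invalid FDI code in labels sidecar: '%s'", code_chr))
      }
      ranges <- spec[[code_chr]]
      if (is.vector(ranges) && !is.list(ranges) && length(ranges) == 2) {
        ranges <- matrix(ranges, 1)
      }
      ranges <- as.matrix(ranges)
      for (i in seq_len(nrow(ranges))) {
        lo <- as.integer(ranges[i, 1]); hi <- as.integer(ranges[i, 2])
        if (lo < 0L || hi >= n || lo > hi) {
          abort(sprintf("label range [%d, %d] for tooth %s out of vertex range [0, %d]",
                        lo, hi, code_chr, n - 1L))
        }
        labels[(lo + 1L):(hi + 1L)] <- code
      }
    }
  }
  colored_mesh(mesh$vertices, mesh$faces, mesh$colors, labels)
}

#' Construct an anatomical landmark set for the occlusal frame
#'
#' Three landmarks define the mandibular occlusal plane: the midpoint between
#' the mesial line angles of the central incisors (the frame origin) and the
#' distobuccal cusp apexes of the left and right last molars. An optional
#' superior reference point (any point toward the maxilla) enables a
#' left/right swap check when the frame is built.
#'
#' @param incisor_midpoint,db_cusp_left,db_cusp_right Numeric length-3 points
#'   in mesh/world millimetres.
#' @param superior_ref Optional length-3 point on the maxillary side.
#' @return An object of class `landmark_set`.
#' @examples
#' landmark_set(c(0, 0, 0), c(-40, 25, 0), c(-40, -25, 0))
#' @export
landmark_set <- function(incisor_midpoint, db_cusp_left, db_cusp_right,
                         superior_ref = NULL) {
  pts <- list(incisor_midpoint = incisor_midpoint, db_cusp_left = db_cusp_left,
              db_cusp_right = db_cusp_right)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3 || any(!is.finite(p))) {
      abort(sprintf("landmark '%s' must be a finite length-3 point", nm))
    }
    pts[[nm]] <- p
  }
  # non-collinearity: triangle area above tolerance
  a <- 0.5 * sqrt(sum(cross3(pts$db_cusp_left - pts$incisor_midpoint,
                             pts$db_cusp_right - pts$incisor_midpoint)^2))
  if (a < 1e-6) abort("landmarks are collinear (occlusal-plane triangle area < 1e-6 mm^2)")
  if (!is.null(superior_ref)) {
    superior_ref <- as.numeric(superior_ref)
    if (length(superior_ref) != 3) abort("superior_ref must be a length-3 point")
  }
  structure(c(pts, list(superior_ref = superior_ref)), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in c("incisor_midpoint", "db_cusp_left", "db_cusp_right")) {
    cat(sprintf("  %-17s (%.3f, %.3f, %.3f) mm\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  if (!is.null(x$superior_ref)) cat("  + superior_ref\n")
  invisible(x)
}

#' Read landmarks from a JSON sidecar
#'
#' Expects `{"incisor_midpoint": [x,y,z], "db_cusp_left": [...],
#' "db_cusp_right": [...]}` with an optional `"superior_ref"`, all in
#' mesh/world millimetres.
#'
#' @param path Path to the landmarks JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("incisor_midpoint", "db_cusp_left", "db_cusp_right")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    abort(sprintf("landmarks file lacks: %s", paste(missing, collapse = ", ")))
  }
  landmark_set(j$incisor_midpoint, j$db_cusp_left, j$db_cusp_right, j$superior_ref)
}

#' Write landmarks to a JSON sidecar
#' @param landmarks A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- landmarks[c("incisor_midpoint", "db_cusp_left", "db_cusp_right")]
  if (!is.null(landmarks$superior_ref)) obj$superior_ref <- landmarks$superior_ref
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
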