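# Anatomical occlusal coordinate frame: origin at the incisor midpoint, x-y
# plane through the origin and the distobuccal cusps of the last molars
# (the mandibular occlusal plane), x anterior, y patient-left, z upward
# (toward the maxilla).

#' Build the occlusal coordinate frame from anatomical landmarks
#'
#' Constructs a right-handed orthonormal frame: origin at the incisor
#' midpoint; y-axis along the line from the right to the left last-molar
#' distobuccal cusp (positive toward patient-left); z-axis normal to the
#' plane through the three landmarks, signed so that x = y x z points
#' anteriorly (from the molar line toward the incisors); the occlusal plane
#' is z = 0. With anatomically correct left/right labels this leaves z
#' pointing upward (toward the maxilla). If the landmarks carry a
#' `superior_ref` point, a swapped left/right labeling (which would flip z
#' downward) is detected and raised as an error.
#'
#' @param landmarks A [landmark_set()].
#' @return An object of class `occlusal_frame` with `origin` (length-3) and
#'   `axes` (3 x 3 rotation matrix; rows are the x, y, z unit vectors).
#' @examples
#' lm <- landmark_set(c(0, 0, 0), c(-40, 25, 0), c(-40, -25, 0))
#' build_occlusal_frame(lm)
#' @export
build_occlusal_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  o <- landmarks$incisor_midpoint
  l <- landmarks$db_cusp_left
  r <- landmarks$db_cusp_right
  yhat <- unitize(l - r)
  n <- cross3(l - o, r - o)
  if (sqrt(sum(n^2)) < 2e-6) abort("landmarks are collinear; cannot define the occlusal plane")
  nhat <- unitize(n)
  xhat <- cross3(yhat, nhat)
  # x must point anteriorly: from the molar-line midpoint toward the origin
  mid <- (l + r) / 2
  if (sum(xhat * (o - mid)) < 0) {
    nhat <- -nhat
    xhat <- -xhat
  }
  zhat <- cross3(xhat, yhat)
  if (!is.null(landmarks$superior_ref)) {
    if (sum(zhat * (landmarks$superior_ref - o)) < 0) {
      abort("left/right landmarks likely swapped: frame z-axis points away from the superior reference")
    }
  }
  axes <- rbind(x = xhat, y = yhat, z = zhat)
  structure(list(origin = o, axes = axes), class = "occlusal_frame")
}

#' @export
print.occlusal_frame <- function(x, ...) {
  cat("<occlusal_frame>\n  origin:",
      sprintf("(%.3f, %.3f, %.3f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  ax <- format(round(x$axes, 6))
  for (i in 1:3) {
    cat(sprintf("  %s-axis: (%s, %s, %s)\n", rownames(x$axes)[i],
                ax[i, 1], ax[i, 2], ax[i, 3]))
  }
  invisible(x)
}

#' Transform world points into occlusal-frame coordinates
#'
#' Applies `p' = A (p - origin)` with the frame's rotation `A`. In the
#' result, the occlusal plane is `z = 0`, x is anterior, y patient-left, z
#' upward.
#'
#' @param points Numeric matrix or data frame, n x 3, world mm; a single
#'   length-3 point is also accepted.
#' @param frame An [build_occlusal_frame()] result.
#' @return An n x 3 matrix of frame coordinates.
#' @export
to_frame <- function(points, frame) {
  stopifnot(inherits(frame, "occlusal_frame"))
  single <- is.null(dim(points)) && length(points) == 3
  p <- if (single) matrix(points, 1) else as_matrix3(points, "points")
  out <- sweep(p, 2, frame$origin) %*% t(frame$axes)
  colnames(out) <- c("x", "y", "z")
  if (single) out[1, ] else out
}

#' Transform occlusal-frame points back to world coordinates
#' @inheritParams to_frame
#' @return An n x 3 matrix of world coordinates.
#' @export
from_frame <- function(points, frame) {
  stopifnot(inherits(frame, "occlusal_frame"))
  single <- is.null(dim(points)) && length(points) == 3
  p <- if (single) matrix(points, 1) else as_matrix3(points, "points")
  out <- sweep(p %*% frame$axes, 2, frame$origin, `+`)
  colnames(out) <- c("x", "y", "z")
  if (single) out[1, ] else out
}

#' Orthographic projection onto the occlusal plane
#'
#' For points already in occlusal-frame coordinates, drops the z coordinate.
#' This replaces the screenshot-based 2D view of the occlusal surface: an
#' orthographic projection along -z. Distances and areas of geometry lying in
#' the occlusal plane are preserved exactly.
#'
#' @param points n x 3 matrix of frame coordinates (or a length-3 point).
#' @return n x 2 matrix (columns `x`, `y`).
#' @export
project_to_plane <- function(points) {
  single <- is.null(dim(points)) && length(points) == 3
  p <- if (single) matrix(points, 1) else as_matrix3(points, "points")
  out <- p[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  if (single) out[1, ] else out
}

#' Export / import an occlusal frame as JSON
#' @param frame An `occlusal_frame`.
#' @param path JSON path.
#' @return `path` invisibly (write); an `occlusal_frame` (read).
#' @export
write_frame <- function(frame, path) {
  jsonlite::write_json(list(origin = frame$origin,
                            axes = apply(frame$axes, 1, identity, simplify = FALSE)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- if (is.list(j$axes)) do.call(rbind, j$axes) else matrix(unlist(j$axes), 3, byrow = TRUE)
  rownames(axes) <- c("x", "y", "z")
  # re-validate orthonormality on import
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-6) abort("frame axes are not orthonormal")
  structure(list(origin = as.numeric(j$origin), axes = axes), class = "occlusal_frame")
}
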