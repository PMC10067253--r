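#' Construct a colored dental-surface mesh
#'
#' A `colored_mesh` is a triangulated surface in millimetres with optional
#' per-vertex RGB colors (0-255, e.g. articulating-paper marks captured by an
#' intraoral scanner) and optional per-vertex FDI tooth labels (mandible:
#' 31-38, 41-48; 0 = non-tooth/unlabeled).
#'
#' @param vertices Numeric matrix or data frame, n x 3 (x, y, z in mm).
#' @param faces Integer matrix or data frame, m x 3, 1-based vertex indices.
#' @param colors Optional n x 3 integer matrix of RGB values in 0-255.
#' @param labels Optional integer vector of length n of FDI codes (0 allowed).
#' @return An object of class `colored_mesh`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' f <- rbind(c(1, 2, 3), c(2, 4, 3))
#' m <- colored_mesh(v, f, colors = matrix(255L, 4, 3))
#' m
#' @export
colored_mesh <- function(vertices, faces, colors = NULL, labels = NULL) {
  vertices <- as_matrix3(vertices, "vertices")
  faces <- as_matrix3(faces, "faces")
  storage.mode(faces) <- "integer"
  n <- nrow(vertices)
  if (nrow(faces) > 0) {
    if (any(faces < 1L) || any(faces > n)) {
      bad <- which(rowSums(faces < 1L | faces > n) > 0)[1]
      abort(sprintf("face %d references a vertex index out of range [1, %d]", bad, n))
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
    if (any(degen)) {
      abort(sprintf("face %d is degenerate (repeated vertex index)", which(degen)[1]))
    }
  }
  if (!is.null(colors)) {
    colors <- as_matrix3(colors, "colors")
    storage.mode(colors) <- "integer"
    if (nrow(colors) != n) abort("colors must have one row per vertex")
    if (any(colors < 0L) || any(colors > 255L)) abort("colors must be in [0, 255]")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) abort("labels must have one entry per vertex")
    bad <- !is_valid_fdi(labels)
    if (any(bad)) {
      abort(sprintf("invalid FDI code(s) in labels: %s",
                    paste(unique(labels[bad]), collapse = ", ")))
    }
  }
  structure(
    list(vertices = vertices, faces = faces, colors = colors, labels = labels),
    class = "colored_mesh"
  )
}

#' @export
print.colored_mesh <- function(x, ...) {
  cat(sprintf("<colored_mesh> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) ", no colors" else ", RGB colors",
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled teeth", length(setdiff(unique(x$labels), 0L)))))
  invisible(x)
}

#' Tidy views of a mesh
#'
#' `as_tibble()` on a `colored_mesh` returns one row per vertex with columns
#' `vertex` (1-based index), `x`, `y`, `z`, and when present `r`, `g`, `b`
#' and `tooth`.
#'
#' @param x A `colored_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per vertex.
#' @export
as_tibble.colored_mesh <- function(x, ...) {
  out <- tibble(
    vertex = seq_len(nrow(x$vertices)),
    x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3]
  )
  if (!is.null(x$colors)) {
    out$r <- x$colors[, 1]; out$g <- x$colors[, 2]; out$b <- x$colors[, 3]
  }
  if (!is.null(x$labels)) out$tooth <- x$labels
  out
}

# Edge list (each undirected edge once) of the triangulation, as an
# integer matrix with 2 columns. Used for vertex-adjacency connectivity.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Area-weighted per-vertex normals (sum of incident face normals weighted by
# face area, normalized). Used as orientation fallback for near-vertical
# contact patches.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  u <- p2 - p1
  w <- p3 - p1
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])  # 2*area-weighted
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (ax in 1:3) {
      acc <- tapply(fn[, ax], f[, k], sum)
      idx <- as.integer(names(acc))
      vn[idx, ax] <- vn[idx, ax] + acc
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn / nrm
}
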