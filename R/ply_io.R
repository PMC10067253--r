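# PLY mesh I/O: ASCII and binary-little-endian, per-vertex x,y,z (float) and
# red,green,blue (uchar), optional per-vertex integer "tooth" property, face
# list property "vertex_indices". Coordinates are millimetres by contract;
# PLY carries no unit metadata.

ply_type_info <- function(type) {
  switch(type,
    "char" = , "int8" = list(what = "integer", size = 1L, signed = TRUE),
    "uchar" = , "uint8" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4L, signed = TRUE),
    "uint" = , "uint32" = list(what = "integer", size = 4L, signed = TRUE),
    "float" = , "float32" = list(what = "double", size = 4L, signed = TRUE),
    "double" = , "float64" = list(what = "double", size = 8L, signed = TRUE),
    abort(sprintf("unsupported PLY property type '%s'", type))
  )
}

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) abort("not a PLY file (missing 'ply' magic)")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) abort("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        abort(sprintf("unsupported PLY format '%s' (ascii or binary_little_endian only)", fmt))
      }
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) abort("PLY property outside element")
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], value_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) abort("PLY header has no format line")
  list(format = fmt, elements = elements)
}

# Extract one scalar property from an interleaved binary record block.
slice_binary_prop <- function(raw_block, n, rec_size, offset, info) {
  idx <- rep(seq.int(offset + 1L, by = rec_size, length.out = n), each = info$size) +
    rep(seq.int(0L, info$size - 1L), times = n)
  readBin(raw_block[idx], what = info$what, n = n, size = info$size,
          signed = info$signed || info$size >= 4L, endian = "little")
}

#' Read a colored dental mesh from a PLY file
#'
#' Reads ASCII or binary-little-endian PLY with vertex properties `x`, `y`,
#' `z` and `red`, `green`, `blue`, preserving vertex and face order. A
#' per-vertex integer property `tooth`, when present, is read as FDI tooth
#' labels. Coordinates are taken as millimetres (PLY stores no units).
#'
#' @param path Path to a `.ply` file.
#' @return A [colored_mesh()].
#' @seealso [write_ply_mesh()], [read_tooth_labels()]
#' @examples
#' m <- flat_grid_mesh(width = 1, height = 1, edge = 0.5)
#' f <- tempfile(fileext = ".ply")
#' write_ply_mesh(m, f)
#' read_ply_mesh(f)
#' @export
read_ply_mesh <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  ve <- hdr$elements[["vertex"]]
  fe <- hdr$elements[["face"]]
  if (is.null(ve)) abort("PLY file has no vertex element")
  vprops <- names(ve$props)
  if (!all(c("x", "y", "z") %in% vprops)) abort("PLY vertex element lacks x/y/z")
  if (!all(c("red", "green", "blue") %in% vprops)) {
    abort("no vertex colors: PLY vertex element lacks red/green/blue properties")
  }
  has_tooth <- "tooth" %in% vprops
  n <- ve$count
  m <- if (is.null(fe)) 0L else fe$count

  if (hdr$format == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n + m) abort("PLY body truncated")
    vtok <- strsplit(trimws(txt[seq_len(n)]), "\\s+")
    nv <- length(vprops)
    if (any(lengths(vtok) != nv)) abort("malformed PLY vertex line")
    vmat <- matrix(as.numeric(unlist(vtok, use.names = FALSE)), nrow = n, ncol = nv,
                   byrow = TRUE, dimnames = list(NULL, vprops))
    vals <- as.data.frame(vmat)
    faces <- matrix(integer(0), 0, 3)
    if (m > 0) {
      ftok <- strsplit(trimws(txt[n + seq_len(m)]), "\\s+")
      cnts <- vapply(ftok, function(t) as.integer(t[1]), integer(1))
      if (any(cnts != 3L)) {
        abort(sprintf("face %d is not a triangle (%d vertices)",
                      which(cnts != 3L)[1], cnts[cnts != 3L][1]))
      }
      faces <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4), use.names = FALSE)),
                      ncol = 3, byrow = TRUE) + 1L
    }
  } else {
    infos <- lapply(ve$props, function(p) {
      if (p$list) abort("list property in vertex element is unsupported")
      ply_type_info(p$type)
    })
    rec_size <- sum(vapply(infos, `[[`, integer(1), "size"))
    raw_block <- readBin(con, "raw", n = n * rec_size)
    if (length(raw_block) < n * rec_size) abort("PLY body truncated")
    offs <- cumsum(c(0L, utils::head(vapply(infos, `[[`, integer(1), "size"), -1)))
    vals <- as.data.frame(Map(function(info, off) {
      slice_binary_prop(raw_block, n, rec_size, off, info)
    }, infos, offs))
    names(vals) <- vprops
    faces <- matrix(integer(0), 0, 3)
    if (m > 0) {
      fp <- fe$props[["vertex_indices"]] %||% fe$props[["vertex_index"]]
      if (is.null(fp) || !fp$list) abort("PLY face element lacks a vertex_indices list property")
      cinfo <- ply_type_info(fp$count_type)
      vinfo <- ply_type_info(fp$value_type)
      frec <- cinfo$size + 3L * vinfo$size
      raw_f <- readBin(con, "raw", n = m * frec)
      if (length(raw_f) < m * frec) abort("PLY face block truncated (non-triangular faces?)")
      cnts <- slice_binary_prop(raw_f, m, frec, 0L, cinfo)
      if (any(cnts != 3L)) {
        abort(sprintf("face %d is not a triangle (%d vertices)",
                      which(cnts != 3L)[1], cnts[cnts != 3L][1]))
      }
      faces <- sapply(1:3, function(k) {
        slice_binary_prop(raw_f, m, frec, cinfo$size + (k - 1L) * vinfo$size, vinfo)
      })
      faces <- matrix(as.integer(faces), ncol = 3) + 1L
    }
  }

  colored_mesh(
    vertices = cbind(vals$x, vals$y, vals$z),
    faces = faces,
    colors = cbind(vals$red, vals$green, vals$blue),
    labels = if (has_tooth) as.integer(vals$tooth) else NULL
  )
}

#' Write a colored dental mesh to a PLY file
#'
#' Writes vertex positions, RGB colors and (when present) FDI tooth labels as
#' a per-vertex integer property `tooth`. Coordinates are written at double
#' precision (10 significant digits in ASCII, float64 in binary) so that
#' round-trips with [read_ply_mesh()] preserve them within 1e-6 mm; colors,
#' labels and vertex/face order are preserved exactly.
#'
#' @param mesh A [colored_mesh()]; must carry colors.
#' @param path Output path.
#' @param format `"ascii"` (default) or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply_mesh <- function(mesh, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  if (is.null(mesh$colors)) abort("mesh has no vertex colors to write")
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  has_tooth <- !is.null(mesh$labels)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0", format),
    "comment occlusal3d mesh (units: mm)",
    sprintf("element vertex %d", n),
    if (format == "ascii") {
      c("property float x", "property float y", "property float z")
    } else {
      c("property double x", "property double y", "property double z")
    },
    "property uchar red", "property uchar green", "property uchar blue",
    if (has_tooth) "property int tooth",
    sprintf("element face %d", m),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (format == "ascii") {
    vcols <- cbind(
      sprintf("%.10g", mesh$vertices[, 1]), sprintf("%.10g", mesh$vertices[, 2]),
      sprintf("%.10g", mesh$vertices[, 3]),
      mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3],
      if (has_tooth) mesh$labels
    )
    vlines <- do.call(paste, c(as.data.frame(vcols), sep = " "))
    flines <- if (m > 0) {
      paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
    } else character(0)
    writeLines(c(hdr, vlines, flines), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    # interleave per-vertex records
    coords <- t(mesh$vertices)
    cols <- t(mesh$colors)
    for (i in seq_len(n)) {
      writeBin(as.numeric(coords[, i]), con, size = 8L, endian = "little")
      writeBin(as.integer(cols[, i]), con, size = 1L)
      if (has_tooth) writeBin(as.integer(mesh$labels[i]), con, size = 4L, endian = "little")
    }
    if (m > 0) {
      f0 <- t(mesh$faces - 1L)
      for (i in seq_len(m)) {
        writeBin(3L, con, size = 1L)
        writeBin(as.integer(f0[, i]), con, size = 4L, endian = "little")
      }
    }
  }
  invisible(path)
}
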