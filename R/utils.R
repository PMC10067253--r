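# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# FDI two-digit tooth codes: quadrant 1-4, position 1-8; 0 = unlabeled.
is_valid_fdi <- function(code) {
  code == 0L | (code >= 11L & code <= 48L & (code %% 10L) >= 1L & (code %% 10L) <= 8L)
}

#' Map FDI tooth codes to dental arch regions
#'
#' Regions derive from the FDI units digit: positions 1-3 are anterior
#' (incisors and canine), 4-5 premolar, 6-8 molar. Code 0 (unlabeled)
#' maps to `"unassigned"`.
#'
#' @param fdi Integer vector of FDI tooth codes (e.g. 31-38, 41-48) or 0.
#' @return Character vector of `"anterior"`, `"premolar"`, `"molar"`,
#'   `"unassigned"`.
#' @examples
#' fdi_region(c(31, 34, 37, 0))
#' @export
fdi_region <- function(fdi) {
  fdi <- as.integer(fdi)
  bad <- !is_valid_fdi(fdi)
  if (any(bad)) {
    abort(sprintf("invalid FDI code(s): %s", paste(unique(fdi[bad]), collapse = ", ")))
  }
  pos <- fdi %% 10L
  dplyr::case_when(
    fdi == 0L ~ "unassigned",
    pos <= 3L ~ "anterior",
    pos <= 5L ~ "premolar",
    TRUE ~ "molar"
  )
}

region_levels <- function() c("anterior", "premolar", "molar", "unassigned")

# Unit-normalize rows of a matrix / a vector.
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Area of triangles given 3 corner matrices (n x 3 each).
triangle_areas <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) abort(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  unname(x)
}
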