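# 2D similarity registration of the pressure-film record onto the projected
# occlusal contacts, and mutual-nearest-neighbor contact matching.

#' 2D similarity transform (scale, rotation, translation)
#'
#' @param scale Positive scale factor.
#' @param theta_deg Rotation angle, degrees counterclockwise.
#' @param t Length-2 translation in mm.
#' @return An object of class `similarity2d`.
#' @export
similarity2d <- function(scale = 1, theta_deg = 0, t = c(0, 0)) {
  if (scale <= 0) abort("similarity scale must be positive")
  structure(list(scale = scale, theta = theta_deg * pi / 180, t = as.numeric(t)),
            class = "similarity2d")
}

#' @export
print.similarity2d <- function(x, ...) {
  cat(sprintf("<similarity2d> s = %.6g, theta = %.6g deg, t = (%.6g, %.6g) mm\n",
              x$scale, x$theta * 180 / pi, x$t[1], x$t[2]))
  rms <- attr(x, "rms")
  if (!is.null(rms)) cat(sprintf("  fit RMS = %.6g mm over %d pairs\n", rms, attr(x, "n_pairs")))
  invisible(x)
}

#' Apply or invert a 2D similarity transform
#'
#' @param points n x 2 matrix (or length-2 point).
#' @param tf A [similarity2d()].
#' @return Transformed points, same shape as input.
#' @export
apply_similarity <- function(points, tf) {
  stopifnot(inherits(tf, "similarity2d"))
  single <- is.null(dim(points)) && length(points) == 2
  p <- if (single) matrix(points, 1) else as.matrix(points)
  R <- matrix(c(cos(tf$theta), sin(tf$theta), -sin(tf$theta), cos(tf$theta)), 2)
  out <- tf$scale * p %*% t(R)
  out[, 1] <- out[, 1] + tf$t[1]
  out[, 2] <- out[, 2] + tf$t[2]
  colnames(out) <- c("x", "y")
  if (single) out[1, ] else out
}

#' @rdname apply_similarity
#' @export
invert_similarity <- function(tf) {
  stopifnot(inherits(tf, "similarity2d"))
  s <- 1 / tf$scale
  th <- -tf$theta
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  similarity2d(s, th * 180 / pi, -s * as.numeric(R %*% tf$t))
}

#' Least-squares 2D similarity from point correspondences
#'
#' Estimates scale, rotation and translation minimizing
#' `sum(|T(src_i) - dst_i|^2)` over corresponding rows (closed form via the
#' complex-regression identity). Reflections are disallowed: film and scan
#' are both viewed from the occlusal direction, so a reflected fit indicates
#' a flipped film. If the reflection solution fits better by more than a
#' factor 2 in RMS, an error is raised.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 2).
#' @return A [similarity2d()] with attributes `rms` (residual RMS, mm) and
#'   `n_pairs`.
#' @export
estimate_similarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) abort("src and dst must have the same number of rows")
  n <- nrow(src)
  if (n < 2) abort("at least 2 correspondence pairs are required")
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  zsc <- zs - mean(zs)
  zdc <- zd - mean(zd)
  denom <- sum(Mod(zsc)^2)
  if (denom < 1e-18) abort("degenerate correspondences: all source points coincide")
  a <- sum(Conj(zsc) * zdc) / denom          # similarity (rotation branch)
  rms_rot <- sqrt(mean(Mod(zdc - a * zsc)^2))
  b <- sum(zsc * zdc) / denom                # reflected branch
  rms_ref <- sqrt(mean(Mod(zdc - b * Conj(zsc))^2))
  if (Mod(a) < 1e-15) abort("degenerate correspondences: zero similarity scale")
  if (rms_ref * 2 < rms_rot) {
    abort(sprintf(paste0("reflection fits substantially better (RMS %.3g vs %.3g mm): ",
                         "the film record appears mirrored; flip it before registration"),
                  rms_ref, rms_rot))
  }
  tf <- similarity2d(Mod(a), Arg(a) * 180 / pi,
                     c(Re(mean(zd) - a * mean(zs)), Im(mean(zd) - a * mean(zs))))
  attr(tf, "rms") <- rms_rot
  attr(tf, "n_pairs") <- n
  tf
}

#' Match projected contact patches to film force points
#'
#' Mutual-nearest-neighbor matching: a patch and a film point pair up when
#' each is the other's nearest neighbor and their distance does not exceed
#' `max_match_distance_mm`. Conflicts (exact distance ties) resolve greedily
#' by ascending distance, then smallest ids. Unmatched entries are listed,
#' never silently dropped.
#'
#' @param patch_centroids Data frame with `patch_id`, `x`, `y` (projected
#'   occlusal-plane coordinates, mm).
#' @param force_points Data frame with `point_id` (or `id`), `x`, `y` (film
#'   points already transformed into the same 2D frame).
#' @param max_match_distance_mm Pairing distance cutoff (default 2 mm).
#' @return An object of class `contact_matching`: `pairs` (tibble `patch_id`,
#'   `point_id`, `residual_mm`), `unmatched_patches`, `unmatched_points`
#'   (integer id vectors).
#' @export
match_contacts <- function(patch_centroids, force_points, max_match_distance_mm = 2) {
  pc <- as_tibble(patch_centroids)
  fp <- as_tibble(force_points)
  if (!"point_id" %in% names(fp) && "id" %in% names(fp)) {
    fp <- dplyr::rename(fp, point_id = "id")
  }
  empty <- tibble(patch_id = integer(), point_id = integer(), residual_mm = numeric())
  if (nrow(pc) == 0 || nrow(fp) == 0) {
    return(structure(list(pairs = empty, unmatched_patches = pc$patch_id,
                          unmatched_points = fp$point_id),
                     class = "contact_matching"))
  }
  pc <- dplyr::arrange(pc, .data$patch_id)
  fp <- dplyr::arrange(fp, .data$point_id)
  d <- sqrt(outer(pc$x, fp$x, `-`)^2 + outer(pc$y, fp$y, `-`)^2)
  nn_of_patch <- apply(d, 1, which.min)  # ties: smallest index = smallest id
  nn_of_point <- apply(d, 2, which.min)
  cand <- tibble(
    i = seq_len(nrow(pc)),
    j = nn_of_patch,
    residual_mm = d[cbind(seq_len(nrow(pc)), nn_of_patch)]
  ) |>
    dplyr::filter(nn_of_point[.data$j] == .data$i,
                  .data$residual_mm <= max_match_distance_mm) |>
    dplyr::mutate(patch_id = pc$patch_id[.data$i], point_id = fp$point_id[.data$j]) |>
    dplyr::arrange(.data$residual_mm, .data$patch_id, .data$point_id)
  used_i <- logical(nrow(pc)); used_j <- logical(nrow(fp)); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
      keep[k] <- TRUE
      used_i[cand$i[k]] <- TRUE
      used_j[cand$j[k]] <- TRUE
    }
  }
  pairs <- cand[keep, c("patch_id", "point_id", "residual_mm")]
  structure(
    list(pairs = pairs,
         unmatched_patches = setdiff(pc$patch_id, pairs$patch_id),
         unmatched_points = setdiff(fp$point_id, pairs$point_id)),
    class = "contact_matching"
  )
}

#' @export
print.contact_matching <- function(x, ...) {
  cat(sprintf("<contact_matching> %d pairs, %d unmatched patches, %d unmatched points\n",
              nrow(x$pairs), length(x$unmatched_patches), length(x$unmatched_points)))
  if (nrow(x$pairs)) {
    cat(sprintf("  residuals: median %.3f mm, max %.3f mm\n",
                stats::median(x$pairs$residual_mm), max(x$pairs$residual_mm)))
  }
  invisible(x)
}
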