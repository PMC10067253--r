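# Independent oracles and tiny fixture builders shared across tests.

# Unit 1 mm x 1 mm square: 4 vertices, 2 triangles.
square_mesh <- function(colors = matrix(255L, 4, 3)) {
  colored_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
    faces = rbind(c(1, 2, 3), c(2, 4, 3)),
    colors = colors
  )
}

# Brute-force connected components of marked vertices under shared-edge
# adjacency: plain BFS over an adjacency list built by looping over faces.
# Deliberately naive and independent of the package's igraph route.
brute_components <- function(mesh, mask) {
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[r, ]
    for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- f[pair[1]]; b <- f[pair[2]]
      if (mask[a] && mask[b]) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  seen <- logical(n)
  comps <- list()
  for (s in which(mask)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Brute-force plane-normal search: coarse 1-degree grid over the upper unit
# hemisphere, then local refinement, minimizing perpendicular RMS about the
# centroid. Oracle for the eigen-decomposition route on small patches.
brute_normal <- function(points) {
  pc <- sweep(points, 2, colMeans(points))
  rms_for <- function(theta, phi) {
    n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    sqrt(mean((pc %*% n)^2))
  }
  best <- c(0, 0); best_rms <- Inf
  for (theta in seq(0, pi / 2, by = pi / 180)) {
    for (phi in seq(0, 2 * pi, by = pi / 180)) {
      r <- rms_for(theta, phi)
      if (r < best_rms) { best_rms <- r; best <- c(theta, phi) }
    }
  }
  for (step in c(0.2, 0.04, 0.008) * pi / 180) {
    for (theta in best[1] + seq(-5, 5) * step) {
      for (phi in best[2] + seq(-5, 5) * step) {
        r <- rms_for(theta, phi)
        if (r < best_rms) { best_rms <- r; best <- c(theta, phi) }
      }
    }
  }
  c(sin(best[1]) * cos(best[2]), sin(best[1]) * sin(best[2]), cos(best[1]))
}

angle_between <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Map truth contacts to extracted patch ids by centroid proximity.
truth_patch_ids <- function(truth, patches) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- (patches$centroid_x - truth$center_x[i])^2 +
      (patches$centroid_y - truth$center_y[i])^2
    patches$patch_id[which.min(d)]
  }, integer(1))
}

# Small painted arch shared by several test files (built once per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_occlusion(arch_cfg(edge = 0.3), seed = 42)
    }
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
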