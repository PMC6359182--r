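# Independent oracles and generators used across the suite.

# O(n^2) connected-components oracle for fixed-radius clustering:
# two points share a cluster iff joined by a chain of hops <= r.
brute_force_clusters <- function(xyz, r, min_size = 1) {
  n <- nrow(xyz)
  if (n == 0) return(list())
  d <- as.matrix(stats::dist(xyz))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= r)
      m <- min(comp[nb], comp[i])
      if (any(comp[c(i, nb)] != m)) {
        comp[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cl <- split(seq_len(n), comp)
  cl <- lapply(cl, sort)
  sizes <- lengths(cl)
  first <- vapply(cl, `[`, integer(1), 1L)
  cl <- cl[order(-sizes, first)]
  cl <- cl[lengths(cl) >= min_size]
  names(cl) <- NULL
  cl
}

# Uniform sample on a sphere surface (optionally only the cap facing -z).
sample_sphere <- function(n, center, radius, cap = FALSE) {
  z <- if (cap) runif(n, -1, 0) else runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  tibble::tibble(
    x = center[1] + radius * s * cos(phi),
    y = center[2] + radius * s * sin(phi),
    z = center[3] + radius * z
  )
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Points along a 3D line with isotropic Gaussian noise.
sample_line <- function(n, p, t, span, sigma = 0) {
  t <- t / sqrt(sum(t^2))
  s <- seq(-span / 2, span / 2, length.out = n)
  pts <- cbind(p[1] + s * t[1], p[2] + s * t[2], p[3] + s * t[3])
  if (sigma > 0) pts <- pts + matrix(rnorm(3 * n, 0, sigma), n, 3)
  colnames(pts) <- c("x", "y", "z")
  tibble::as_tibble(pts)
}

# Angle (degrees) between two directions ignoring sign.
axis_angle <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(ca, 1)) * 180 / pi
}

# 3-vector cross product (oracle for perpendicular distances).
crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
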