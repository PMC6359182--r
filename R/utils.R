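# internal helpers shared across modules

# Normalise a 3-vector to unit length; error on (near-)zero input.
unitize <- function(v, what = "vector") {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv <= .Machine$double.eps) {
    abort(paste0("cannot normalise a zero-length ", what),
          class = "guavapose_zero_vector")
  }
  v / nv
}

# Fixed sign convention for line directions so outputs are reproducible:
# non-negative z component; ties broken by non-negative y, then x.
canonical_direction <- function(t) {
  flip <- if (t[3] != 0) t[3] < 0 else if (t[2] != 0) t[2] < 0 else t[1] < 0
  if (flip) -t else t
}

# Extract an n x 3 coordinate matrix from a data frame (x/y/z columns),
# a numeric matrix, or a single length-3 vector.
as_xyz <- function(points) {
  if (is.data.frame(points)) {
    for (col in c("x", "y", "z")) {
      if (!col %in% names(points)) {
        abort(sprintf("`points` must have an `%s` column", col))
      }
    }
    return(cbind(x = points$x, y = points$y, z = points$z))
  }
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    colnames(points) <- c("x", "y", "z")
    return(points)
  }
  if (is.numeric(points) && length(points) == 3) {
    return(matrix(points, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  abort("`points` must be a data frame with x/y/z, an n x 3 matrix, or a length-3 vector")
}

# Run code under a temporary RNG state when a seed is supplied, so callers
# get determinism without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
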