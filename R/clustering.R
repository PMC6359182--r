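#' Clustering parameters
#'
#' `distance_threshold` is the region-growing radius in millimetres: two
#' points belong to the same fruit cluster iff they are connected by a
#' chain of hops each no longer than it. 4 mm separates adjacent guava
#' fruits while keeping single fruits whole at typical Kinect V2 point
#' spacing. `min_cluster_size` discards speckle clusters (mis-segmented
#' stray pixels) that would otherwise surface as tiny spurious fruits.
#'
#' @param distance_threshold Positive radius in mm (default 4).
#' @param min_cluster_size Minimum points per retained cluster (default 30).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(distance_threshold = 4, min_cluster_size = 30) {
  if (!is.numeric(distance_threshold) || distance_threshold <= 0) {
    abort("`distance_threshold` must be > 0", class = "guavapose_parameter_error")
  }
  if (!is.numeric(min_cluster_size) || min_cluster_size < 1) {
    abort("`min_cluster_size` must be >= 1", class = "guavapose_parameter_error")
  }
  structure(list(distance_threshold = as.numeric(distance_threshold),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Euclidean clustering of a point cloud
#'
#' Region-growing partition: points are grouped into connected components
#' of the graph whose edges join pairs at Euclidean distance no more than
#' `distance_threshold`. The radius search is exact (grid-hashed cells of
#' side equal to the threshold, so only the 27 neighbouring cells need
#' checking), so cluster membership matches a brute-force all-pairs
#' computation exactly. Clusters smaller than `min_cluster_size` are
#' discarded; the rest are returned in decreasing size order, ties broken
#' by smallest member index.
#'
#' @param points Data frame with `x`, `y`, `z` columns (mm) or an n x 3
#'   matrix; may be empty.
#' @param params A [cluster_params()] object (or its two fields passed via
#'   `...` style helpers).
#' @return A list of integer vectors, each the (ascending) row indices of
#'   one cluster.
#' @examples
#' pts <- tibble::tibble(x = c(0, 3, 6, 20), y = 0, z = 0)
#' euclidean_cluster(pts, cluster_params(4, 1))
#' @export
euclidean_cluster <- function(points, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  xyz <- if (is.null(points) || (is.data.frame(points) && nrow(points) == 0)) {
    matrix(numeric(0), 0, 3)
  } else {
    as_xyz(points)
  }
  n <- nrow(xyz)
  if (n == 0) return(list())

  edges <- radius_edges(xyz, params$distance_threshold)
  membership <- if (nrow(edges) == 0) {
    seq_len(n)
  } else {
    g <- igraph::make_graph(edges = as.vector(t(edges)), n = n, directed = FALSE)
    igraph::components(g)$membership
  }

  clusters <- split(seq_len(n), membership)
  clusters <- lapply(clusters, sort)
  sizes <- lengths(clusters)
  first <- vapply(clusters, `[`, integer(1), 1L)
  clusters <- clusters[order(-sizes, first)]
  clusters <- clusters[lengths(clusters) >= params$min_cluster_size]
  names(clusters) <- NULL
  clusters
}

# Exact fixed-radius edge list. Small clouds use the full distance matrix;
# larger ones hash points into cells of side `r` and compare each cell only
# with its half-neighbourhood, which is exact for a radius-r search.
radius_edges <- function(xyz, r) {
  n <- nrow(xyz)
  if (n <= 2000) {
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= r & upper.tri(d), arr.ind = TRUE)
    return(unname(hit))
  }
  cell <- floor(sweep(xyz, 2, c(0, 0, 0)) / r)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  bucket_at <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = bucket_at)

  # half-space of the 27 cell offsets (self handled separately)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]
  r2 <- r^2
  out <- vector("list", length(buckets) * (nrow(offs) + 1L))
  m <- 0L
  for (k in names(buckets)) {
    ia <- buckets[[k]]
    A <- xyz[ia, , drop = FALSE]
    # within-cell pairs
    if (length(ia) > 1) {
      d <- as.matrix(stats::dist(A))
      hit <- which(d <= r & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit)) {
        m <- m + 1L
        out[[m]] <- cbind(ia[hit[, 1]], ia[hit[, 2]])
      }
    }
    ck <- as.numeric(strsplit(k, ",", fixed = TRUE)[[1]])
    for (o in seq_len(nrow(offs))) {
      nk <- paste(ck[1] + offs$dx[o], ck[2] + offs$dy[o], ck[3] + offs$dz[o],
                  sep = ",")
      ib <- if (exists(nk, envir = bucket_at, inherits = FALSE)) {
        get(nk, envir = bucket_at)
      } else NULL
      if (is.null(ib)) next
      B <- xyz[ib, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      hit <- which(d2 <= r2, arr.ind = TRUE)
      if (nrow(hit)) {
        m <- m + 1L
        out[[m]] <- cbind(ia[hit[, 1]], ib[hit[, 2]])
      }
    }
  }
  if (m == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, out[seq_len(m)])
}
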