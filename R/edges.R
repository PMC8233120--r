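#' Upper-triangle edge index map
#'
#' Fixes the package-wide vectorization convention for symmetric
#' connectomes: upper-triangle edges (i < j) in row-major order, i.e.
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N), in 1-based indices.
#'
#' @param n Number of regions.
#' @return Data frame with columns `i`, `j` (1-based row/column indices),
#'   one row per edge, `n * (n - 1) / 2` rows.
#' @export
edge_index_map <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Vectorize a symmetric connectome matrix
#'
#' Extracts the upper-triangle edges in the package's canonical order
#' ([edge_index_map()]). With `within_hemisphere` given, the matrix is
#' first restricted to the regions of that hemisphere plus bilateral
#' regions (55 regions for the default atlas, giving 1485 edges).
#'
#' @param m Symmetric numeric matrix (NA marks missing edges).
#' @param atlas Region atlas; required when `within_hemisphere` is given.
#' @param within_hemisphere Optional `"left"` or `"right"`.
#' @return Numeric vector of edge values; attribute `"map"` holds the edge
#'   index data frame (indices into the possibly restricted matrix) and
#'   attribute `"regions"` the 0-based region ids of the matrix rows.
#' @export
edge_vector <- function(m, atlas = NULL, within_hemisphere = NULL) {
  regions <- seq_len(nrow(m)) - 1L
  if (!is.null(within_hemisphere)) {
    if (is.null(atlas)) stop("atlas required for hemisphere restriction")
    regions <- hemisphere_regions(atlas, within_hemisphere)
    m <- m[regions + 1L, regions + 1L, drop = FALSE]
  }
  map <- edge_index_map(nrow(m))
  v <- m[cbind(map$i, map$j)]
  attr(v, "map") <- map
  attr(v, "regions") <- regions
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [edge_vector()] (without hemisphere restriction): fills the
#' upper and lower triangles from the canonical edge order and sets the
#' diagonal to zero.
#'
#' @param v Edge value vector of length `n * (n - 1) / 2`.
#' @param n Number of regions.
#' @return An `n` by `n` symmetric matrix with zero diagonal.
#' @export
edges_to_matrix <- function(v, n) {
  map <- edge_index_map(n)
  if (length(v) != nrow(map)) stop("edge vector length does not match n")
  m <- matrix(0, n, n)
  m[cbind(map$i, map$j)] <- v
  m[cbind(map$j, map$i)] <- v
  m
}

# Linear (column-major) indices of canonical edges of an n x n matrix,
# used to gather edge vectors from many matrices at once.
edge_linear_index <- function(n) {
  map <- edge_index_map(n)
  (map$j - 1L) * n + map$i
}

# Edge permutation induced by a region permutation perm (perm[slot] =
# source region, 1-based): result p satisfies new_edges = old_edges[p].
edge_permutation <- function(region_perm, n) {
  map <- edge_index_map(n)
  edge_column(region_perm[map$i], region_perm[map$j], n)
}

# Edge-column index of edge (a, b) (1-based region indices) in the
# canonical edge order for an n-region matrix. Vectorized.
edge_column <- function(a, b, n) {
  i <- pmin(a, b)
  j <- pmax(a, b)
  if (any(i == j)) stop("self edges have no column")
  # edges before row i: sum_{r<i} (n - r); offset within row: j - i
  (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i)
}
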