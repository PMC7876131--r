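#' Build a voxel graph from an edge list
#'
#' Undirected simple graph over linked voxels: duplicate edges and self-loops
#' are removed. Accepts a two-column matrix/data frame of voxel ids, the
#' two-column whitespace/comma-separated TXT format of a connection dump, or
#' an igraph object (returned as is).
#'
#' @param edges Two-column object of voxel ids, a path to an edge TXT/CSV
#'   file, or an igraph graph.
#' @return An undirected simple \code{igraph} graph.
#' @export
voxel_graph <- function(edges) {
  if (inherits(edges, "igraph")) {
    return(igraph::simplify(igraph::as_undirected(edges)))
  }
  if (is.character(edges) && length(edges) == 1L) {
    edges <- utils::read.table(edges, header = FALSE, sep = "",
                               col.names = c("from", "to"))
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2), directed = FALSE)
  igraph::simplify(g)
}

#' Shortest-path statistics of a voxel network
#'
#' The path length L between two voxels is the minimum number of links needed
#' to connect them (unweighted breadth-first distance). \code{average_L}
#' averages L over connected ordered pairs of distinct vertices (pairs in
#' different components have no finite path and are excluded);
#' \code{max_L} is the largest finite L — the diameter of the largest-diameter
#' component.
#'
#' @param g A graph accepted by \code{\link{voxel_graph}}.
#' @return List of class \code{"path_stats"} with \code{average_L},
#'   \code{max_L}, \code{n_vertices}, \code{n_pairs} (connected ordered
#'   pairs).
#' @export
#' @examples
#' path_stats(rbind(c("a", "b"), c("b", "c")))  # average_L = 4/3, max_L = 2
path_stats <- function(g) {
  g <- voxel_graph(g)
  if (igraph::vcount(g) == 0L) stop("graph is empty", call. = FALSE)
  d <- igraph::distances(g)
  diag(d) <- Inf
  finite <- is.finite(d)
  if (!any(finite)) stop("graph has no edges: no finite path lengths", call. = FALSE)
  structure(
    list(average_L = mean(d[finite]), max_L = max(d[finite]),
         n_vertices = igraph::vcount(g), n_pairs = sum(finite)),
    class = "path_stats"
  )
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("Path statistics: average L = %.4f, max L = %g (%d vertices, %d connected pairs)\n",
              x$average_L, x$max_L, x$n_vertices, x$n_pairs))
  invisible(x)
}

#' Clustering coefficients of a voxel network
#'
#' Per-vertex \eqn{C_i = 2 e_i / (k_i (k_i - 1))} where \eqn{e_i} counts the
#' links among the neighbors of voxel \eqn{i}; vertices with fewer than 2
#' links have \eqn{C_i = 0}. The network average \eqn{C = (1/N) \sum C_i}
#' runs, by default, over the \eqn{N} voxels with at least one link (the
#' linked part of the network); set \code{linked_only = FALSE} to average
#' over every vertex.
#'
#' @param g A graph accepted by \code{\link{voxel_graph}}.
#' @param linked_only Average over vertices with >= 1 link only? Default
#'   \code{TRUE}.
#' @return List of class \code{"clustering_stats"} with \code{local}
#'   (named per-vertex \eqn{C_i}) and \code{average}.
#' @export
clustering_coefficients <- function(g, linked_only = TRUE) {
  g <- voxel_graph(g)
  if (igraph::vcount(g) == 0L) stop("graph is empty", call. = FALSE)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(ci) <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  deg <- igraph::degree(g)
  avg <- if (linked_only) {
    if (!any(deg >= 1)) 0 else mean(ci[deg >= 1])
  } else {
    mean(ci)
  }
  structure(list(local = ci, average = avg, linked_only = linked_only),
            class = "clustering_stats")
}

#' @export
print.clustering_stats <- function(x, ...) {
  cat(sprintf("Clustering: average C = %.4f over %d vertices%s\n",
              x$average, length(x$local),
              if (x$linked_only) " (linked only)" else ""))
  invisible(x)
}

#' Edge list of the thresholded correlation network
#'
#' Companion to \code{\link{build_degree_vector}}: returns the voxel pairs
#' whose correlation exceeds the threshold, suitable for
#' \code{\link{voxel_graph}} or for dumping as the two-column connection TXT.
#' Intended for desk-scale graphs (it materializes the pair list).
#'
#' @inheritParams build_degree_vector
#' @return Two-column integer matrix of linked voxel row indices (i < j).
#' @export
correlation_edges <- function(ts, threshold = 0.7, mask = NULL,
                              var_eps = 1e-12) {
  values <- if (inherits(ts, "voxel_time_series")) ts$values else as.matrix(ts)
  if (ncol(values) < 2L) stop("at least 2 timepoints are required", call. = FALSE)
  v <- nrow(values)
  keep <- rep(TRUE, v)
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  ctr <- values - rowMeans(values)
  ss <- rowSums(ctr^2)
  keep <- keep & (ss / ncol(values) > var_eps)
  rows <- which(keep)
  if (length(rows) < 2L) return(matrix(integer(), ncol = 2,
                                       dimnames = list(NULL, c("from", "to"))))
  z <- ctr[rows, , drop = FALSE] / sqrt(ss[rows])
  r <- z %*% t(z)
  hit <- which(r > threshold & upper.tri(r), arr.ind = TRUE)
  cbind(from = rows[hit[, 1]], to = rows[hit[, 2]])
}
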