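#' Pairwise Euclidean distances between samples
#'
#' Distances between sample (column) expression profiles over a selected
#' gene set: \eqn{d(i,j) = \sqrt{\sum_g (x_{gi} - x_{gj})^2}}.
#'
#' @param x numeric matrix, genes x samples.
#' @param genes optional character vector restricting the rows (e.g. a
#'   progression signature); must be non-empty and present in
#'   \code{rownames(x)}.
#' @return symmetric distance matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
pairwise_euclidean <- function(x, genes = NULL) {
  if (!is.null(genes)) {
    if (length(genes) == 0) stop("empty gene set", call. = FALSE)
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) {
      stop("genes absent from matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[genes, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("empty gene set", call. = FALSE)
  if (ncol(x) < 2) stop("need at least two samples", call. = FALSE)
  as.matrix(stats::dist(t(x), method = "euclidean"))
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking: candidate edges
#' are sorted by (weight, first node, second node) in lexicographic node
#' order, so equal-weight distances always yield the same tree.
#'
#' @param d symmetric distance matrix with dimnames naming the nodes.
#' @return data.frame of the n-1 tree edges: \code{node_a}, \code{node_b},
#'   \code{weight}, sorted as added.
#' @export
build_mst <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least two nodes", call. = FALSE)
  stopifnot(ncol(d) == n)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  # union-find with path compression
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- matrix(0L, n - 1, 2)
  w <- numeric(n - 1)
  k <- 0
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1
      edges[k, ] <- c(i, j)
      w[k] <- d[i, j]
      if (k == n - 1) break
    }
  }
  data.frame(node_a = ids[edges[, 1]], node_b = ids[edges[, 2]],
             weight = w, stringsAsFactors = FALSE)
}

#' Group coherence on a minimum spanning tree
#'
#' For each group, counts the connected components of the subgraph the
#' group's nodes induce on the tree. A count of 1 means the group forms
#' one contiguous subtree (the group "clusters together" on the tree);
#' larger counts mean its members are scattered among other groups.
#'
#' @param mst_edges edge data.frame from [build_mst()].
#' @param groups named vector (names = node ids) or factor aligned with
#'   the node ids appearing in the edges; every node must be labeled.
#' @return named integer vector: induced component count per group.
#' @export
group_coherence <- function(mst_edges, groups) {
  nodes <- unique(c(mst_edges$node_a, mst_edges$node_b))
  if (is.null(names(groups))) {
    stop("groups must be a named vector covering every node", call. = FALSE)
  }
  unlabeled <- setdiff(nodes, names(groups))
  if (length(unlabeled)) {
    stop("unlabeled nodes: ", paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(mst_edges[, c("node_a", "node_b")],
                                     directed = FALSE, vertices = nodes)
  grp <- as.character(groups[nodes])
  out <- vapply(sort(unique(grp)), function(lev) {
    sub <- igraph::induced_subgraph(g, which(grp == lev))
    igraph::components(sub)$no
  }, numeric(1))
  out
}

#' Sample-similarity graph over a gene signature
#'
#' Convenience wrapper producing the full sample graph: Euclidean
#' distances over the selected genes, the minimum spanning tree, and the
#' per-group coherence counts.
#'
#' @inheritParams pairwise_euclidean
#' @param groups group label per column of \code{x}.
#' @return list of class \code{"sample_graph"}: \code{distances},
#'   \code{mst_edges}, \code{coherence}, \code{groups}.
#' @export
sample_graph <- function(x, groups, genes = NULL) {
  stopifnot(length(groups) == ncol(x))
  d <- pairwise_euclidean(x, genes)
  edges <- build_mst(d)
  grp <- stats::setNames(as.character(groups), colnames(x))
  structure(list(distances = d, mst_edges = edges,
                 coherence = group_coherence(edges, grp), groups = grp),
            class = "sample_graph")
}
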