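#' Construct a simple undirected network
#'
#' The basic container used throughout the package: a simple undirected graph
#' over string vertex identifiers with optional nonnegative edge weights.
#' Self-loops are dropped (every topological measure here assumes a simple
#' graph) and parallel edges are collapsed keeping the maximum weight, a
#' conservative choice when weights encode interaction or co-expression
#' strength.  Vertex order is fixed at first-seen order and every matrix in
#' the package is indexed by it.
#'
#' @param edges two-column character matrix (or data.frame) of endpoints; may
#'   have zero rows.
#' @param vertices optional character vector of vertex identifiers; vertices
#'   appearing in `edges` but not listed here are appended in first-seen
#'   order.  Use this to register isolated vertices.
#' @param weights optional numeric vector of nonnegative edge weights, one
#'   per row of `edges` (default 1).
#' @return An object of class `nettop_network` with elements `vertices`
#'   (character), `edges` (integer matrix, columns `from`/`to`, always
#'   `from < to`), and `weights` (numeric).
#' @examples
#' net <- network(cbind(c("a", "b"), c("b", "c")))
#' vcount(net)
#' @export
network <- function(edges, vertices = NULL, weights = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns")
  }
  storage.mode(edges) <- "character"
  edges <- matrix(trimws(edges), ncol = 2L)
  if (is.null(weights)) {
    weights <- rep(1, nrow(edges))
  }
  if (length(weights) != nrow(edges)) {
    stop("`weights` must have one entry per edge")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("edge weights must be finite and nonnegative")
  }
  verts <- unique(c(as.character(vertices), as.vector(t(edges))))
  verts <- verts[nzchar(verts)]

  loops <- edges[, 1L] == edges[, 2L]
  n_loops <- sum(loops)
  if (n_loops > 0L) {
    message(sprintf("dropped %d self-loop(s)", n_loops))
    edges <- edges[!loops, , drop = FALSE]
    weights <- weights[!loops]
  }

  from <- match(edges[, 1L], verts)
  to <- match(edges[, 2L], verts)
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to)
  if (anyDuplicated(key)) {
    w <- tapply(weights, key, max)
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
    weights <- as.numeric(w[paste(from, to)])
  }
  ord <- order(from, to)
  em <- cbind(from = from[ord], to = to[ord])
  storage.mode(em) <- "integer"
  structure(
    list(vertices = verts, edges = em, weights = weights[ord],
         n_dropped_loops = n_loops),
    class = "nettop_network"
  )
}

#' @export
print.nettop_network <- function(x, ...) {
  cat(sprintf("<nettop_network> %d vertices, %d edges\n",
              vcount(x), ecount(x)))
  invisible(x)
}

#' Number of vertices / edges of a network
#' @param net a `nettop_network`
#' @return integer count
#' @export
vcount <- function(net) length(net$vertices)

#' @rdname vcount
#' @export
ecount <- function(net) nrow(net$edges)

#' Adjacency structures
#'
#' `adjacency_list()` returns, per vertex, the integer indices of its
#' neighbours; `adjacency_matrix()` the dense symmetric matrix `A` (weighted
#' if `weighted = TRUE`) with vertex identifiers as dimnames.
#'
#' @param net a `nettop_network`
#' @param weighted logical; fill the matrix with edge weights instead of 0/1
#' @return a list of integer vectors, or a numeric matrix
#' @export
adjacency_list <- function(net) {
  n <- vcount(net)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (ecount(net) > 0L) {
    e <- net$edges
    adj <- unname(split(c(e[, 2L], e[, 1L]),
                        factor(c(e[, 1L], e[, 2L]), levels = seq_len(n))))
    adj <- lapply(adj, as.integer)
  }
  adj
}

#' @rdname adjacency_list
#' @export
adjacency_matrix <- function(net, weighted = FALSE) {
  n <- vcount(net)
  A <- matrix(0, n, n, dimnames = list(net$vertices, net$vertices))
  if (ecount(net) > 0L) {
    e <- net$edges
    w <- if (weighted) net$weights else rep(1, nrow(e))
    A[cbind(e[, 1L], e[, 2L])] <- w
    A[cbind(e[, 2L], e[, 1L])] <- w
  }
  A
}

#' Convert to an igraph object
#'
#' Used internally for community detection and available for interoperability
#' (plotting, additional igraph analyses).
#'
#' @param net a `nettop_network`
#' @return an undirected [igraph::graph] with a `name` vertex attribute and a
#'   `weight` edge attribute
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = vcount(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$vertices)
  if (ecount(net) > 0L) {
    g <- igraph::add_edges(g, t(net$edges), weight = net$weights)
  }
  g
}
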