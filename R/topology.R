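#' Names of the thirteen topological features, in fixed column order
#'
#' Every feature table produced by [compute_all()] carries exactly these
#' columns, in this order, after the `vertex` column.
#'
#' @return character vector of length 13
#' @export
feature_names <- function() {
  c("degree", "coreness", "clustering_coefficient", "betweenness",
    "closeness", "proximity_prestige", "barycenter", "eigenvector",
    "katz", "subgraph", "within_module_z", "k_step_markov",
    "structural_holes")
}

#' Vertex degree
#'
#' Number of connections of each vertex (edge weights are ignored; degree
#' counts edges).
#'
#' @param net a [network()] object
#' @return named numeric vector over vertices; sums to twice the edge count
#' @export
degree <- function(net) {
  stats::setNames(as.numeric(lengths(adjacency_list(net))), net$vertices)
}

#' Coreness (k-core index)
#'
#' The largest k such that the vertex survives the k-core peeling: vertices
#' of degree < k are removed recursively until none remain.
#'
#' @param net a [network()] object
#' @return named numeric vector of core indices
#' @export
coreness <- function(net) {
  adj <- adjacency_list(net)
  n <- vcount(net)
  core <- integer(n)
  if (n > 0L) {
    degc <- lengths(adj)
    alive <- rep(TRUE, n)
    k <- 0L
    for (step in seq_len(n)) {
      live <- which(alive)
      v <- live[which.min(degc[live])]
      k <- max(k, degc[v])
      core[v] <- k
      alive[v] <- FALSE
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      degc[nb] <- degc[nb] - 1L
    }
  }
  stats::setNames(as.numeric(core), net$vertices)
}

#' Local clustering coefficient
#'
#' Ratio of the number of edges among a vertex's neighbours to the maximum
#' possible `deg(v)*(deg(v)-1)/2`.  Vertices of degree < 2 have an empty
#' neighbourhood ratio and are assigned 0.
#'
#' @param net a [network()] object
#' @return named numeric vector in `[0, 1]`
#' @export
clustering_coefficient <- function(net) {
  adj <- adjacency_list(net)
  n <- vcount(net)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k >= 2L) {
      e_i <- sum(vapply(nb, function(w) sum(adj[[w]] %in% nb), 0L)) / 2
      cc[v] <- e_i / (k * (k - 1) / 2)
    }
  }
  stats::setNames(cc, net$vertices)
}

# Single-source BFS over an adjacency list.  Returns geodesic distances
# (edge counts, -1 for unreachable), the number of distinct shortest paths
# sigma, the visit order, and predecessor lists on shortest paths.
bfs_paths <- function(adj, s, want_pred = FALSE) {
  n <- length(adj)
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  pred <- if (want_pred) vector("list", n) else NULL
  order <- integer(0)
  frontier <- s
  d <- 0L
  while (length(frontier) > 0L) {
    order <- c(order, frontier)
    nxt <- integer(0)
    for (v in frontier) {
      nb <- adj[[v]]
      fresh <- nb[dist[nb] < 0L]
      if (length(fresh) > 0L) {
        dist[fresh] <- d + 1L
        nxt <- c(nxt, fresh)
      }
      succ <- nb[dist[nb] == d + 1L]
      if (length(succ) > 0L) {
        sigma[succ] <- sigma[succ] + sigma[v]
        if (want_pred) {
          for (w in succ) pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  list(dist = dist, sigma = sigma, order = order, pred = pred)
}

#' All-pairs geodesic summary
#'
#' Exact BFS distances (geodesics measured in edge counts, regardless of
#' edge weights) and shortest-path counts for every ordered vertex pair.
#'
#' @param net a [network()] object
#' @return an object of class `nettop_sp` with numeric matrices `dist`
#'   (`Inf` for unreachable pairs) and `count` (number of distinct shortest
#'   paths; 0 for unreachable pairs), both with vertex-identifier dimnames
#' @seealso [geodesic_through_count()]
#' @export
shortest_paths <- function(net) {
  adj <- adjacency_list(net)
  n <- vcount(net)
  dist <- matrix(Inf, n, n, dimnames = list(net$vertices, net$vertices))
  count <- matrix(0, n, n, dimnames = list(net$vertices, net$vertices))
  for (s in seq_len(n)) {
    b <- bfs_paths(adj, s)
    reach <- b$dist >= 0L
    dist[s, reach] <- b$dist[reach]
    count[s, reach] <- b$sigma[reach]
  }
  structure(list(dist = dist, count = count), class = "nettop_sp")
}

#' Number of s-t geodesics passing strictly through v
#'
#' Computed from the shortest-path counting identity: a geodesic from s to t
#' passes through interior vertex v iff `dist(s,v) + dist(v,t) = dist(s,t)`,
#' and then the number of such geodesics is `count(s,v) * count(v,t)`.
#'
#' @param sp a `nettop_sp` from [shortest_paths()]
#' @param s,t,v vertex identifiers
#' @return nonnegative count; 0 when v is an endpoint or off every geodesic
#' @export
geodesic_through_count <- function(sp, s, t, v) {
  if (v == s || v == t) return(0)
  d <- sp$dist[s, t]
  if (!is.finite(d)) return(0)
  if (sp$dist[s, v] + sp$dist[v, t] == d) {
    sp$count[s, v] * sp$count[v, t]
  } else {
    0
  }
}

#' Betweenness centrality (ordered-pair convention)
#'
#' Sum over all ordered pairs (s, t), with s, t and v distinct, of the
#' fraction of s-t geodesics on which v is an interior vertex.  Because the
#' sum runs over ordered pairs, each unordered pair contributes twice: the
#' value is exactly twice the usual unordered-pair betweenness.  Set
#' `halve = TRUE` to recover the unordered convention.  Computed with
#' Brandes' dependency accumulation.
#'
#' @param net a [network()] object
#' @param halve divide by 2 to obtain the unordered-pair convention
#' @return named numeric vector of betweenness values
#' @export
betweenness <- function(net, halve = FALSE) {
  adj <- adjacency_list(net)
  n <- vcount(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    b <- bfs_paths(adj, s, want_pred = TRUE)
    delta <- numeric(n)
    for (w in rev(b$order)) {
      p <- b$pred[[w]]
      if (length(p) > 0L) {
        delta[p] <- delta[p] + b$sigma[p] * ((1 + delta[w]) / b$sigma[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (halve) bc <- bc / 2
  stats::setNames(bc, net$vertices)
}

#' Harmonic closeness centrality
#'
#' Sum of reciprocal geodesic distances to every other vertex, with
#' unreachable vertices contributing 0 (1/Inf).  Well-defined on
#' disconnected networks without extracting the largest component.
#'
#' @param net a [network()] object
#' @param sp optional precomputed [shortest_paths()] summary
#' @return named numeric vector
#' @export
closeness <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_paths(net)
  d <- sp$dist
  diag(d) <- Inf
  stats::setNames(rowSums(1 / d), net$vertices)
}

#' Proximity prestige
#'
#' Ratio of the fraction of vertices able to reach v to their mean geodesic
#' distance from v: `(I_v / (|V|-1)) / (sum(dist) / I_v)` where `I_v` is the
#' number of vertices in v's influence domain (in an undirected graph, its
#' component size minus one).  Vertices with empty domain score 0.
#'
#' @inheritParams closeness
#' @return named numeric vector in `[0, 1]`
#' @export
proximity_prestige <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_paths(net)
  n <- vcount(net)
  d <- sp$dist
  diag(d) <- Inf
  reach <- is.finite(d)
  i_v <- rowSums(reach)
  tot <- rowSums(ifelse(reach, d, 0))
  pp <- ifelse(i_v > 0, (i_v / (n - 1)) / (tot / i_v), 0)
  stats::setNames(pp, net$vertices)
}

#' Barycenter score
#'
#' Reciprocal of the total geodesic distance from the vertex to all vertices
#' of its own connected component.  Vertices with zero total distance
#' (isolated, or singleton components) score 0.
#'
#' @inheritParams closeness
#' @return named numeric vector
#' @export
barycenter <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_paths(net)
  d <- sp$dist
  diag(d) <- Inf
  tot <- rowSums(ifelse(is.finite(d), d, 0))
  stats::setNames(ifelse(tot > 0, 1 / tot, 0), net$vertices)
}

#' Eigenvector centrality
#'
#' The leading eigenvector of the (binary) adjacency matrix A, scaled to
#' unit Euclidean norm with nonnegative entries.  Power iteration is run on
#' A + I, which has the same eigenvectors and makes the Perron eigenvalue
#' strictly dominant even on bipartite graphs.
#'
#' @param net a [network()] object; must have at least one edge
#' @param tol convergence tolerance on the successive-iterate infinity norm
#' @param max_iter iteration cap
#' @return named numeric vector, unit Euclidean norm
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  if (ecount(net) == 0L) {
    stop("eigenvector centrality is undefined on an edgeless network")
  }
  A <- adjacency_matrix(net)
  n <- vcount(net)
  x <- rep(1 / sqrt(n), n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x   # (A + I) x
    y <- y / sqrt(sum(y^2))
    res <- max(abs(y - x))
    x <- y
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf("power iteration did not converge: residual %.3e after %d iterations",
                 res, max_iter))
  }
  x <- abs(x)
  x <- x / sqrt(sum(x^2))
  stats::setNames(x, net$vertices)
}

# Spectral radius of the binary adjacency matrix (0 for edgeless graphs).
spectral_radius <- function(net) {
  if (ecount(net) == 0L) return(0)
  A <- adjacency_matrix(net)
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

#' Katz status index
#'
#' Counts walks terminating at each vertex, damping a walk of length k by
#' `alpha^k`: evaluates `((I - alpha * t(A))^-1 - I) %*% 1` by a direct
#' dense solve.  Requires `0 < alpha < 1/lambda_max` for the series to
#' converge.  When `alpha` is omitted it is set to
#' `alpha_fraction / lambda_max`.
#'
#' @param net a [network()] object
#' @param alpha scaling factor; default `alpha_fraction / lambda_max`
#' @param alpha_fraction fraction of the critical value used for the default
#'   alpha (0.5 unless configured otherwise)
#' @return named numeric vector; isolated vertices score 0
#' @export
katz_index <- function(net, alpha = NULL, alpha_fraction = 0.5) {
  lam <- spectral_radius(net)
  if (is.null(alpha)) {
    alpha <- if (lam > 0) alpha_fraction / lam else alpha_fraction
  }
  if (alpha <= 0) stop("alpha must be positive")
  if (lam > 0 && alpha >= 1 / lam) {
    stop(sprintf(
      "alpha = %g >= 1/lambda_max = %g: the Katz walk series diverges",
      alpha, 1 / lam))
  }
  A <- adjacency_matrix(net)
  n <- vcount(net)
  x <- solve(diag(n) - alpha * t(A), rep(1, n)) - 1
  x[abs(x) < .Machine$double.eps * n * 10] <- 0  # keep isolated rows at exact 0
  stats::setNames(x, net$vertices)
}

#' Subgraph centrality
#'
#' Weighted count of closed walks through each vertex,
#' `sum_k (A^k)_vv / k!`, i.e. the diagonal of the matrix exponential of A,
#' evaluated through the symmetric eigendecomposition
#' `sum_j u_j(v)^2 exp(lambda_j)`.
#'
#' @param net a [network()] object
#' @return named numeric vector, every entry >= 1 (the k = 0 term)
#' @export
subgraph_centrality <- function(net) {
  n <- vcount(net)
  if (ecount(net) == 0L) {
    return(stats::setNames(rep(1, n), net$vertices))
  }
  es <- eigen(adjacency_matrix(net), symmetric = TRUE)
  sc <- as.vector((es$vectors^2) %*% exp(es$values))
  stats::setNames(sc, net$vertices)
}

#' Partition a network into modules
#'
#' Default is greedy modularity maximization (fast-greedy agglomeration);
#' method `"components"` uses connected components.  The result feeds the
#' within-module z-score.
#'
#' @param net a [network()] object
#' @param method `"greedy"` or `"components"`
#' @return named integer vector mapping each vertex to a module id
#'   (contiguous, starting at 1)
#' @export
detect_modules <- function(net, method = c("greedy", "components")) {
  method <- match.arg(method)
  g <- as_igraph(net)
  memb <- switch(method,
    greedy = {
      cl <- igraph::cluster_fast_greedy(g, weights = NULL)
      igraph::membership(cl)
    },
    components = igraph::components(g)$membership
  )
  memb <- as.integer(factor(as.integer(memb)))
  stats::setNames(memb, net$vertices)
}

#' Within-module z-score
#'
#' Standardized within-module degree: `z_i = (k_i - mean_k) / sd_k` where
#' `k_i` counts edges from i to vertices of its own module and mean/sd are
#' taken over that module (population standard deviation).  Modules with
#' zero spread give z = 0.
#'
#' @param net a [network()] object
#' @param modules named integer vector from [detect_modules()] covering all
#'   vertices
#' @return named numeric vector
#' @export
within_module_zscore <- function(net, modules = NULL) {
  if (is.null(modules)) modules <- detect_modules(net)
  if (!all(net$vertices %in% names(modules))) {
    stop("`modules` must assign a module to every vertex")
  }
  m <- as.integer(modules[net$vertices])
  adj <- adjacency_list(net)
  n <- vcount(net)
  k <- vapply(seq_len(n), function(v) sum(m[adj[[v]]] == m[v]), 0L)
  z <- numeric(n)
  for (mod in unique(m)) {
    idx <- which(m == mod)
    mu <- mean(k[idx])
    s <- sqrt(mean((k[idx] - mu)^2))
    if (s > 0) z[idx] <- (k[idx] - mu) / s
  }
  stats::setNames(z, net$vertices)
}

#' k-step Markov centrality
#'
#' Probability that a k-step random walk, started from the uniform
#' distribution over a root set R (default: all vertices), ends at each
#' vertex.  The transition matrix is the row-normalized weighted adjacency,
#' so out-probabilities sum to 1; degree-0 vertices are absorbing.  The
#' default walk length is 6 steps.
#'
#' @param net a [network()] object
#' @param k number of steps (>= 0)
#' @param start optional character vector of root vertices
#' @return named probability vector (sums to 1)
#' @export
k_step_markov <- function(net, k = 6L, start = NULL) {
  if (k < 0) stop("k must be nonnegative")
  n <- vcount(net)
  W <- adjacency_matrix(net, weighted = TRUE)
  strength <- rowSums(W)
  Tm <- W / ifelse(strength > 0, strength, 1)
  absorbing <- which(strength == 0)
  if (length(absorbing) > 0L) {
    Tm[cbind(absorbing, absorbing)] <- 1
  }
  p <- rep(0, n)
  if (is.null(start)) {
    p[] <- 1 / n
  } else {
    idx <- match(trimws(start), net$vertices)
    if (anyNA(idx)) {
      stop(sprintf("unknown start vertex '%s'", start[which(is.na(idx))[1L]]))
    }
    p[unique(idx)] <- 1 / length(unique(idx))
  }
  for (step in seq_len(k)) {
    p <- as.vector(p %*% Tm)
  }
  stats::setNames(p, net$vertices)
}

#' Burt's aggregate structural-hole constraint
#'
#' For each vertex i, `C_i = sum_{j in N(i)} (p_ij + sum_{q != i,j} p_iq *
#' p_qj)^2` with proportional tie strength `p_ij = w_ij / sum_q w_iq` (equal
#' to `1/deg(i)` when unweighted).  Low constraint marks brokers spanning
#' otherwise disconnected neighbours; the raw constraint is reported (no
#' `1 - C` transform).  Isolated vertices score 0.
#'
#' @param net a [network()] object
#' @return named nonnegative numeric vector
#' @export
structural_holes <- function(net) {
  n <- vcount(net)
  W <- adjacency_matrix(net, weighted = TRUE)
  strength <- rowSums(W)
  P <- W / ifelse(strength > 0, strength, 1)
  inner <- P + P %*% P       # diag(P) = 0, so q = i, j terms vanish
  mask <- adjacency_matrix(net) > 0
  ci <- rowSums((inner * mask)^2)
  stats::setNames(ci, net$vertices)
}

#' Compute the full 13-feature topology table
#'
#' Runs every measure and assembles the feature table in the fixed
#' [feature_names()] column order.  Geodesic-based measures treat every edge
#' as unit length; edge weights enter only the random-walk transition
#' probabilities and the structural-hole tie proportions.
#'
#' @param net a [network()] object
#' @param config optional list of settings: `katz` (`alpha`,
#'   `alpha_fraction`), `markov` (`k`, `start`), `modules` (`method`),
#'   `eigen` (`tol`, `max_iter`)
#' @return data.frame with columns `vertex` and the 13 features
#' @export
compute_all <- function(net, config = list()) {
  cfg <- utils::modifyList(
    list(katz = list(alpha = NULL, alpha_fraction = 0.5),
         markov = list(k = 6L, start = NULL),
         modules = list(method = "greedy"),
         eigen = list(tol = 1e-10, max_iter = 10000L)),
    config)
  sp <- shortest_paths(net)
  modules <- detect_modules(net, method = cfg$modules$method)
  out <- data.frame(
    vertex = net$vertices,
    degree = unname(degree(net)),
    coreness = unname(coreness(net)),
    clustering_coefficient = unname(clustering_coefficient(net)),
    betweenness = unname(betweenness(net)),
    closeness = unname(closeness(net, sp)),
    proximity_prestige = unname(proximity_prestige(net, sp)),
    barycenter = unname(barycenter(net, sp)),
    eigenvector = unname(eigenvector_centrality(net, tol = cfg$eigen$tol,
                                                max_iter = cfg$eigen$max_iter)),
    katz = unname(katz_index(net, alpha = cfg$katz$alpha,
                             alpha_fraction = cfg$katz$alpha_fraction)),
    subgraph = unname(subgraph_centrality(net)),
    within_module_z = unname(within_module_zscore(net, modules)),
    k_step_markov = unname(k_step_markov(net, k = cfg$markov$k,
                                         start = cfg$markov$start)),
    structural_holes = unname(structural_holes(net)),
    stringsAsFactors = FALSE
  )
  out
}
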