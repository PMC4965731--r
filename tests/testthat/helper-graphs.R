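# Small graph builders -------------------------------------------------------

g_path <- function(n) {
  v <- letters[seq_len(n)]
  network(cbind(v[-n], v[-1]))
}

g_complete <- function(n) {
  v <- letters[seq_len(n)]
  network(t(combn(v, 2)))
}

g_star <- function(k) {
  network(cbind("hub", paste0("leaf", seq_len(k))))
}

g_cycle <- function(n) {
  v <- letters[seq_len(n)]
  network(cbind(v, v[c(2:n, 1)]))
}

# Connected Erdos-Renyi draw on <= 8 vertices (resamples until connected).
random_connected_graph <- function(seed, n_max = 8L) {
  set.seed(seed)
  repeat {
    n <- sample(4:n_max, 1L)
    p <- runif(1, 0.3, 0.8)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) next
    v <- sprintf("v%02d", seq_len(n))
    net <- network(cbind(v[pairs[keep, 1L]], v[pairs[keep, 2L]]),
                   vertices = v)
    if (oracle_is_connected(net)) return(net)
  }
}

# Brute-force oracles ---------------------------------------------------------
# All independent of the package implementations: path enumeration, explicit
# series, dense linear algebra.

oracle_adj_matrix <- function(net) adjacency_matrix(net)

oracle_is_connected <- function(net) {
  A <- oracle_adj_matrix(net)
  n <- nrow(A)
  if (n <= 1L) return(TRUE)
  reach <- (diag(n) + A) > 0
  for (i in seq_len(n)) reach <- (reach %*% reach) > 0
  all(reach[1L, ])
}

# Enumerate every simple path between every ordered pair by DFS.  Returns,
# per ordered pair, the geodesic length, the geodesic count, and the list of
# geodesics (vertex index sequences).
oracle_geodesics <- function(net) {
  adj <- adjacency_list(net)
  n <- length(adj)
  geo <- vector("list", n * n)
  dim(geo) <- c(n, n)
  dist <- matrix(Inf, n, n)
  count <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    count[s, s] <- 1
    for (t in seq_len(n)) {
      if (t == s) next
      paths <- list()
      dfs <- function(v, visited, path) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- path
          return(invisible())
        }
        for (w in adj[[v]]) {
          if (!visited[w]) {
            visited[w] <- TRUE
            dfs(w, visited, c(path, w))
            visited[w] <- FALSE
          }
        }
      }
      visited <- rep(FALSE, n)
      visited[s] <- TRUE
      dfs(s, visited, s)
      if (length(paths) > 0L) {
        lens <- lengths(paths) - 1L
        d <- min(lens)
        dist[s, t] <- d
        geod <- paths[lens == d]
        count[s, t] <- length(geod)
        geo[[s, t]] <- geod
      }
    }
  }
  dimnames(dist) <- dimnames(count) <- list(net$vertices, net$vertices)
  list(dist = dist, count = count, geodesics = geo)
}

oracle_betweenness <- function(net, geo = oracle_geodesics(net)) {
  n <- vcount(net)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(geo$dist[s, t])) next
    paths <- geo$geodesics[[s, t]]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / length(paths)
    }
  }
  stats::setNames(bc, net$vertices)
}

oracle_closeness <- function(net, geo = oracle_geodesics(net)) {
  d <- geo$dist
  diag(d) <- Inf
  rowSums(1 / d)
}

oracle_proximity_prestige <- function(net, geo = oracle_geodesics(net)) {
  d <- geo$dist
  diag(d) <- Inf
  n <- nrow(d)
  sapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]))
    if (length(reach) == 0L) return(0)
    (length(reach) / (n - 1)) / (sum(d[v, reach]) / length(reach))
  })
}

oracle_barycenter <- function(net, geo = oracle_geodesics(net)) {
  d <- geo$dist
  diag(d) <- Inf
  sapply(seq_len(nrow(d)), function(v) {
    tot <- sum(d[v, is.finite(d[v, ])])
    if (tot > 0) 1 / tot else 0
  })
}

# Peel for each k explicitly: coreness(v) = largest k whose k-core keeps v.
oracle_coreness <- function(net) {
  A <- oracle_adj_matrix(net)
  n <- nrow(A)
  core <- integer(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      drop <- alive
      drop[alive] <- deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
      if (!any(alive)) break
    }
    core[alive] <- k
  }
  core
}

oracle_clustering <- function(net) {
  A <- oracle_adj_matrix(net)
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
}

oracle_subgraph <- function(net, k_max = 30L) {
  A <- oracle_adj_matrix(net)
  n <- nrow(A)
  acc <- diag(n)
  Ak <- diag(n)
  for (k in seq_len(k_max)) {
    Ak <- Ak %*% A
    acc <- acc + Ak / factorial(k)
  }
  diag(acc)
}

oracle_katz <- function(net, alpha) {
  A <- oracle_adj_matrix(net)
  n <- nrow(A)
  as.vector((solve(diag(n) - alpha * t(A)) - diag(n)) %*% rep(1, n))
}

oracle_eigenvector <- function(net) {
  es <- eigen(oracle_adj_matrix(net), symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

oracle_k_step_markov <- function(net, k, start = NULL) {
  W <- adjacency_matrix(net, weighted = TRUE)
  s <- rowSums(W)
  Tm <- W / ifelse(s > 0, s, 1)
  iso <- which(s == 0)
  if (length(iso)) Tm[cbind(iso, iso)] <- 1
  Tk <- diag(nrow(W))
  for (i in seq_len(k)) Tk <- Tk %*% Tm
  n <- nrow(W)
  p0 <- rep(0, n)
  if (is.null(start)) p0[] <- 1 / n else {
    idx <- match(start, net$vertices)
    p0[idx] <- 1 / length(idx)
  }
  as.vector(p0 %*% Tk)
}

oracle_constraint <- function(net) {
  W <- adjacency_matrix(net, weighted = TRUE)
  n <- nrow(W)
  s <- rowSums(W)
  P <- W / ifelse(s > 0, s, 1)
  sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) == 0L) return(0)
    sum(sapply(nb, function(j) {
      ind <- 0
      for (q in seq_len(n)) {
        if (q != i && q != j) ind <- ind + P[i, q] * P[q, j]
      }
      (P[i, j] + ind)^2
    }))
  })
}

oracle_within_module_z <- function(net, modules) {
  A <- oracle_adj_matrix(net)
  m <- as.integer(modules[net$vertices])
  n <- nrow(A)
  k <- sapply(seq_len(n), function(v) sum(A[v, m == m[v]]))
  z <- numeric(n)
  for (mod in unique(m)) {
    idx <- which(m == mod)
    mu <- mean(k[idx])
    s <- sqrt(mean((k[idx] - mu)^2))
    if (s > 0) z[idx] <- (k[idx] - mu) / s
  }
  z
}

# Newman modularity of a partition (unweighted).
oracle_modularity <- function(net, membership) {
  A <- oracle_adj_matrix(net)
  m2 <- sum(A)
  deg <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(deg, deg) / m2) * same) / m2
}

# Random labeled datasets -----------------------------------------------------

random_labeled_dataset <- function(seed, n_features = 3L) {
  set.seed(seed)
  n_min <- sample(3:10, 1L)
  n_maj <- n_min + sample(2:20, 1L)
  X <- matrix(rnorm((n_min + n_maj) * n_features), ncol = n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  df <- as.data.frame(X)
  df <- cbind(vertex = sprintf("r%03d", seq_len(nrow(df))), df)
  df$label <- c(rep(1L, n_min), rep(0L, n_maj))
  df$provenance <- "original"
  df
}

# Clearly separable two-feature dataset with a rare positive class.
separable_dataset <- function(n = 200L, pos_frac = 0.05, seed = 1L) {
  set.seed(seed)
  n_pos <- max(2L, round(n * pos_frac))
  n_neg <- n - n_pos
  df <- data.frame(
    vertex = sprintf("s%04d", seq_len(n)),
    x1 = c(rnorm(n_pos, 4), rnorm(n_neg, 0)),
    x2 = c(rnorm(n_pos, 4), rnorm(n_neg, 0)),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    provenance = "original",
    stringsAsFactors = FALSE
  )
  df[sample(n), ]
}
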