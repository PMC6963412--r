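# Exhaustive shortest-path oracle, independent of igraph: enumerates every
# simple path between every ordered node pair by depth-first search, then
# derives distances, geodesic counts, betweenness, closeness and the
# characteristic path length from first principles. Only usable for tiny
# graphs (<= 8 nodes).

enumerateSimplePaths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (adj[v, w] == 1L && !visited[w]) {
        vis <- visited
        vis[w] <- TRUE
        walk(w, vis, c(path, w))
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  walk(s, visited, s)
  paths
}

oracleTopology <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  geodesics <- vector("list", n * n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- enumerateSimplePaths(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1)) - 1L
      dmat[s, t] <- min(lens)
      geodesics[[(s - 1L) * n + t]] <- paths[lens == min(lens)]
    }
  }

  betweenness <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      geo <- geodesics[[(s - 1L) * n + t]]
      if (is.null(geo) || !length(geo)) next
      sigma <- length(geo)
      inner <- unlist(lapply(geo, function(p) p[-c(1L, length(p))]))
      if (length(inner)) {
        counts <- tabulate(inner, nbins = n)
        betweenness <- betweenness + counts / sigma
      }
    }
  }
  if (n > 2L) betweenness <- betweenness * 2 / ((n - 1) * (n - 2))

  closeness <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(dmat[v, ]))
    if (length(reach) < 2L) return(0)
    (length(reach) - 1) / sum(dmat[v, reach])
  }, numeric(1))

  finite <- dmat[is.finite(dmat) & dmat > 0]
  cpl <- if (length(finite)) mean(finite) else NA_real_

  list(betweenness = betweenness, closeness = closeness, cpl = cpl,
       distances = dmat)
}

randomAdjacency <- function(n, p, rng) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adjacencyToNetwork <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(gene_a = nodes[idx[, 1L]], gene_b = nodes[idx[, 2L]],
                      r = rep(0.9, nrow(idx)), p = rep(0.001, nrow(idx)),
                      sign = rep("+", nrow(idx)), stringsAsFactors = FALSE)
  buildNetwork(edges, nodes = nodes)
}

# small helper: LeafExpression from a bare matrix with default metadata
makeExpression <- function(m, unit = "counts", lengths = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  LeafExpression(m, geneLengths = lengths, unit = unit)
}
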