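#' All pairwise Pearson correlations with significance
#'
#' Computes r for every unordered gene pair across samples, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x genes-by-samples matrix of log2(RPKM + 1) values over all
#'   samples, or a [LeafExpression-class] (constant-flagged genes dropped).
#'   At least 3 samples are required.
#' @return A list of class `correlationCandidates`: `r` and `p` (symmetric
#'   gene x gene matrices) and `n` (sample count).
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' cand <- pairwiseCorrelation(m)
#' range(cand$r[upper.tri(cand$r)])
#' @export
pairwiseCorrelation <- function(x) {
  m <- .profileMatrix(x)
  n <- ncol(m)
  if (n < 3L) stop("at least 3 samples are required for correlation")
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    stop("constant gene profile(s) must be excluded: ",
         paste(utils::head(rownames(m)[sds == 0], 5L), collapse = ", "))
  }
  r <- cor(t(m))
  r[r > 1] <- 1
  r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  diag(p) <- 1
  structure(list(r = r, p = p, n = n), class = "correlationCandidates")
}

#' Threshold correlation candidates into network edges
#'
#' Keeps unordered pairs with `|r| >= minAbsR` and `p <= alpha`, both
#' inclusive; raising `minAbsR` never adds edges.
#'
#' @param candidates output of [pairwiseCorrelation()].
#' @param minAbsR inclusive absolute-correlation threshold.
#' @param alpha inclusive p-value threshold.
#' @return data.frame of edges (`gene_a < gene_b`, `r`, `p`,
#'   `sign` in `{"+", "-"}`).
#' @export
thresholdEdges <- function(candidates, minAbsR = 0.8, alpha = 0.05) {
  stopifnot(inherits(candidates, "correlationCandidates"))
  r <- candidates$r
  p <- candidates$p
  keep <- upper.tri(r) & abs(r) >= minAbsR & p <= alpha
  idx <- which(keep, arr.ind = TRUE)
  genes <- rownames(r)
  a <- genes[idx[, 1L]]
  b <- genes[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      r = r[idx], p = p[idx],
                      sign = ifelse(r[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

#' Assemble a co-expression network from an edge list
#'
#' @param edges edge data.frame from [thresholdEdges()].
#' @param nodes optional node set; defaults to the genes incident to at
#'   least one edge.
#' @return A [CoexpressionNetwork-class] (topology metrics unset; call
#'   [topology()]).
#' @export
buildNetwork <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  rownames(edges) <- NULL
  new("CoexpressionNetwork", nodes = nodes, edges = edges,
      nodeMetrics = data.frame(), graphMetrics = list())
}

.asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = net@nodes)
  )
  g
}

#' Topology metrics of a co-expression network
#'
#' Treats the graph as simple, undirected and unweighted (the correlation
#' sign is an edge attribute only) and computes, per node: degree;
#' betweenness centrality (Brandes' algorithm, normalized by
#' `2 / ((n - 1)(n - 2))`); closeness `(n_c - 1) / sum(d)` where the sum of
#' shortest-path distances runs over the node's connected component of size
#' `n_c`; and the local clustering coefficient
#' `2 T(v) / (deg(v) (deg(v) - 1))`, 0 for degree < 2. Graph-level metrics:
#' the global clustering coefficient (mean local coefficient — by default
#' including degree-< 2 nodes as 0; set `clusteringConvention =
#' "excludeLow"` for the other common convention), the characteristic path
#' length (mean shortest-path length over all connected ordered pairs;
#' disconnected pairs are excluded), and the component sizes.
#'
#' @param net a [CoexpressionNetwork-class] with at least one node.
#' @param clusteringConvention `"includeLow"` (default) or `"excludeLow"`:
#'   whether degree-< 2 nodes enter the global clustering coefficient mean.
#' @return `net` with `nodeMetrics` and `graphMetrics` populated.
#' @examples
#' edges <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
#'                     r = c(0.9, 0.95), p = c(0.001, 0.001),
#'                     sign = c("+", "+"))
#' net <- topology(buildNetwork(edges))
#' nodeMetrics(net)
#' @export
topology <- function(net, clusteringConvention = c("includeLow",
                                                   "excludeLow")) {
  stopifnot(is(net, "CoexpressionNetwork"))
  clusteringConvention <- match.arg(clusteringConvention)
  if (length(net@nodes) == 0L) stop("empty graph")
  g <- .asIgraph(net)
  n <- igraph::vcount(g)

  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = n > 2L)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(local) <- igraph::V(g)$name
  local[deg < 2L] <- 0

  comp <- igraph::components(g)
  dmat <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    members <- comp$membership == comp$membership[i]
    nc <- sum(members)
    if (nc < 2L) return(0)
    (nc - 1) / sum(dmat[i, members])
  }, numeric(1))

  finite <- dmat[is.finite(dmat) & dmat > 0]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  globalCC <- if (clusteringConvention == "includeLow") {
    mean(local)
  } else {
    if (any(deg >= 2L)) mean(local[deg >= 2L]) else NA_real_
  }

  net@nodeMetrics <- data.frame(
    gene = igraph::V(g)$name, degree = as.integer(deg),
    betweenness = unname(btw), closeness = clo,
    clustering = unname(local),
    row.names = igraph::V(g)$name, stringsAsFactors = FALSE
  )
  net@graphMetrics <- list(
    globalClustering = globalCC,
    characteristicPathLength = cpl,
    componentSizes = sort(as.integer(comp$csize), decreasing = TRUE)
  )
  net
}

#' Accessors for CoexpressionNetwork
#'
#' `networkNodes()` and `networkEdges()` return the node set and edge table;
#' `nodeMetrics()` and `graphMetrics()` return the tables populated by
#' [topology()].
#'
#' @param x a [CoexpressionNetwork-class].
#' @return See the individual descriptions.
#' @name CoexpressionNetwork-accessors
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork"))
  x@nodes
}

#' @rdname CoexpressionNetwork-accessors
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork"))
  x@edges
}

#' @rdname CoexpressionNetwork-accessors
#' @export
nodeMetrics <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork"))
  x@nodeMetrics
}

#' @rdname CoexpressionNetwork-accessors
#' @export
graphMetrics <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork"))
  x@graphMetrics
}

.topSet <- function(values, names, count) {
  ord <- order(-values, names)
  cutoff <- values[ord[count]]
  # ties at the cutoff value are included in full
  names[values >= cutoff]
}

#' Joint-centrality hub ranking
#'
#' A hub is a node in the top `percentile` fraction simultaneously for
#' degree, betweenness centrality and closeness centrality. Each top set
#' holds the `ceiling(percentile * n)` best nodes by that metric, extended
#' by any node tied with the value at the cutoff; the hub set is the
#' intersection of the three, ordered by decreasing degree then gene
#' identifier.
#'
#' @param net a [CoexpressionNetwork-class]; [topology()] is applied if
#'   metrics are missing.
#' @param percentile top fraction per metric, in (0, 1].
#' @return Character vector of hub gene identifiers.
#' @export
hubRank <- function(net, percentile = 0.10) {
  stopifnot(is(net, "CoexpressionNetwork"))
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")
  if (!nrow(net@nodeMetrics)) net <- topology(net)
  nm <- net@nodeMetrics
  count <- ceiling(percentile * nrow(nm))
  hubs <- Reduce(intersect, list(
    .topSet(nm$degree, nm$gene, count),
    .topSet(nm$betweenness, nm$gene, count),
    .topSet(nm$closeness, nm$gene, count)
  ))
  hubs[order(-nm[hubs, "degree"], hubs)]
}

#' Gene with the highest number of connections
#'
#' @param net a [CoexpressionNetwork-class] with at least one node.
#' @return The maximal-degree gene; ties are broken lexicographically.
#' @export
maxDegreeGene <- function(net) {
  stopifnot(is(net, "CoexpressionNetwork"))
  if (length(net@nodes) == 0L) stop("empty graph")
  if (!nrow(net@nodeMetrics)) net <- topology(net)
  nm <- net@nodeMetrics
  top <- nm$gene[nm$degree == max(nm$degree)]
  sort(top)[1L]
}

#' Induced subnetwork, optionally re-thresholded
#'
#' Restricts the network to `geneSet` (genes absent from the network are
#' ignored with a warning) and optionally applies a stricter
#' absolute-correlation threshold to the surviving edges, as used for
#' focused module views. Topology metrics are recomputed when the parent
#' had them.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param geneSet genes to keep.
#' @param minAbsR optional stricter `|r|` threshold (e.g. 0.9).
#' @return A [CoexpressionNetwork-class] on the induced subgraph.
#' @export
subnetwork <- function(net, geneSet, minAbsR = NULL) {
  stopifnot(is(net, "CoexpressionNetwork"))
  missing <- setdiff(geneSet, net@nodes)
  if (length(missing)) {
    warning(length(missing), " gene(s) not in the network were ignored")
  }
  keepNodes <- intersect(net@nodes, geneSet)
  e <- net@edges
  e <- e[e$gene_a %in% keepNodes & e$gene_b %in% keepNodes, , drop = FALSE]
  if (!is.null(minAbsR)) e <- e[abs(e$r) >= minAbsR, , drop = FALSE]
  sub <- buildNetwork(e, nodes = keepNodes)
  if (nrow(net@nodeMetrics) && length(keepNodes)) sub <- topology(sub)
  sub
}
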