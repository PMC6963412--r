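.profileMatrix <- function(x) {
  if (is(x, "LeafExpression")) {
    m <- exprs(x)
    rd <- SummarizedExperiment::rowData(x)
    if ("constant" %in% names(rd)) m <- m[!rd$constant, , drop = FALSE]
    m
  } else {
    as.matrix(x)
  }
}

# k-means++ seeding (Arthur & Vassilvitskii): each new center is drawn with
# probability proportional to the squared distance to the nearest chosen one
.kmeansppCenters <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((m - m[rep(centers[1L], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((m - m[rep(centers[j + 1L], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' K-means clustering of expression profiles
#'
#' Lloyd iterations from k-means++ starts, keeping the best of `nInit`
#' restarts by total within-cluster sum of squares. Profiles are clustered
#' in Euclidean space; on per-gene z-scaled profiles the Euclidean and
#' centered-Pearson orderings coincide, which is why the pipeline clusters
#' z-scores. Cluster indices are relabeled by decreasing cluster size, and
#' the fit is deterministic given `seed`.
#'
#' @param x z-scaled profile matrix (genes x conditions) or a
#'   [LeafExpression-class] of unit `"zscore"` (constant-flagged genes are
#'   dropped).
#' @param k number of clusters, `2 <= k <=` number of genes.
#' @param seed integer seed.
#' @param nInit number of k-means++ restarts.
#' @return A [ClusterResult-class].
#' @examples
#' m <- rbind(matrix(rnorm(40, 5), 10, 4), matrix(rnorm(40, -5), 10, 4))
#' rownames(m) <- sprintf("g%02d", 1:20)
#' fit <- kmeansFit(m, k = 2, seed = 1)
#' table(clusterAssignment(fit))
#' @export
kmeansFit <- function(x, k, seed = 1L, nInit = 50L) {
  m <- .profileMatrix(x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(m)) stop("k exceeds the number of gene profiles")
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nInit)) {
    centers <- .kmeansppCenters(m, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(m, centers = centers, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce ", k,
                          " non-empty clusters")

  # canonical labels: decreasing cluster size, ties by first occurrence
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(order(-sizes))
  assignment <- setNames(relabel[best$cluster], rownames(m))
  centroids <- best$centers[order(-sizes), , drop = FALSE]
  rownames(centroids) <- seq_len(k)

  score <- .scoreToCore(m, assignment, centroids)
  new("ClusterResult", k = k, assignment = as.integer(assignment) |>
        setNames(rownames(m)),
      centroids = centroids, scoreToCore = score,
      sse = best$tot.withinss,
      diagnostics = data.frame(), seed = as.integer(seed))
}

.scoreToCore <- function(m, assignment, centroids) {
  score <- vapply(seq_len(nrow(m)), function(i) {
    cen <- centroids[assignment[i], ]
    if (sd(cen) == 0) {
      stop("score to core is undefined against a constant centroid")
    }
    cor(m[i, ], cen)
  }, numeric(1))
  setNames(score, rownames(m))
}

#' Accessors for ClusterResult
#'
#' `clusterAssignment()` returns the named gene -> cluster vector,
#' `centroids()` the k x conditions centroid matrix, `scoreToCore()` each
#' gene's Pearson correlation with its own cluster centroid, and
#' `clusterSSE()` the total within-cluster sum of squares.
#'
#' @param x a [ClusterResult-class].
#' @return See the individual descriptions.
#' @name ClusterResult-accessors
#' @export
clusterAssignment <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@assignment
}

#' @rdname ClusterResult-accessors
#' @export
centroids <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@centroids
}

#' @rdname ClusterResult-accessors
#' @export
scoreToCore <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@scoreToCore
}

#' @rdname ClusterResult-accessors
#' @export
clusterSSE <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@sse
}

#' Per-k clustering diagnostics
#'
#' Fits [kmeansFit()] for every k in `kRange` and reports the total
#' within-cluster sum of squares (SSE), the mean silhouette width (Euclidean
#' distance, via \pkg{cluster}), the Calinski-Harabasz index
#' `(B/(k-1)) / (W/(n-k))` and the maximum pairwise Pearson correlation
#' among the fitted centroids.
#'
#' @inheritParams kmeansFit
#' @param kRange integer vector of cluster numbers to evaluate.
#' @return data.frame with columns `k`, `sse`, `silhouette`, `ch`,
#'   `maxCentroidCorr`.
#' @export
kDiagnostics <- function(x, kRange = 2:15, seed = 1L, nInit = 50L) {
  m <- .profileMatrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > nrow(m))) {
    stop("kRange must lie within [2, number of genes]")
  }
  d <- dist(m)
  totss <- sum(scale(m, scale = FALSE)^2)
  n <- nrow(m)
  rows <- lapply(kRange, function(k) {
    fit <- kmeansFit(m, k, seed = seed, nInit = nInit)
    w <- fit@sse
    b <- totss - w
    ch <- if (n > k && w > 0) (b / (k - 1)) / (w / (n - k)) else Inf
    sil <- mean(cluster::silhouette(as.integer(fit@assignment), d)[, "sil_width"])
    cc <- centroidCorrelationMatrix(fit)
    data.frame(k = k, sse = w, silhouette = sil, ch = ch,
               maxCentroidCorr = max(cc[upper.tri(cc)]))
  })
  do.call(rbind, rows)
}

#' A-posteriori selection of the number of clusters
#'
#' Returns the largest k in `kRange` whose fitted centroids have a maximum
#' pairwise Pearson correlation strictly below `maxCentroidCorr` — the idea
#' being that once two centroids become near-collinear, a true cluster has
#' been split and k is too large. k values are evaluated in descending order
#' and the first success is returned (equivalent to "highest qualifying k").
#' If no k qualifies, `min(kRange)` is returned with attribute
#' `fallback = TRUE` and a warning.
#'
#' @inheritParams kDiagnostics
#' @param maxCentroidCorr exclusive upper bound on centroid correlation.
#' @return Integer k, with attributes `maxCentroidCorr` (realized value at
#'   the selected k) and `fallback`.
#' @export
selectK <- function(x, kRange = 2:15, maxCentroidCorr = 0.8, seed = 1L,
                    nInit = 50L) {
  m <- .profileMatrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  for (k in rev(kRange)) {
    fit <- kmeansFit(m, k, seed = seed, nInit = nInit)
    cc <- centroidCorrelationMatrix(fit)
    realized <- max(cc[upper.tri(cc)])
    if (realized < maxCentroidCorr) {
      return(structure(k, maxCentroidCorr = realized, fallback = FALSE))
    }
  }
  warning("no k in range satisfies the centroid-correlation rule; ",
          "falling back to k = ", min(kRange))
  structure(min(kRange), maxCentroidCorr = NA_real_, fallback = TRUE)
}

#' Gene closest to a cluster core
#'
#' @param result a [ClusterResult-class].
#' @param cluster cluster index.
#' @return The gene with maximal score to core in the cluster; ties are
#'   broken by lexicographic gene identifier.
#' @export
coreDriver <- function(result, cluster) {
  stopifnot(is(result, "ClusterResult"))
  members <- names(result@assignment)[result@assignment == cluster]
  if (!length(members)) stop("cluster ", cluster, " is empty or unknown")
  s <- result@scoreToCore[members]
  members <- members[s == max(s)]
  sort(members)[1L]
}

#' Pearson correlation matrix of cluster centroids
#'
#' The off-diagonal entries quantify how related (or, when strongly
#' negative, how antagonistic) the cluster mean profiles are; the
#' anticorrelated photosynthesis module pair shows up as an entry near -1.
#'
#' @param result a [ClusterResult-class].
#' @return Symmetric k x k correlation matrix with unit diagonal.
#' @export
centroidCorrelationMatrix <- function(result) {
  stopifnot(is(result, "ClusterResult"))
  cc <- cor(t(result@centroids))
  diag(cc) <- 1
  cc
}
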