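#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom MASS mvrnorm
#' @importFrom stats cor dist kmeans rnbinom runif rnorm sd setNames
#'   p.adjust pt phyper
#' @importFrom utils read.delim write.table packageVersion
NULL

.EXPRESSION_UNITS <- c("counts", "RPKM", "log2RPKM", "zscore")

#' Container for a genes-by-samples expression matrix
#'
#' `LeafExpression` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with an explicit
#' expression `unit`. The single assay (`"exprs"`) holds the matrix; sample
#' metadata (`cultivar`, `year`, `replicate`) lives in `colData` and per-gene
#' transcript lengths (`length_bp`, required for RPKM) in `rowData`. Unit
#' transitions are restricted to the pipeline order
#' `counts -> RPKM -> log2RPKM -> zscore`, enforced by the transformation
#' methods rather than by the validity check, so that a matrix read from disk
#' can enter at any declared unit.
#'
#' @slot unit character scalar, one of `"counts"`, `"RPKM"`, `"log2RPKM"`,
#'   `"zscore"`.
#'
#' @seealso [LeafExpression()], [rpkm()], [log2p1()], [zscale()],
#'   [conditionMeans()]
#' @export
setClass("LeafExpression",
  contains = "SummarizedExperiment",
  representation(unit = "character")
)

setValidity("LeafExpression", function(object) {
  msg <- NULL
  if (length(object@unit) != 1L || !object@unit %in% .EXPRESSION_UNITS) {
    msg <- c(msg, sprintf(
      "'unit' must be one of: %s", paste(.EXPRESSION_UNITS, collapse = ", ")
    ))
  }
  if (length(SummarizedExperiment::assays(object)) < 1L) {
    msg <- c(msg, "one assay named 'exprs' is required")
  } else {
    m <- SummarizedExperiment::assay(object)
    if (anyNA(m)) msg <- c(msg, "expression values must not contain NA")
    if (object@unit != "zscore" && any(m < 0)) {
      msg <- c(msg, sprintf("negative values are not allowed for unit '%s'",
                            object@unit))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Result of a K-means fit on expression profiles
#'
#' Cluster indices are canonicalized by decreasing cluster size (cluster 1 is
#' the largest), which makes results comparable across runs up to label
#' permutation.
#'
#' @slot k number of clusters.
#' @slot assignment named integer vector, gene -> cluster index in `1..k`.
#' @slot centroids `k x n_conditions` matrix of cluster mean profiles.
#' @slot scoreToCore named numeric vector: Pearson correlation of each gene
#'   profile with the centroid of its own cluster.
#' @slot sse total within-cluster sum of squared errors.
#' @slot diagnostics per-k diagnostics table (possibly empty) as produced by
#'   [kDiagnostics()].
#' @slot seed integer seed used for the restarts.
#'
#' @seealso [kmeansFit()], [selectK()], [coreDriver()],
#'   [centroidCorrelationMatrix()]
#' @export
setClass("ClusterResult", representation(
  k = "integer",
  assignment = "integer",
  centroids = "matrix",
  scoreToCore = "numeric",
  sse = "numeric",
  diagnostics = "data.frame",
  seed = "integer"
))

setValidity("ClusterResult", function(object) {
  msg <- NULL
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@assignment))) {
    msg <- c(msg, "assignment must be named by gene")
  }
  if (length(object@assignment) &&
      !all(object@assignment %in% seq_len(object@k))) {
    msg <- c(msg, "assignment values must lie in 1..k")
  }
  if (length(unique(object@assignment)) != object@k) {
    msg <- c(msg, "every cluster must be non-empty")
  }
  if (nrow(object@centroids) != object@k) {
    msg <- c(msg, "centroids must have one row per cluster")
  }
  s <- object@scoreToCore
  if (length(s) && (any(s < -1 - 1e-8) || any(s > 1 + 1e-8))) {
    msg <- c(msg, "scoreToCore must lie in [-1, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Thresholded gene co-expression network
#'
#' An undirected simple graph over genes. Each edge carries the Pearson
#' correlation `r`, its two-sided p-value and the correlation sign; the graph
#' itself is treated as unweighted and unsigned for all topology metrics.
#' Nodes are the genes incident to at least one retained edge.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `r`, `p`, `sign`.
#' @slot nodeMetrics data.frame of per-node `degree`, `betweenness`
#'   (normalized), `closeness`, `clustering` (local clustering coefficient);
#'   empty until [topology()] is called.
#' @slot graphMetrics list with `globalClustering`, `characteristicPathLength`
#'   and `componentSizes`; empty until [topology()] is called.
#'
#' @seealso [buildNetwork()], [topology()], [hubRank()], [subnetwork()]
#' @export
setClass("CoexpressionNetwork", representation(
  nodes = "character",
  edges = "data.frame",
  nodeMetrics = "data.frame",
  graphMetrics = "list"
))

setValidity("CoexpressionNetwork", function(object) {
  msg <- NULL
  e <- object@edges
  need <- c("gene_a", "gene_b", "r", "p", "sign")
  if (!all(need %in% names(e))) {
    msg <- c(msg, sprintf("edges must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$gene_a >= e$gene_b)) {
      msg <- c(msg, "edges must be stored with gene_a < gene_b")
    }
    if (anyDuplicated(paste(e$gene_a, e$gene_b))) {
      msg <- c(msg, "at most one edge per unordered gene pair")
    }
    if (!all(e$sign %in% c("+", "-"))) msg <- c(msg, "sign must be '+' or '-'")
    if (!all(unique(c(e$gene_a, e$gene_b)) %in% object@nodes)) {
      msg <- c(msg, "all edge endpoints must be listed in nodes")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-stage attrition report of the database construction filters
#'
#' @slot stages data.frame with columns `stage`, `n_in`, `n_removed`, `n_out`;
#'   the out-count of each stage equals the in-count of the next.
#' @slot survivors character vector of gene identifiers surviving all stages.
#'
#' @seealso [buildDatabase()]
#' @export
setClass("FilterReport", representation(
  stages = "data.frame",
  survivors = "character"
))

setValidity("FilterReport", function(object) {
  st <- object@stages
  msg <- NULL
  if (!all(c("stage", "n_in", "n_removed", "n_out") %in% names(st))) {
    msg <- c(msg, "stages needs columns stage, n_in, n_removed, n_out")
  } else if (nrow(st)) {
    if (!all(st$n_out == st$n_in - st$n_removed)) {
      msg <- c(msg, "n_out must equal n_in - n_removed at every stage")
    }
    if (nrow(st) > 1L &&
        !all(st$n_in[-1L] == st$n_out[-nrow(st)])) {
      msg <- c(msg, "out-count of stage i must equal in-count of stage i+1")
    }
    if (length(object@survivors) != st$n_out[nrow(st)]) {
      msg <- c(msg, "survivor count must match the final stage out-count")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic leaf RNA-seq simulator
#'
#' Defaults emulate the study design the package targets: 23 samples from
#' four cultivars grown in two production years (three replicates each, one
#' cultivar-year with two), two strongly anticorrelated expression modules of
#' 465 and 281 genes, 1100 uncorrelated background genes, and a latent-factor
#' cross-module correlation target of -0.97.
#'
#' @slot nSamples total number of samples.
#' @slot design data.frame with columns `cultivar`, `year`, `replicates`;
#'   replicate counts must sum to `nSamples`.
#' @slot moduleSpecs data.frame with columns `module`, `nGenes`, `sign`
#'   (+1/-1 latent loading sign), `loading` (magnitude in (0, 1]).
#' @slot nBackgroundGenes number of independent background genes.
#' @slot nHubGenes number of planted hub genes per module.
#' @slot hubExtraTargets number of background genes recruited per hub.
#' @slot loadingSpread per-gene loading heterogeneity: module gene loadings
#'   are drawn uniformly from `[loading - loadingSpread, loading]`.
#' @slot hubLoading loading given to hub genes (the top of the gradient).
#' @slot targetLoading secondary loading given to hub-target background
#'   genes.
#' @slot hubDispersion negative-binomial dispersion of hub genes; hubs are
#'   core genes with tight profiles, so their default noise is low.
#' @slot baselineMean baseline negative-binomial mean count.
#' @slot nbDispersion negative-binomial dispersion (1/size).
#' @slot geneLengthRange integer length-2 vector, uniform range of transcript
#'   lengths in bp.
#' @slot targetCrossModuleCorr target latent correlation between the two
#'   module factors, in \[-1, 0).
#' @slot nSilentGenes number of background genes simulated as near-silent
#'   (these fail the leaf-expression filter by construction).
#' @slot seed integer seed; all randomness is drawn from one stream.
#'
#' @seealso [simulationConfig()], [simulateCounts()]
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer",
  design = "data.frame",
  moduleSpecs = "data.frame",
  nBackgroundGenes = "integer",
  nHubGenes = "integer",
  hubExtraTargets = "integer",
  loadingSpread = "numeric",
  hubLoading = "numeric",
  targetLoading = "numeric",
  hubDispersion = "numeric",
  baselineMean = "numeric",
  nbDispersion = "numeric",
  geneLengthRange = "integer",
  targetCrossModuleCorr = "numeric",
  nSilentGenes = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (sum(object@design$replicates) != object@nSamples) {
    msg <- c(msg, "design replicate counts must sum to nSamples")
  }
  ms <- object@moduleSpecs
  if (nrow(ms)) {
    if (any(ms$nGenes < 2L)) msg <- c(msg, "module sizes must be >= 2")
    if (any(ms$loading <= 0 | ms$loading > 1)) {
      msg <- c(msg, "loading magnitudes must lie in (0, 1]")
    }
    if (!all(ms$sign %in% c(-1, 1))) msg <- c(msg, "module signs must be +-1")
  }
  if (nrow(ms) > 2L) {
    msg <- c(msg, "at most one anticorrelated module pair is supported")
  }
  if (object@nBackgroundGenes < 0L) msg <- c(msg, "nBackgroundGenes < 0")
  if (object@nSilentGenes > object@nBackgroundGenes) {
    msg <- c(msg, "nSilentGenes cannot exceed nBackgroundGenes")
  }
  if (any(object@geneLengthRange < 1L)) {
    msg <- c(msg, "gene lengths must be >= 1 bp")
  }
  if (length(object@targetCrossModuleCorr) != 1L ||
      object@targetCrossModuleCorr >= 0 ||
      object@targetCrossModuleCorr < -1) {
    msg <- c(msg, "targetCrossModuleCorr must lie in [-1, 0)")
  }
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (nrow(ms) * object@nHubGenes * object@hubExtraTargets >
      object@nBackgroundGenes - object@nSilentGenes) {
    msg <- c(msg, "not enough background genes to host all hub targets")
  }
  if (object@loadingSpread < 0 ||
      (nrow(ms) && object@loadingSpread >= min(ms$loading))) {
    msg <- c(msg, "loadingSpread must lie in [0, min module loading)")
  }
  if (object@hubLoading <= 0 || object@hubLoading > 1) {
    msg <- c(msg, "hubLoading must lie in (0, 1]")
  }
  if (object@targetLoading <= 0 || object@targetLoading > 1) {
    msg <- c(msg, "targetLoading must lie in (0, 1]")
  }
  if (object@hubDispersion < 0) msg <- c(msg, "hubDispersion must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LeafExpression", function(object) {
  cat(sprintf("LeafExpression: %d genes x %d samples [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  callNextMethod()
})

setMethod("show", "ClusterResult", function(object) {
  sizes <- table(object@assignment)
  cat(sprintf("ClusterResult: k = %d over %d genes (SSE = %.4g)\n",
              object@k, length(object@assignment), object@sse))
  cat("  cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (length(object@graphMetrics)) {
    cat(sprintf("  global clustering coefficient: %.3f\n",
                object@graphMetrics$globalClustering))
    cat(sprintf("  characteristic path length: %.3f\n",
                object@graphMetrics$characteristicPathLength))
  }
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@stages, row.names = FALSE)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d samples, %d module genes + %d background (seed %d)\n",
    object@nSamples, sum(object@moduleSpecs$nGenes),
    object@nBackgroundGenes, object@seed
  ))
})
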