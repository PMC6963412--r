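#' Validated pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its documented
#' default: genome-hit, full-length and leaf-expression database filters;
#' the co-expression |r| and p thresholds; the stricter subnetwork |r|; the
#' joint hub percentile; the DEG thresholds; the centroid-correlation bound
#' and k range for cluster-number selection. Values outside their documented
#' domain raise an error naming the offending key.
#'
#' @param ... overrides of the defaults listed below.
#' @return A named list of class `pipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(seed = 42L)
#' cfg$min_abs_r
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    fl_min = 0.7, genome_hits_max = 1L,
    expr_min_count = 10, expr_occupancy = 0.9,
    min_abs_r = 0.8, alpha = 0.05, subnet_min_abs_r = 0.9,
    hub_percentile = 0.10,
    fdr_max = 0.05, min_abs_lfc = 1.0,
    max_centroid_corr = 0.8, k_range = 2:15, n_init = 50L,
    clustering_convention = "includeLow",
    go_term = "GO:0044767", min_score_to_core = 0.893,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  .validateConfig(cfg)
  structure(cfg, class = "pipelineConfig")
}

.validateConfig <- function(cfg) {
  inUnit <- function(key, lo = 0, hi = 1) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi) {
      stop("invalid value for '", key, "': must be a number in [",
           lo, ", ", hi, "]")
    }
  }
  inUnit("fl_min"); inUnit("expr_occupancy"); inUnit("alpha")
  inUnit("min_abs_r"); inUnit("subnet_min_abs_r"); inUnit("fdr_max")
  inUnit("max_centroid_corr")
  if (cfg$hub_percentile <= 0 || cfg$hub_percentile > 1) {
    stop("invalid value for 'hub_percentile': must lie in (0, 1]")
  }
  if (cfg$genome_hits_max < 0) stop("invalid value for 'genome_hits_max'")
  if (cfg$expr_min_count < 0) stop("invalid value for 'expr_min_count'")
  if (cfg$min_abs_lfc < 0) stop("invalid value for 'min_abs_lfc'")
  if (any(cfg$k_range < 2L)) stop("invalid value for 'k_range': minimum 2")
  if (!cfg$clustering_convention %in% c("includeLow", "excludeLow")) {
    stop("invalid value for 'clustering_convention'")
  }
  invisible(cfg)
}

.writeTsv <- function(d, path, rowNames = FALSE) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = rowNames,
              col.names = TRUE)
}

#' Export an edge list and a Cytoscape SIF file
#'
#' `writeEdgeList()` writes the tab-separated `gene_a, gene_b, r, p, sign`
#' table; `writeSif()` writes the Cytoscape simple-interaction format
#' (`geneA <tab> interaction <tab> geneB`, the interaction being `pos` or
#' `neg` by correlation sign).
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @name network-export
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "CoexpressionNetwork"))
  .writeTsv(networkEdges(net), path)
  invisible(path)
}

#' @rdname network-export
#' @export
writeSif <- function(net, path) {
  stopifnot(is(net, "CoexpressionNetwork"))
  e <- networkEdges(net)
  sif <- data.frame(geneA = e$gene_a,
                    interaction = ifelse(e$sign == "+", "pos", "neg"),
                    geneB = e$gene_b)
  write.table(sif, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by the pipeline
#'
#' Reads a genes-by-samples TSV (gene identifiers in the first column)
#' together with its JSON sidecar (`<file>.json`) recording the unit, and
#' optionally a sample-metadata TSV.
#'
#' @param path matrix TSV path.
#' @param sampleInfoPath optional sample metadata TSV (columns `sample`,
#'   `cultivar`, `year`, `replicate`).
#' @return A [LeafExpression-class].
#' @export
readExpressionTsv <- function(path, sampleInfoPath = NULL) {
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
  sidecarPath <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecarPath)) {
    jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  } else list(unit = "counts")
  info <- NULL
  if (!is.null(sampleInfoPath)) {
    info <- read.delim(sampleInfoPath)
    rownames(info) <- info$sample
    info <- info[colnames(m), setdiff(names(info), "sample"), drop = FALSE]
  }
  x <- LeafExpression(m, sampleInfo = info, unit = sidecar$unit)
  if (!is.null(sidecar$mappedTotals)) {
    S4Vectors::metadata(x)$mappedTotals <-
      unlist(sidecar$mappedTotals)[colnames(m)]
  }
  x
}

#' Write an expression matrix with its unit sidecar
#'
#' @param x a [LeafExpression-class].
#' @param path output TSV path; the unit goes to `<path>.json`.
#' @return The path, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
  stopifnot(is(x, "LeafExpression"))
  d <- data.frame(gene_id = rownames(x), exprs(x), check.names = FALSE)
  .writeTsv(d, path)
  sidecar <- list(unit = expressionUnit(x))
  mt <- S4Vectors::metadata(x)$mappedTotals
  if (!is.null(mt)) sidecar$mappedTotals <- as.list(mt)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over flat-file artifacts in `outDir` so that any
#' stage can be re-run from its persisted inputs: `simulate` (synthetic
#' counts, annotation, ground truth), `build-db` (database filters),
#' `normalize` (RPKM and log2 transforms), `cluster` (condition means,
#' k selection, K-means fit), `network` (pairwise correlation, thresholded
#' edges, topology), `hubs` (joint-centrality ranking), `associate`
#' (developmental-gene hits) and `all`. A JSON run manifest (configuration,
#' seed, package version, stage timings) is always written.
#'
#' @param stage one of `"simulate"`, `"build-db"`, `"normalize"`,
#'   `"cluster"`, `"network"`, `"hubs"`, `"associate"`, `"all"`.
#' @param config a [pipelineConfig()] list.
#' @param outDir artifact directory (created if missing).
#' @param simConfig optional [SimulationConfig-class] for the simulate
#'   stage; defaults to `simulationConfig(seed = config$seed)`.
#' @return Invisibly, a list of the stage results produced in this call.
#' @export
runPipeline <- function(stage = "all", config = pipelineConfig(),
                        outDir = tempfile("leafgcn_"), simConfig = NULL) {
  stages <- c("simulate", "build-db", "normalize", "cluster", "network",
              "hubs", "associate")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outDir, f)
  need <- function(f) {
    p <- path(f)
    if (!file.exists(p)) stop("missing input artifact: ", p)
    p
  }
  results <- list()
  timings <- list()

  for (st in todo) {
    t0 <- Sys.time()
    if (st == "simulate") {
      sc <- if (is.null(simConfig)) {
        simulationConfig(seed = config$seed)
      } else simConfig
      sim <- simulateCounts(sc)
      ann <- simulateAnnotation(sim$truth, seed = sc@seed)
      writeExpressionTsv(sim$expression, path("counts.tsv"))
      info <- sampleInfo(sim$expression)
      .writeTsv(data.frame(sample = rownames(info), info),
                path("samples.tsv"))
      .writeTsv(ann, path("annotation.tsv"))
      .writeTsv(data.frame(gene_id = rownames(exprs(sim$expression)),
                           length_bp = geneLengths(sim$expression)),
                path("gene_lengths.tsv"))
      jsonlite::write_json(
        list(modules = as.list(sim$truth$modules),
             hubs = sim$truth$hubs, silent = sim$truth$silent),
        path("ground_truth.json"), auto_unbox = TRUE)
      results$simulate <- sim
      results$annotation <- ann
    } else if (st == "build-db") {
      counts <- .readCounts(need, path)
      ann <- read.delim(need("annotation.tsv"))
      db <- buildDatabase(ann[ann$category == "TF", , drop = FALSE],
                          ann[ann$category == "PHOTO", , drop = FALSE],
                          counts,
                          flMin = config$fl_min,
                          maxHits = config$genome_hits_max,
                          minCount = config$expr_min_count,
                          occupancy = config$expr_occupancy)
      .writeTsv(db$database, path("database.tsv"))
      jsonlite::write_json(
        list(stages = filterStages(db$report),
             survivors = survivors(db$report)),
        path("filter_report.json"), auto_unbox = TRUE)
      results$database <- db
    } else if (st == "normalize") {
      counts <- .readCounts(need, path)
      keep <- survivors(.readReport(need))
      counts <- counts[rownames(counts) %in% keep, ]
      rk <- rpkm(counts)
      lg <- log2p1(rk)
      writeExpressionTsv(rk, path("rpkm.tsv"))
      writeExpressionTsv(lg, path("log2rpkm.tsv"))
      results$rpkm <- rk
      results$log2rpkm <- lg
    } else if (st == "cluster") {
      rk <- readExpressionTsv(need("rpkm.tsv"), need("samples.tsv"))
      profiles <- zscale(log2p1(conditionMeans(rk)))
      k <- selectK(profiles, kRange = config$k_range,
                   maxCentroidCorr = config$max_centroid_corr,
                   seed = config$seed, nInit = config$n_init)
      fit <- kmeansFit(profiles, k, seed = config$seed,
                       nInit = config$n_init)
      .writeTsv(data.frame(gene_id = names(clusterAssignment(fit)),
                           cluster = unname(clusterAssignment(fit)),
                           score_to_core = unname(scoreToCore(fit))),
                path("clusters.tsv"))
      jsonlite::write_json(list(k = as.integer(k)), path("k.json"),
                           auto_unbox = TRUE)
      results$clustering <- fit
    } else if (st == "network") {
      lg <- readExpressionTsv(need("log2rpkm.tsv"), need("samples.tsv"))
      cand <- pairwiseCorrelation(lg)
      edges <- thresholdEdges(cand, minAbsR = config$min_abs_r,
                              alpha = config$alpha)
      net <- topology(buildNetwork(edges),
                      clusteringConvention = config$clustering_convention)
      writeEdgeList(net, path("edges.tsv"))
      writeSif(net, path("network.sif"))
      .writeTsv(nodeMetrics(net), path("node_metrics.tsv"))
      results$network <- net
    } else if (st == "hubs") {
      net <- .readNetwork(need)
      hubs <- hubRank(net, percentile = config$hub_percentile)
      .writeTsv(data.frame(gene_id = hubs, rank = seq_along(hubs)),
                path("hubs.tsv"))
      results$hubs <- hubs
    } else if (st == "associate") {
      cl <- read.delim(need("clusters.tsv"))
      ann <- read.delim(need("annotation.tsv"))
      tagged <- ann$gene_id[vapply(
        strsplit(ann$go_terms, ";", fixed = TRUE),
        function(t) config$go_term %in% t, logical(1))]
      hits <- cl[cl$cluster %in% c(1L, 2L) & cl$gene_id %in% tagged &
                   cl$score_to_core >= config$min_score_to_core, ,
                 drop = FALSE]
      hits <- hits[order(hits$cluster, -hits$score_to_core), , drop = FALSE]
      .writeTsv(hits, path("developmental_hits.tsv"))
      results$developmental <- hits
    }
    timings[[st]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  manifest <- list(
    package = "leafGCN",
    version = as.character(packageVersion("leafGCN")),
    seed = config$seed,
    config = unclass(config),
    stages = todo,
    timings_sec = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(results)
}

.readCounts <- function(need, path) {
  counts <- readExpressionTsv(need("counts.tsv"), need("samples.tsv"))
  lens <- read.delim(need("gene_lengths.tsv"))
  x <- LeafExpression(exprs(counts), sampleInfo = sampleInfo(counts),
                      geneLengths = setNames(lens$length_bp, lens$gene_id),
                      unit = "counts")
  S4Vectors::metadata(x) <- S4Vectors::metadata(counts)
  x
}

.readReport <- function(need) {
  rep <- jsonlite::read_json(need("filter_report.json"),
                             simplifyVector = TRUE)
  new("FilterReport", stages = as.data.frame(rep$stages),
      survivors = as.character(rep$survivors))
}

.readNetwork <- function(need) {
  edges <- read.delim(need("edges.tsv"))
  topology(buildNetwork(edges))
}
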