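#' Configure the synthetic leaf RNA-seq simulator
#'
#' Builds a validated [SimulationConfig-class]. The defaults reproduce the
#' statistical structure the downstream pipeline assumes: 23 samples (four
#' cultivars, two production years, three biological replicates each with one
#' cultivar-year at two), two large anticorrelated modules (465 and 281
#' genes) driven by a shared latent factor with a target cross-module
#' correlation of -0.97, and 1100 independent background genes.
#'
#' Counts are drawn from a negative binomial around
#' `baselineMean * exp(sign * loading * factor)`, so `loading` acts on the
#' natural-log scale of the mean; at the default dispersion the realized
#' within-module pairwise correlations on log2(RPKM + 1) exceed 0.8.
#'
#' @param nSamples total number of samples.
#' @param design data.frame with columns `cultivar`, `year`, `replicates`.
#' @param moduleSpecs data.frame with columns `module`, `nGenes`, `sign`,
#'   `loading`.
#' @param nBackgroundGenes,nSilentGenes background genes; silent ones are
#'   simulated near zero counts and fail the leaf-expression filter.
#' @param nHubGenes planted hub genes per module (0 disables hub planting).
#' @param hubExtraTargets background genes recruited per hub gene.
#' @param loadingSpread per-gene loading heterogeneity: module gene loadings
#'   are drawn uniformly from `[loading - loadingSpread, loading]` (0 gives
#'   every module gene the nominal loading).
#' @param hubLoading loading of hub genes; planted hubs sit at the top of
#'   the loading gradient, which is what makes them jointly central.
#' @param targetLoading secondary loading of hub-target background genes on
#'   their host module's factor.
#' @param hubDispersion negative-binomial dispersion of hub genes; hub
#'   profiles sit at cluster cores, so they are simulated with low noise.
#' @param baselineMean,nbDispersion negative-binomial mean and dispersion.
#' @param geneLengthRange uniform range of transcript lengths (bp).
#' @param targetCrossModuleCorr target latent correlation between the module
#'   factors, in \[-1, 0).
#' @param seed integer seed for the single RNG stream.
#'
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 7L)
#' cfg
#' @export
simulationConfig <- function(nSamples = 23L,
                             design = NULL,
                             moduleSpecs = NULL,
                             nBackgroundGenes = 1100L,
                             nHubGenes = 0L,
                             hubExtraTargets = 0L,
                             loadingSpread = 0,
                             hubLoading = 0.95,
                             targetLoading = 0.5,
                             hubDispersion = 0.002,
                             baselineMean = 500,
                             nbDispersion = 0.05,
                             geneLengthRange = c(500L, 3000L),
                             targetCrossModuleCorr = -0.97,
                             nSilentGenes = 0L,
                             seed = 1L) {
  if (is.null(design)) {
    cultivars <- c("Domari", "Myrna", "Flester", "Confiance")
    design <- expand.grid(cultivar = cultivars, year = c(2011L, 2012L),
                          stringsAsFactors = FALSE)
    design$replicates <- 3L
    # 23 = 4 cultivars x 2 years x 3 replicates minus one sample
    design$replicates[nrow(design)] <- 2L
  }
  if (is.null(moduleSpecs)) {
    moduleSpecs <- data.frame(
      module = c("module1", "module2"),
      nGenes = c(465L, 281L),
      sign = c(1, -1),
      loading = c(0.9, 0.9)
    )
  }
  new("SimulationConfig",
      nSamples = as.integer(nSamples),
      design = design,
      moduleSpecs = moduleSpecs,
      nBackgroundGenes = as.integer(nBackgroundGenes),
      nHubGenes = as.integer(nHubGenes),
      hubExtraTargets = as.integer(hubExtraTargets),
      loadingSpread = loadingSpread,
      hubLoading = hubLoading,
      targetLoading = targetLoading,
      hubDispersion = hubDispersion,
      baselineMean = baselineMean,
      nbDispersion = nbDispersion,
      geneLengthRange = as.integer(geneLengthRange),
      targetCrossModuleCorr = targetCrossModuleCorr,
      nSilentGenes = as.integer(nSilentGenes),
      seed = as.integer(seed))
}


#' Simulate a count matrix with planted co-expression structure
#'
#' Draws integer counts for all module, hub-target, silent and background
#' genes. Module genes share a standard-normal latent factor drawn at the
#' cultivar-by-year condition level (biological replicates share their
#' condition's factor value up to a small replicate jitter); the second
#' module's factor is a mixture correlated with the first at
#' `targetCrossModuleCorr` and its loading enters with the module's sign, so
#' the realized inter-module centroid correlation approaches the target.
#' Hub genes are planted at the top of the module loading gradient
#' (`hubLoading`) and recruit `hubExtraTargets` background genes through a
#' weaker secondary loading (`targetLoading`) on the host module's factor:
#' with graded loadings, only the highest-loading genes stay above the
#' co-expression edge threshold against marginal genes, so hubs acquire
#' jointly high degree, betweenness and closeness while remaining module
#' members. All randomness is drawn from a single stream seeded with
#' `config@seed`, in documented order (gene lengths, latent factors,
#' per-gene loadings, mapped totals, counts), so equal seeds give identical
#' output.
#'
#' The simulated genes stand for a curated panel within a much larger leaf
#' transcriptome, so each sample's mapped-read total (used by [rpkm()]) is
#' simulated independently of the module factor — around 20 million reads
#' with 10% lognormal variation — and recorded in the object metadata and
#' in the ground truth.
#'
#' @param config a [SimulationConfig-class].
#'
#' @return A list with elements:
#' \describe{
#'   \item{expression}{a [LeafExpression-class] of unit `"counts"` with gene
#'     lengths and the cultivar/year/replicate sample metadata.}
#'   \item{truth}{ground truth: `modules` (named gene -> module label or
#'     `"background"`), `hubs`, `hubTargets` (named list), `silent`, and the
#'     per-sample latent `factors` matrix.}
#' }
#' @examples
#' sim <- simulateCounts(simulationConfig(
#'   moduleSpecs = data.frame(module = c("m1", "m2"), nGenes = c(20L, 15L),
#'                            sign = c(1, -1), loading = c(0.9, 0.9)),
#'   nBackgroundGenes = 30L, seed = 11L))
#' dim(exprs(sim$expression))
#' table(sim$truth$modules)
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  ms <- config@moduleSpecs
  nModule <- sum(ms$nGenes)
  nGenes <- nModule + config@nBackgroundGenes
  geneIds <- sprintf("gene%05d", seq_len(nGenes))
  moduleOf <- rep("background", nGenes)
  idx <- 0L
  for (i in seq_len(nrow(ms))) {
    moduleOf[idx + seq_len(ms$nGenes[i])] <- ms$module[i]
    idx <- idx + ms$nGenes[i]
  }
  names(moduleOf) <- geneIds

  samples <- do.call(rbind, lapply(seq_len(nrow(config@design)), function(i) {
    d <- config@design[i, ]
    data.frame(cultivar = d$cultivar, year = d$year,
               replicate = seq_len(d$replicates))
  }))
  rownames(samples) <- sprintf("%s_%d_r%d", samples$cultivar, samples$year,
                               samples$replicate)
  stopifnot(nrow(samples) == config@nSamples)

  # 1. gene lengths
  geneLen <- as.integer(round(runif(
    nGenes, config@geneLengthRange[1], config@geneLengthRange[2])))
  names(geneLen) <- geneIds

  # 2. latent factors. The module factor is a condition-level (cultivar x
  #    year) effect shared by biological replicates, with a small
  #    replicate-level jitter: module expression differs between cultivars
  #    and years, not arbitrarily between replicates. Module 2's factor is
  #    correlated with module 1's at the configured target.
  n <- config@nSamples
  condKey <- paste(samples$cultivar, samples$year, sep = "_")
  conds <- unique(condKey)
  rho <- abs(config@targetCrossModuleCorr)
  sigma <- matrix(c(1, rho, rho, 1), 2L)
  if (length(conds) >= 3L) {
    # exact-moment sampling: the realized condition-level factor moments
    # equal the target exactly, so the planted structure does not drift
    # with the sampling noise of a handful of condition draws
    fc <- MASS::mvrnorm(length(conds), mu = c(0, 0), Sigma = sigma,
                        empirical = TRUE)
  } else {
    fc <- MASS::mvrnorm(max(length(conds), 2L), mu = c(0, 0), Sigma = sigma)
    fc <- fc[seq_along(conds), , drop = FALSE]
  }
  f1c <- setNames(fc[, 1L], conds)
  f2c <- setNames(fc[, 2L], conds)
  repJitter <- 0.15
  f1 <- f1c[condKey] + repJitter * rnorm(n)
  f2 <- f2c[condKey] + repJitter * rnorm(n)
  if (n >= 3L) {
    # standardize realized per-sample factors to exact moments (mean 0,
    # sd 1, cross-correlation exactly rho with the sign applied later via
    # the module spec) so the planted correlation structure does not
    # wobble with the replicate weighting of the condition draws
    f1 <- as.vector(scale(f1))
    resid <- f2 - sum(f2 * f1) / sum(f1^2) * f1
    if (sd(resid) > 0) {
      f2 <- rho * f1 + sqrt(1 - rho^2) * as.vector(scale(resid))
    } else {
      f2 <- rho * f1
    }
  }
  factors <- cbind(f1 = f1, f2 = f2)
  rownames(factors) <- rownames(samples)

  moduleFactor <- function(m) {
    i <- match(m, ms$module)
    ms$sign[i] * factors[, min(i, 2L)]
  }

  # 3. per-gene loadings: module genes get a graded loading drawn from
  #    [loading - loadingSpread, loading]; hub genes sit at hubLoading, the
  #    top of the gradient, which is what makes them super-connectors (they
  #    alone stay above the edge threshold against marginal-loading genes)
  geneLoading <- setNames(rep(NA_real_, nGenes), geneIds)
  for (i in seq_len(nrow(ms))) {
    mem <- geneIds[moduleOf == ms$module[i]]
    geneLoading[mem] <- runif(length(mem),
                              ms$loading[i] - config@loadingSpread,
                              ms$loading[i])
  }

  # 4. hub bookkeeping: hubs are the first nHubGenes genes of each module;
  #    their extra targets are carved from the head of the background block
  #    and receive a weaker secondary loading on the host module's factor
  hubs <- character(0)
  if (config@nHubGenes > 0L) {
    for (m in ms$module) {
      hubs <- c(hubs, geneIds[moduleOf == m][seq_len(config@nHubGenes)])
    }
    geneLoading[hubs] <- config@hubLoading
  }
  # 5. per-sample mapped totals: the simulated genes are a curated subset of
  #    the full leaf transcriptome, so library totals are dominated by the
  #    tens of thousands of genes outside the panel and do not track the
  #    module factor; modelled as 20M reads with 10% lognormal variation
  mappedTotals <- round(2e7 * exp(rnorm(n, 0, 0.1)))
  names(mappedTotals) <- rownames(samples)

  bgPool <- geneIds[moduleOf == "background"]
  silent <- if (config@nSilentGenes > 0L) {
    bgPool[seq(length(bgPool) - config@nSilentGenes + 1L, length(bgPool))]
  } else character(0)
  hubTargets <- list()
  cursor <- 0L
  for (h in hubs) {
    hubTargets[[h]] <- bgPool[cursor + seq_len(config@hubExtraTargets)]
    cursor <- cursor + config@hubExtraTargets
  }
  targetOf <- setNames(rep(names(hubTargets),
                           lengths(hubTargets)), unlist(hubTargets))

  # 6. counts, gene by gene: mean = baseline * exp(loading * factor)
  counts <- matrix(0L, nGenes, n, dimnames = list(geneIds, rownames(samples)))
  drawRow <- function(mu, dispersion) {
    if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
    else as.integer(round(mu))
  }
  for (g in geneIds) {
    m <- moduleOf[[g]]
    disp <- if (g %in% hubs) config@hubDispersion else config@nbDispersion
    if (m != "background") {
      mu <- config@baselineMean * exp(geneLoading[[g]] * moduleFactor(m))
    } else if (g %in% silent) {
      mu <- rep(0.5, n)
    } else if (g %in% names(targetOf)) {
      host <- moduleOf[[targetOf[[g]]]]
      mu <- config@baselineMean *
        exp(config@targetLoading * moduleFactor(host))
    } else {
      mu <- rep(config@baselineMean, n)
    }
    counts[g, ] <- drawRow(mu, disp)
  }

  expression <- LeafExpression(counts, samples, geneLengths = geneLen,
                               unit = "counts")
  S4Vectors::metadata(expression)$mappedTotals <- mappedTotals
  truth <- list(modules = moduleOf, hubs = hubs, hubTargets = hubTargets,
                silent = silent, factors = factors,
                mappedTotals = mappedTotals)
  list(expression = expression, truth = truth)
}

#' Simulate a gene annotation table with planted filter failures
#'
#' Emits one record per simulated gene with the fields the database filters
#' consume: TF/PHOTO category, family, deduced and reference protein lengths,
#' genome hit count, MapMan validation flag and GO terms. A configurable
#' number of records is planted to fail exactly one filter each (genome-hit,
#' protein-completeness, MapMan), on distinct non-silent genes, so per-stage
#' attrition of [buildDatabase()] can be checked exactly; leaf-expression
#' failures are planted in the count matrix instead (see `nSilentGenes` in
#' [simulationConfig()]). A configurable fraction of module genes carries the
#' developmental-process term `GO:0044767`.
#'
#' @param truth ground truth from [simulateCounts()].
#' @param failCounts named integer vector with entries `genome_hits`, `fl`
#'   and `mapman`: how many records fail each filter.
#' @param goFraction fraction of module genes tagged with `goTerm`.
#' @param goTerm GO identifier used for the developmental tag.
#' @param tfFraction fraction of genes annotated as TF (the rest are PHOTO).
#' @param seed integer seed.
#'
#' @return data.frame with columns `gene_id`, `category`, `family`,
#'   `query_protein_length`, `reference_protein_length`, `genome_hits`,
#'   `mapman_validated`, `go_terms` (semicolon-separated).
#' @export
simulateAnnotation <- function(truth,
                               failCounts = c(genome_hits = 0L, fl = 0L,
                                              mapman = 0L),
                               goFraction = 0.25,
                               goTerm = "GO:0044767",
                               tfFraction = 0.8,
                               seed = 1L) {
  set.seed(seed)
  genes <- names(truth$modules)
  nGenes <- length(genes)
  failCounts <- failCounts[c("genome_hits", "fl", "mapman")]
  failCounts[is.na(failCounts)] <- 0L
  names(failCounts) <- c("genome_hits", "fl", "mapman")
  if (sum(failCounts) > nGenes - length(truth$silent)) {
    stop("more planted failures than available non-silent genes")
  }

  eligible <- setdiff(genes, truth$silent)
  failGenes <- sample(eligible, sum(failCounts))
  failGenome <- failGenes[seq_len(failCounts[["genome_hits"]])]
  failFl <- failGenes[failCounts[["genome_hits"]] +
                        seq_len(failCounts[["fl"]])]
  failMapman <- failGenes[failCounts[["genome_hits"]] + failCounts[["fl"]] +
                            seq_len(failCounts[["mapman"]])]

  category <- ifelse(runif(nGenes) < tfFraction, "TF", "PHOTO")
  names(category) <- genes
  # MapMan validation only applies to TF records, so planted MapMan failures
  # must be TFs; PHOTO records keep an arbitrary flag value
  category[failMapman] <- "TF"

  families <- c("bHLH", "MYB", "ERF", "WRKY", "NAC", "C2H2", "GRAS", "bZIP",
                "TCP", "ARF")
  refLen <- sample(150:900, nGenes, replace = TRUE)
  frac <- runif(nGenes, 0.75, 1)
  queryLen <- pmax(1L, as.integer(ceiling(refLen * frac)))
  genomeHits <- sample(0:1, nGenes, replace = TRUE)
  mapman <- rep(TRUE, nGenes)
  # PHOTO records are not MapMan-binned; flag is FALSE and must be ignored
  mapman[category == "PHOTO"] <- FALSE

  ann <- data.frame(
    gene_id = genes,
    category = unname(category),
    family = sample(families, nGenes, replace = TRUE),
    query_protein_length = queryLen,
    reference_protein_length = refLen,
    genome_hits = genomeHits,
    mapman_validated = mapman,
    stringsAsFactors = FALSE
  )
  rownames(ann) <- genes
  ann[failGenome, "genome_hits"] <- sample(2:5, length(failGenome),
                                           replace = TRUE)
  ann[failFl, "query_protein_length"] <- pmax(1L, as.integer(floor(
    ann[failFl, "reference_protein_length"] * runif(length(failFl), 0.3, 0.65)
  )))
  ann[failMapman, "mapman_validated"] <- FALSE

  moduleGenes <- genes[truth$modules != "background"]
  nTag <- round(goFraction * length(moduleGenes))
  tagged <- if (nTag > 0) sample(moduleGenes, nTag) else character(0)
  otherTerms <- sprintf("GO:%07d", sample(1e6, nGenes, replace = TRUE))
  ann$go_terms <- otherTerms
  ann$go_terms[match(tagged, genes)] <-
    paste(goTerm, otherTerms[match(tagged, genes)], sep = ";")
  attr(ann, "planted") <- list(genome_hits = failGenome, fl = failFl,
                               mapman = failMapman, go = tagged)
  ann
}

#' Simulate per-comparison differential-expression tables
#'
#' For each declared comparison, emits one row per gene with a log2 fold
#' change and an FDR such that planted genes pass both DEG thresholds
#' (FDR <= 0.05 and |log2FC| >= 1, with a consistent positive sign) and all
#' other genes fail at least one.
#'
#' @param truth ground truth from [simulateCounts()].
#' @param comparisons data.frame with columns `label`, `cultivar_a`,
#'   `cultivar_b`, `year`.
#' @param planted named list, comparison label -> character vector of genes
#'   differentially expressed in that comparison.
#' @param seed integer seed.
#'
#' @return named list of data.frames (`gene`, `log2FC`, `FDR`), one per
#'   comparison, each carrying the comparison metadata as attributes.
#' @export
simulateDegTables <- function(truth, comparisons, planted = list(),
                              seed = 1L) {
  set.seed(seed)
  stopifnot(all(c("label", "cultivar_a", "cultivar_b", "year") %in%
                  names(comparisons)))
  genes <- names(truth$modules)
  out <- list()
  for (i in seq_len(nrow(comparisons))) {
    lab <- comparisons$label[i]
    hit <- genes %in% planted[[lab]]
    lfc <- runif(length(genes), -0.9, 0.9)
    fdr <- runif(length(genes))
    lfc[hit] <- runif(sum(hit), 1.5, 4)
    fdr[hit] <- runif(sum(hit), 1e-6, 0.01)
    tab <- data.frame(gene = genes, log2FC = lfc, FDR = fdr,
                      stringsAsFactors = FALSE)
    attr(tab, "cultivar_a") <- comparisons$cultivar_a[i]
    attr(tab, "cultivar_b") <- comparisons$cultivar_b[i]
    attr(tab, "year") <- comparisons$year[i]
    out[[lab]] <- tab
  }
  out
}

#' Canned configuration for the hub-recovery benchmark
#'
#' A compact co-expression study in which ten planted super-connector genes
#' are identifiable by the joint top-decile centrality criterion: 48
#' samples (four cultivars, two years, six replicates), two 40-gene
#' modules with graded loadings (nominal 0.26, spread 0.04), five hub
#' genes per module at the top of the loading gradient with low noise,
#' four weakly loaded background targets per hub, and 150 background
#' genes. Modules are kept moderately co-expressed so that degree,
#' betweenness and closeness single out the hubs rather than saturating
#' on near-complete modules.
#'
#' @param seed integer seed.
#' @return A [SimulationConfig-class].
#' @seealso [simulateCounts()], [hubRank()]
#' @examples
#' sim <- simulateCounts(hubStudyConfig(seed = 1L))
#' length(sim$truth$hubs)  # 10 planted super-connectors
#' @export
hubStudyConfig <- function(seed = 1L) {
  design <- expand.grid(cultivar = c("Domari", "Myrna", "Flester",
                                     "Confiance"),
                        year = c(2011L, 2012L), stringsAsFactors = FALSE)
  design$replicates <- 6L
  simulationConfig(
    nSamples = 48L, design = design,
    moduleSpecs = data.frame(module = c("module1", "module2"),
                             nGenes = c(40L, 40L), sign = c(1, -1),
                             loading = c(0.26, 0.26)),
    nBackgroundGenes = 150L, nHubGenes = 5L, hubExtraTargets = 4L,
    loadingSpread = 0.04, hubLoading = 1.0, targetLoading = 0.26,
    nbDispersion = 0.02, hubDispersion = 0.002, seed = seed)
}
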