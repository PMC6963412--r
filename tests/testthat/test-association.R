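fakeCluster <- function(assignment, scores) {
  new("ClusterResult", k = max(assignment),
      assignment = assignment,
      centroids = matrix(rnorm(4 * max(assignment)), max(assignment)),
      scoreToCore = scores, sse = 1, diagnostics = data.frame(), seed = 1L)
}

test_that("developmental-gene search honors tag, cluster and score floor", {
  genes <- sprintf("g%02d", 1:20)
  asg <- setNames(rep(c(1L, 2L, 3L), c(12, 5, 3)), genes)
  scores <- setNames(c(rep(0.95, 7), rep(0.5, 5), rep(0.95, 5),
                       rep(0.9, 3)), genes)
  ann <- data.frame(gene_id = genes,
                    go_terms = ifelse(seq_along(genes) <= 12,
                                      "GO:0044767;GO:0000001", "GO:0000001"))
  hits <- selectDevelopmental(fakeCluster(asg, scores), ann,
                              clusters = c(1L, 2L), minScore = 0.8)
  # 12 tagged genes in cluster one, 5 of them below the floor -> 7 hits
  expect_equal(nrow(hits), 7L)
  expect_true(all(hits$cluster == 1L))
  expect_true(all(hits$score_to_core >= 0.8))
  expect_true(all(diff(hits$score_to_core) <= 0))

  none <- selectDevelopmental(fakeCluster(asg, scores), ann,
                              goTerm = "GO:9999999")
  expect_equal(nrow(none), 0L)
  expect_error(selectDevelopmental(fakeCluster(asg, scores), ann,
                                   clusters = 9L), "unknown cluster")
})

test_that("the default score floor keeps only near-core genes", {
  genes <- c("lo", "hi")
  asg <- setNames(c(1L, 1L), genes)
  scores <- setNames(c(0.892, 0.893), genes)
  ann <- data.frame(gene_id = genes, go_terms = "GO:0044767")
  hits <- selectDevelopmental(fakeCluster(c(asg, x = 2L),
                                          c(scores, x = 0.1)), ann,
                              clusters = 1L)
  expect_equal(hits$gene_id, "hi")   # 0.893 floor is inclusive
})

degFixture <- function(passMatrix, genes, lfcSign = NULL) {
  comps <- expand.grid(a = c("Flester", "Confiance"),
                       b = c("Domari", "Myrna"), year = c(2011L, 2012L),
                       stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(comps)), function(i) {
    pass <- passMatrix[, i]
    lfc <- ifelse(pass, 2.5, 0.2)
    if (!is.null(lfcSign)) lfc <- lfc * lfcSign[, i]
    tab <- data.frame(gene = genes, log2FC = lfc,
                      FDR = ifelse(pass, 0.001, 0.5))
    attr(tab, "cultivar_a") <- comps$a[i]
    attr(tab, "cultivar_b") <- comps$b[i]
    attr(tab, "year") <- comps$year[i]
    tab
  })
  names(tabs) <- sprintf("cmp%d", seq_along(tabs))
  tabs
}

test_that("consistent DEGs must pass every comparison with one sign", {
  genes <- c("always", "seven", "flip")
  pass <- matrix(TRUE, 3, 8, dimnames = list(genes, NULL))
  pass["seven", 8] <- FALSE
  sign <- matrix(1, 3, 8, dimnames = list(genes, NULL))
  sign["flip", 5] <- -1
  tabs <- degFixture(pass, genes, sign)
  got <- consistentDegs(tabs, groupA = c("Flester", "Confiance"),
                        groupB = c("Domari", "Myrna"),
                        years = c(2011L, 2012L))
  expect_equal(got, "always")
})

test_that("missing comparisons abort with the offending design cell", {
  genes <- c("g1")
  tabs <- degFixture(matrix(TRUE, 1, 8), genes)[1:7]
  expect_error(consistentDegs(tabs, c("Flester", "Confiance"),
                              c("Domari", "Myrna"), c(2011L, 2012L)),
               "incomplete comparison design")
})

test_that("intersection over more tables can only shrink", {
  sim <- simulateCounts(simulationConfig(
    moduleSpecs = data.frame(module = "m1", nGenes = 10L, sign = 1,
                             loading = 0.9),
    nBackgroundGenes = 20L, seed = 41L))
  genes <- names(sim$truth$modules)
  comps <- expand.grid(a = "Flester", b = c("Domari", "Myrna"),
                       year = c(2011L, 2012L), stringsAsFactors = FALSE)
  comps <- data.frame(label = sprintf("c%d", 1:4), cultivar_a = comps$a,
                      cultivar_b = comps$b, year = comps$year)
  planted <- list(c1 = genes[1:5], c2 = genes[1:4], c3 = genes[1:4],
                  c4 = genes[c(1:3, 5)])
  tabs <- simulateDegTables(sim$truth, comps, planted, seed = 2L)
  full <- consistentDegs(tabs, "Flester", c("Domari", "Myrna"),
                         c(2011L, 2012L))
  half <- consistentDegs(tabs[c("c1", "c2")], "Flester",
                         c("Domari", "Myrna"), 2011L)
  expect_setequal(full, genes[1:3])
  expect_true(all(full %in% half))
})

test_that("hypergeometric enrichment matches direct tail summation", {
  universe <- sprintf("u%02d", 1:40)
  ann <- data.frame(gene_id = universe,
                    go_terms = c(rep("GO:1;GO:2", 8), rep("GO:2", 32)))
  geneSet <- universe[1:10]   # all 8 GO:1 genes + 2 others
  res <- termEnrichment(geneSet, ann, universe)
  manual <- sum(dhyper(8:8, 8, 32, 10))  # P(X >= 8), X ~ Hyper(8, 32, 10)
  expect_equal(res$p[res$term == "GO:1"], manual, tolerance = 1e-12)
  expect_equal(res$p[res$term == "GO:2"], 1)   # term covers the universe

  whole <- termEnrichment(universe, ann, universe)
  expect_true(all(whole$p == 1))
  expect_error(termEnrichment(geneSet, ann, character(0)), "empty universe")
  expect_error(termEnrichment(c(geneSet, "zz"), ann, universe),
               "within universe")
})

test_that("enrichment p-values are super-uniform under label permutation", {
  set.seed(6)
  universe <- sprintf("u%03d", 1:60)
  ann <- data.frame(gene_id = universe,
                    go_terms = sample(c("GO:A", "GO:B", "GO:C"), 60,
                                      replace = TRUE))
  pvals <- replicate(300, {
    gs <- sample(universe, 15)
    min(termEnrichment(gs, ann, universe)$p)
  })
  # with 3 terms tested, the minimum p at level alpha is seen at most
  # ~3 * alpha of the time under the null
  expect_lte(mean(pvals <= 0.01), 0.06)
  expect_lte(mean(pvals <= 0.05), 0.25)
})
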