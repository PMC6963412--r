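test_that("pairwise correlation matches an independent implementation", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5), c = c(4, 3, 2, 1))
  colnames(m) <- sprintf("s%d", 1:4)
  cand <- pairwiseCorrelation(m)
  ct <- cor.test(m["a", ], m["b", ])
  expect_equal(cand$r["a", "b"], unname(ct$estimate), tolerance = 1e-10)
  expect_equal(cand$p["a", "b"], ct$p.value, tolerance = 1e-10)
  expect_equal(cand$r["a", "c"], -1)
  expect_equal(cand$p["a", "c"], 0)
  dup <- rbind(a = c(1, 5, 2, 7), b = c(1, 5, 2, 7))
  colnames(dup) <- sprintf("s%d", 1:4)
  expect_equal(pairwiseCorrelation(dup)$r["a", "b"], 1)
})

test_that("pairwise correlation guards degenerate input", {
  m <- rbind(a = c(1, 2), b = c(2, 1))
  colnames(m) <- c("s1", "s2")
  expect_error(pairwiseCorrelation(m), "at least 3")
  flat <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  colnames(flat) <- sprintf("s%d", 1:3)
  expect_error(pairwiseCorrelation(flat), "constant")
})

test_that("edge thresholds are inclusive on both r and p", {
  genes <- c("a", "b", "c", "d")
  r <- diag(4); rownames(r) <- colnames(r) <- genes
  p <- matrix(1, 4, 4, dimnames = list(genes, genes))
  r["a", "b"] <- r["b", "a"] <- 0.80;  p["a", "b"] <- p["b", "a"] <- 0.01
  r["a", "c"] <- r["c", "a"] <- 0.79;  p["a", "c"] <- p["c", "a"] <- 1e-6
  r["a", "d"] <- r["d", "a"] <- -0.95; p["a", "d"] <- p["d", "a"] <- 0.001
  r["b", "c"] <- r["c", "b"] <- 0.99;  p["b", "c"] <- p["c", "b"] <- 0.06
  cand <- structure(list(r = r, p = p, n = 10L),
                    class = "correlationCandidates")
  e <- thresholdEdges(cand)
  expect_setequal(paste(e$gene_a, e$gene_b), c("a b", "a d"))
  expect_equal(e$sign[e$gene_b == "d"], "-")
  # raising the threshold never adds edges
  stricter <- thresholdEdges(cand, minAbsR = 0.9)
  expect_true(all(paste(stricter$gene_a, stricter$gene_b) %in%
                    paste(e$gene_a, e$gene_b)))
})

test_that("triangle and path topologies match hand enumeration", {
  tri <- adjacencyToNetwork(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  tri <- topology(tri)
  nm <- nodeMetrics(tri)
  expect_equal(nm$degree, rep(2L, 3))
  expect_equal(nm$clustering, rep(1, 3))
  expect_equal(graphMetrics(tri)$globalClustering, 1)
  expect_equal(graphMetrics(tri)$characteristicPathLength, 1)

  path3 <- adjacencyToNetwork(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  path3 <- topology(path3)
  nm3 <- nodeMetrics(path3)
  expect_equal(nm3["n02", "betweenness"], 1)   # middle node carries all flow
  expect_equal(graphMetrics(path3)$characteristicPathLength, 4 / 3)
})

test_that("star topology: center closeness 1, leaves 4/7, no clustering", {
  adj <- matrix(0L, 5, 5); adj[1, 2:5] <- adj[2:5, 1] <- 1L
  star <- topology(adjacencyToNetwork(adj))
  nm <- nodeMetrics(star)
  expect_equal(nm["n01", "closeness"], 1)
  expect_equal(nm["n02", "closeness"], 4 / 7)  # 1 + 2 + 2 + 2 steps
  expect_equal(graphMetrics(star)$globalClustering, 0)
  expect_equal(nm["n01", "betweenness"], 1)
  expect_equal(maxDegreeGene(star), "n01")
})

test_that("centrality agrees exactly with the exhaustive path oracle", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    adj <- randomAdjacency(n, runif(1, 0.25, 0.7))
    net <- topology(adjacencyToNetwork(adj))
    oracle <- oracleTopology(adj)
    nm <- nodeMetrics(net)
    expect_equal(nm$betweenness, oracle$betweenness, tolerance = 1e-12)
    expect_equal(nm$closeness, oracle$closeness, tolerance = 1e-12)
    if (!is.na(oracle$cpl)) {
      expect_equal(graphMetrics(net)$characteristicPathLength, oracle$cpl,
                   tolerance = 1e-12)
    }
    expect_equal(sum(nm$degree), 2L * nrow(networkEdges(net)))
  }
})

test_that("joint hub criterion intersects the three top sets", {
  # one planted super-connector in a 20-node graph
  adj <- matrix(0L, 20, 20)
  adj[1, 2:15] <- adj[2:15, 1] <- 1L
  for (i in 2:10) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj[16, 17] <- adj[17, 16] <- 1L
  adj[18, 19] <- adj[19, 18] <- 1L
  net <- topology(adjacencyToNetwork(adj))
  expect_equal(hubRank(net, 0.10), "n01")

  # three disjoint metric winners -> empty hub set
  nm <- data.frame(gene = c("a", "b", "c", rep(letters[4:10], 1)),
                   degree = c(10L, 1L, 1L, rep(2L, 7)),
                   betweenness = c(0, 1, 0, rep(0.1, 7)),
                   closeness = c(0.1, 0.1, 1, rep(0.2, 7)),
                   clustering = 0)
  rownames(nm) <- nm$gene
  fake <- buildNetwork(data.frame(gene_a = "a", gene_b = "b", r = 0.9,
                                  p = 0.01, sign = "+"),
                       nodes = nm$gene)
  fake@nodeMetrics <- nm
  expect_length(hubRank(fake, 0.10), 0L)
})

test_that("ties at a top-set cutoff are included in full", {
  nm <- data.frame(gene = letters[1:10],
                   degree = c(5L, rep(3L, 5), rep(1L, 4)),
                   betweenness = seq(1, 0.1, length.out = 10),
                   closeness = seq(1, 0.1, length.out = 10),
                   clustering = 0)
  rownames(nm) <- nm$gene
  fake <- buildNetwork(data.frame(gene_a = "a", gene_b = "b", r = 0.9,
                                  p = 0.01, sign = "+"), nodes = nm$gene)
  fake@nodeMetrics <- nm
  # top-1 by degree is "a" (5); no tie at that cutoff. With percentile 0.2
  # the cutoff value 3 pulls in all five tied genes.
  hubs <- hubRank(fake, 0.20)
  expect_equal(hubs[1], "a")
  expect_setequal(hubs, c("a", "b"))
})

test_that("maximum-degree gene breaks ties lexicographically", {
  ring <- matrix(0L, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; ring[i, j] <- ring[j, i] <- 1L }
  expect_equal(maxDegreeGene(topology(adjacencyToNetwork(ring))), "n01")
})

test_that("induced subnetworks restrict nodes and re-threshold edges", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  net <- topology(adjacencyToNetwork(tri))
  same <- subnetwork(net, networkNodes(net))
  expect_equal(networkEdges(same), networkEdges(net))
  expect_warning(empty <- subnetwork(net, c("zz")), "ignored")
  expect_length(networkNodes(empty), 0L)
  two <- subnetwork(net, c("n01", "n02"))
  expect_equal(nrow(networkEdges(two)), 1L)
  expect_equal(graphMetrics(two)$characteristicPathLength, 1)
  # a stricter |r| threshold drops weak edges
  e <- networkEdges(net); e$r <- c(0.85, 0.92, 0.95)
  net2 <- buildNetwork(e)
  expect_equal(nrow(networkEdges(subnetwork(net2, networkNodes(net2),
                                            minAbsR = 0.9))), 2L)
})

test_that("planted modules give positive within- and negative cross-module
          edges", {
  sim <- simulateCounts(simulationConfig(
    moduleSpecs = data.frame(module = c("m1", "m2"), nGenes = c(30L, 20L),
                             sign = c(1, -1), loading = c(0.9, 0.9)),
    nBackgroundGenes = 30L, seed = 31L))
  lg <- log2p1(rpkm(sim$expression))
  edges <- thresholdEdges(pairwiseCorrelation(lg))
  mods <- sim$truth$modules
  within <- mods[edges$gene_a] == mods[edges$gene_b] &
    mods[edges$gene_a] != "background"
  cross <- mods[edges$gene_a] != mods[edges$gene_b] &
    mods[edges$gene_a] != "background" & mods[edges$gene_b] != "background"
  expect_gte(mean(edges$sign[within] == "+"), 0.95)
  expect_gte(mean(edges$sign[cross] == "-"), 0.95)
})

test_that("planted super-connectors top the degree ranking", {
  sim <- simulateCounts(hubStudyConfig(seed = 77L))
  lg <- log2p1(rpkm(sim$expression))
  net <- topology(buildNetwork(thresholdEdges(pairwiseCorrelation(lg))))
  expect_true(maxDegreeGene(net) %in% sim$truth$hubs)
})
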