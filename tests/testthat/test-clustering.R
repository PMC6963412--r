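blobs <- function(centers, nPer = 10L, noise = 0.05, seed = 1L) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rep(centers[i, ], each = nPer), nPer) +
      matrix(rnorm(nPer * ncol(centers), 0, noise), nPer)
  }))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  m
}

test_that("k-means recovers well-separated planted groups", {
  m <- blobs(rbind(c(5, 5, 0, 0), c(0, 0, 5, 5)), nPer = 12L)
  fit <- kmeansFit(m, k = 2, seed = 1L)
  asg <- clusterAssignment(fit)
  expect_length(unique(asg[1:12]), 1L)
  expect_length(unique(asg[13:24]), 1L)
  expect_false(asg[[1]] == asg[[24]])
  expect_equal(sort(names(asg)), sort(rownames(m)))
})

test_that("k-means is deterministic and canonically labeled", {
  m <- blobs(rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
             nPer = c(5L, 9L, 7L)[1], seed = 2L)
  m <- rbind(m, blobs(rbind(c(0, 3, 0)), nPer = 15L, seed = 3L))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  f1 <- kmeansFit(m, 2L, seed = 5L)
  f2 <- kmeansFit(m, 2L, seed = 5L)
  expect_identical(clusterAssignment(f1), clusterAssignment(f2))
  sizes <- table(clusterAssignment(f1))
  expect_true(all(diff(as.integer(sizes)) <= 0))  # cluster 1 is largest
})

test_that("invalid k is rejected", {
  m <- blobs(rbind(c(1, 0), c(0, 1)), nPer = 3L)
  expect_error(kmeansFit(m, 1L), "at least 2")
  expect_error(kmeansFit(m, 7L), "exceeds")
})

test_that("per-k diagnostics favor the planted number of blobs", {
  m <- blobs(rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 0, 5, 0)),
             nPer = 15L, noise = 0.3, seed = 7L)
  d <- kDiagnostics(m, kRange = 2:6, seed = 1L, nInit = 20L)
  expect_equal(d$k, 2:6)
  expect_true(all(diff(d$sse) <= 1e-8))        # SSE non-increasing in k
  expect_equal(d$k[which.max(d$silhouette)], 3L)
  expect_equal(d$k[which.max(d$ch)], 3L)
})

test_that("SSE vanishes when every gene is its own cluster", {
  m <- blobs(rbind(c(2, 0), c(0, 2)), nPer = 3L, noise = 0.2)
  fit <- kmeansFit(m, k = nrow(m), seed = 1L, nInit = 10L)
  expect_equal(clusterSSE(fit), 0)
})

test_that("the centroid-correlation rule selects the planted k", {
  # three mutually orthogonal profiles: splitting any planted cluster
  # yields two near-collinear centroids, so the rule stops at 3
  m <- blobs(rbind(c(5, 0, 0, 0, 0, 0), c(0, 5, 0, 0, 0, 0),
                   c(0, 0, 5, 0, 0, 0)), nPer = 20L, noise = 0.2, seed = 4L)
  k <- selectK(m, kRange = 2:8, seed = 1L, nInit = 20L)
  expect_equal(as.integer(k), 3L)
  expect_false(attr(k, "fallback"))
  expect_lt(attr(k, "maxCentroidCorr"), 0.8)
})

test_that("a homogeneous cloud falls back to the minimum k with a warning", {
  set.seed(8)
  # profiles spread along one non-constant direction with positive
  # coefficients: every split yields two centroids correlated near one,
  # so no k satisfies the rule
  m <- outer(runif(50, 0.5, 2), c(3, 1, -2, 0, 1, -1)) +
    matrix(rnorm(300, 0, 0.05), 50, 6)
  rownames(m) <- sprintf("g%03d", 1:50)
  expect_warning(k <- selectK(m, kRange = 2:4, seed = 1L, nInit = 10L),
                 "falling back")
  expect_equal(as.integer(k), 2L)
  expect_true(attr(k, "fallback"))
})

test_that("a vacuous centroid-correlation bound returns the largest k", {
  m <- blobs(rbind(c(4, 0), c(0, 4)), nPer = 10L, noise = 0.3)
  k <- selectK(m, kRange = 2:5, maxCentroidCorr = 1.01, seed = 1L,
               nInit = 10L)
  expect_equal(as.integer(k), 5L)
})

test_that("score to core is a scale-invariant correlation in [-1, 1]", {
  m <- blobs(rbind(c(5, 5, 0, 0), c(0, 0, 5, 5)), nPer = 10L, seed = 9L)
  fit <- kmeansFit(m, 2L, seed = 1L)
  s <- scoreToCore(fit)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(all(s > 0.9))  # tight blobs sit close to their centroid

  # a profile proportional to its centroid scores exactly 1
  cen <- centroids(fit)[1, ]
  aligned <- rbind(m, g999 = 2 * cen)
  fit2 <- kmeansFit(aligned, 2L, seed = 1L)
  expect_equal(unname(scoreToCore(fit2)["g999"]), 1, tolerance = 1e-6)
})

test_that("core driver takes the top score with lexicographic ties", {
  asg <- setNames(c(1L, 1L, 1L, 2L, 2L), c("b", "a", "c", "d", "e"))
  res <- new("ClusterResult", k = 2L, assignment = asg,
             centroids = matrix(rnorm(4), 2),
             scoreToCore = setNames(c(0.9, 0.9, 0.5, 0.7, 0.8), names(asg)),
             sse = 1, diagnostics = data.frame(), seed = 1L)
  expect_equal(coreDriver(res, 1L), "a")  # tie between a and b -> "a"
  expect_equal(coreDriver(res, 2L), "e")
  expect_error(coreDriver(res, 3L), "empty or unknown")
})

test_that("centroid correlation matrix is symmetric with unit diagonal", {
  m <- blobs(rbind(c(5, 0, 1, 2), c(0, 5, 2, 1), c(2, 2, 5, 0)),
             nPer = 8L, noise = 0.3, seed = 10L)
  fit <- kmeansFit(m, 3L, seed = 1L)
  cc <- centroidCorrelationMatrix(fit)
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_lt(max(abs(cc - t(cc))), 1e-12)
})

test_that("anticorrelated planted modules meet at a centroid correlation
          near the simulation target", {
  sim <- simulateCounts(simulationConfig(
    moduleSpecs = data.frame(module = c("m1", "m2"), nGenes = c(40L, 25L),
                             sign = c(1, -1), loading = c(0.9, 0.9)),
    nBackgroundGenes = 60L, seed = 23L))
  profiles <- zscale(log2p1(conditionMeans(rpkm(sim$expression))))
  fit <- kmeansFit(profiles, 4L, seed = 1L, nInit = 25L)
  cc <- centroidCorrelationMatrix(fit)
  expect_lte(min(cc), -0.9)
})
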