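#' RPKM normalization
#'
#' Converts raw counts to reads per kilobase of transcript per million
#' mapped reads: `rpkm(g, s) = count(g, s) * 1e9 / (length_bp(g) * N_s)`.
#' `N_s` is taken, in order of preference, from the `mappedTotals`
#' argument, from `metadata(x)$mappedTotals` (recorded by
#' [simulateCounts()], whose genes are a panel within a larger
#' transcriptome), or as the column sum of the count matrix — the standard
#' proxy when true mapped totals are not recoverable from a matrix.
#'
#' @param x a [LeafExpression-class] of unit `"counts"` carrying gene
#'   lengths.
#' @param mappedTotals optional named numeric vector of per-sample mapped
#'   read totals.
#' @return A [LeafExpression-class] of unit `"RPKM"`.
#' @examples
#' m <- matrix(c(10, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' x <- LeafExpression(m, geneLengths = c(g1 = 1000L))
#' exprs(rpkm(x, mappedTotals = c(s1 = 1e6, s2 = 1e6)))  # 10, 0
#' @export
rpkm <- function(x, mappedTotals = NULL) {
  stopifnot(is(x, "LeafExpression"))
  if (expressionUnit(x) != "counts") {
    stop("rpkm() expects unit 'counts', got '", expressionUnit(x), "'")
  }
  len <- geneLengths(x)
  if (is.null(len)) stop("gene lengths (bp) are required for RPKM")
  m <- exprs(x)
  if (is.null(mappedTotals)) {
    mappedTotals <- S4Vectors::metadata(x)$mappedTotals
  }
  if (is.null(mappedTotals)) {
    mappedTotals <- colSums(m)
  } else {
    if (!all(colnames(m) %in% names(mappedTotals))) {
      stop("'mappedTotals' must cover every sample")
    }
    mappedTotals <- mappedTotals[colnames(m)]
  }
  if (any(mappedTotals <= 0)) {
    stop("degenerate sample(s) with zero mapped total: ",
         paste(colnames(m)[mappedTotals <= 0], collapse = ", "))
  }
  vals <- m * 1e9 / (len %o% mappedTotals)
  .newUnit(x, vals, "RPKM")
}

#' log2(x + 1) transform
#'
#' @param x a [LeafExpression-class] of unit `"RPKM"` (non-negative values).
#' @return A [LeafExpression-class] of unit `"log2RPKM"`.
#' @export
log2p1 <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  if (expressionUnit(x) != "RPKM") {
    stop("log2p1() expects unit 'RPKM', got '", expressionUnit(x), "'")
  }
  m <- exprs(x)
  if (any(m < 0)) stop("log2(x + 1) is undefined for negative values")
  .newUnit(x, log2(m + 1), "log2RPKM")
}

#' Per-gene z-scaling
#'
#' Centers each gene to mean zero and scales to unit variance. Constant
#' genes cannot be scaled: they are left untouched and flagged in
#' `rowData(x)$constant`, and must be excluded from downstream clustering
#' and correlation (the clustering and network constructors drop them
#' automatically).
#'
#' @param x a [LeafExpression-class] of unit `"log2RPKM"`.
#' @return A [LeafExpression-class] of unit `"zscore"` with a logical
#'   `constant` column in its `rowData`.
#' @export
zscale <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  if (expressionUnit(x) != "log2RPKM") {
    stop("zscale() expects unit 'log2RPKM', got '", expressionUnit(x), "'")
  }
  m <- exprs(x)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  constant <- s == 0 | is.na(s)
  z <- (m - mu) / ifelse(constant, 1, s)
  z[constant, ] <- m[constant, , drop = FALSE]
  y <- .newUnit(x, z, "zscore")
  SummarizedExperiment::rowData(y)$constant <- unname(constant)
  y
}

#' Average expression over cultivar-by-year conditions
#'
#' Collapses biological replicates to one column per condition group
#' (default cultivar x year; with four cultivars and two production years
#' this yields eight condition-mean profiles). Means are arithmetic over the
#' group's replicate columns and are computed on the current unit, so the
#' reference order "RPKM means, then log-transform, then scale" is obtained
#' by calling `conditionMeans()` on the RPKM object before [log2p1()].
#'
#' @param x a [LeafExpression-class] with populated sample metadata.
#' @param by character vector of `sampleInfo(x)` columns defining the
#'   grouping.
#' @return A [LeafExpression-class] with one column per group, same unit.
#' @export
conditionMeans <- function(x, by = c("cultivar", "year")) {
  stopifnot(is(x, "LeafExpression"))
  info <- sampleInfo(x)
  if (!all(by %in% names(info))) {
    stop("sample metadata lacks grouping column(s): ",
         paste(setdiff(by, names(info)), collapse = ", "))
  }
  key <- interaction(info[by], drop = TRUE, sep = "_")
  if (anyNA(key)) stop("grouping metadata contains missing values")
  m <- exprs(x)
  groups <- levels(key)
  means <- vapply(groups, function(g) {
    rowMeans(m[, key == g, drop = FALSE])
  }, numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m),
                  dimnames = list(rownames(m), groups))
  meta <- unique(info[by])
  rownames(meta) <- do.call(paste, c(meta, sep = "_"))
  meta <- meta[groups, , drop = FALSE]
  LeafExpression(means, sampleInfo = meta, geneLengths = geneLengths(x),
                 unit = expressionUnit(x))
}
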