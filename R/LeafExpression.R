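#' Construct a LeafExpression object
#'
#' @param values numeric genes-by-samples matrix with gene identifiers as row
#'   names and sample identifiers as column names.
#' @param sampleInfo data.frame with one row per sample and columns
#'   `cultivar`, `year`, `replicate` (extra columns are kept).
#' @param geneLengths optional named integer vector of transcript lengths in
#'   bp; required before [rpkm()] can be applied to counts.
#' @param unit declared unit of `values`.
#'
#' @return A [LeafExpression-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' info <- data.frame(cultivar = rep(c("A", "B"), 2),
#'                    year = rep(2011:2012, each = 2), replicate = 1L)
#' LeafExpression(m, info, geneLengths = c(g1 = 500L, g2 = 800L, g3 = 1200L))
#' @export
LeafExpression <- function(values, sampleInfo = NULL, geneLengths = NULL,
                           unit = "counts") {
  unit <- match.arg(unit, .EXPRESSION_UNITS)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene row names and sample column names")
  }
  if (is.null(sampleInfo)) {
    sampleInfo <- data.frame(
      cultivar = rep(NA_character_, ncol(values)),
      year = rep(NA_integer_, ncol(values)),
      replicate = rep(NA_integer_, ncol(values)),
      row.names = colnames(values))
  }
  if (nrow(sampleInfo) != ncol(values)) {
    stop("'sampleInfo' must have one row per sample")
  }
  rowdat <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(geneLengths)) {
    if (!all(rownames(values) %in% names(geneLengths))) {
      stop("'geneLengths' must cover every gene")
    }
    len <- as.integer(geneLengths[rownames(values)])
    if (any(len < 1L)) stop("gene lengths must be >= 1 bp")
    rowdat$length_bp <- len
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = colnames(values)),
    rowData = rowdat
  )
  new("LeafExpression", se, unit = unit)
}

#' Accessors for LeafExpression
#'
#' `exprs()` returns the expression matrix, `expressionUnit()` the declared
#' unit, `geneLengths()` the named transcript-length vector (or `NULL`), and
#' `sampleInfo()` the sample metadata as a plain data.frame.
#'
#' @param x a [LeafExpression-class] object.
#' @return See the individual descriptions.
#' @name LeafExpression-accessors
#' @aliases exprs expressionUnit geneLengths sampleInfo
#' @export
exprs <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  SummarizedExperiment::assay(x, "exprs")
}

#' @rdname LeafExpression-accessors
#' @export
expressionUnit <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  x@unit
}

#' @rdname LeafExpression-accessors
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  rd <- SummarizedExperiment::rowData(x)
  if (!"length_bp" %in% names(rd)) return(NULL)
  setNames(rd$length_bp, rownames(x))
}

#' @rdname LeafExpression-accessors
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "LeafExpression"))
  as.data.frame(SummarizedExperiment::colData(x))
}

.newUnit <- function(x, values, unit) {
  y <- x
  SummarizedExperiment::assay(y, "exprs") <- values
  y@unit <- unit
  validObject(y)
  y
}
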