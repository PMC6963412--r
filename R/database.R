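#' Full-length fraction of a deduced protein
#'
#' The completeness of a de novo assembled transcript is certified by the
#' ratio of its deduced protein length to the length of the annotated
#' reference homolog; records with a fraction below 0.7 are dropped by the
#' database filters.
#'
#' @param queryLen deduced protein length (aa).
#' @param refLen annotated reference protein length (aa); must be >= 1.
#' @return `queryLen / refLen`, vectorized.
#' @examples
#' fullLengthFraction(70, 100)   # 0.7, passes the inclusive threshold
#' fullLengthFraction(69, 100)   # fails
#' @export
fullLengthFraction <- function(queryLen, refLen) {
  if (any(is.na(refLen)) || any(refLen < 1)) {
    stop("reference protein length is missing or < 1 aa")
  }
  queryLen / refLen
}

#' Keep records mapping to at most one genomic locus
#'
#' @param records annotation data.frame with a `genome_hits` column.
#' @param maxHits inclusive upper bound on hits per locus (default 1, i.e.
#'   0 or 1 hits are kept).
#' @return The surviving rows of `records`.
#' @export
filterGenomeHits <- function(records, maxHits = 1L) {
  stopifnot("genome_hits" %in% names(records))
  records[records$genome_hits >= 0L & records$genome_hits <= maxHits, ,
          drop = FALSE]
}

#' Keep genes expressed in leaves
#'
#' A gene is removed iff its read count is below `minCount` in strictly more
#' than `occupancy` of the samples ("more than 90%" is strict: a gene low in
#' exactly 90% of the samples is kept).
#'
#' @param counts a [LeafExpression-class] of unit `"counts"`, or a bare
#'   count matrix.
#' @param minCount minimum read count regarded as expressed.
#' @param occupancy fraction of samples over which low expression triggers
#'   removal.
#' @return Character vector of surviving gene identifiers.
#' @export
filterLeafExpression <- function(counts, minCount = 10, occupancy = 0.90) {
  m <- if (is(counts, "LeafExpression")) exprs(counts) else as.matrix(counts)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty count matrix")
  nLow <- rowSums(m < minCount)
  rownames(m)[nLow <= occupancy * ncol(m)]
}

.flPass <- function(records, flMin) {
  ref <- records$reference_protein_length
  qry <- records$query_protein_length
  # missing reference: completeness cannot be certified -> fails the stage
  ok <- !is.na(ref) & ref >= 1 & !is.na(qry)
  ok[ok] <- fullLengthFraction(qry[ok], ref[ok]) >= flMin
  ok
}

#' Build the curated TF/photosynthesis gene database
#'
#' Applies, in this fixed order, (i) the genome-hit filter (<= `maxHits`
#' loci), (ii) the protein full-length filter (FL >= `flMin`, inclusive;
#' records without a usable reference length fail), (iii) MapMan TF
#' validation — applied to TF records only, photosynthesis (PHOTO) records
#' pass this stage regardless of their flag — and (iv) the leaf-expression
#' filter on the count matrix. Inputs are deduplicated on `gene_id`
#' (identical duplicate rows collapsed; conflicting duplicates are an
#' error), and TF and PHOTO survivors are unioned.
#'
#' @param tfRecords,photoRecords annotation data.frames as produced by
#'   [simulateAnnotation()] (columns `gene_id`, `category`,
#'   `query_protein_length`, `reference_protein_length`, `genome_hits`,
#'   `mapman_validated`, ...). Either may be `NULL`.
#' @param counts count matrix or [LeafExpression-class] covering the
#'   record gene identifiers.
#' @param flMin inclusive full-length threshold.
#' @param maxHits inclusive genome-hit threshold.
#' @param minCount,occupancy leaf-expression filter parameters, see
#'   [filterLeafExpression()].
#'
#' @return A list with `database` (the surviving annotation rows) and
#'   `report` (a [FilterReport-class] with per-stage attrition).
#' @examples
#' sim <- simulateCounts(simulationConfig(
#'   moduleSpecs = data.frame(module = "m1", nGenes = 10L, sign = 1,
#'                            loading = 0.9),
#'   nBackgroundGenes = 20L, seed = 3L))
#' ann <- simulateAnnotation(sim$truth, seed = 3L)
#' res <- buildDatabase(ann[ann$category == "TF", ],
#'                      ann[ann$category == "PHOTO", ], sim$expression)
#' res$report
#' @export
buildDatabase <- function(tfRecords, photoRecords, counts,
                          flMin = 0.7, maxHits = 1L,
                          minCount = 10, occupancy = 0.90) {
  records <- rbind(tfRecords, photoRecords)
  if (is.null(records) || nrow(records) == 0L) stop("no input records")
  if (anyDuplicated(records$gene_id)) {
    dup <- unique(records$gene_id[duplicated(records$gene_id)])
    dupRows <- records[records$gene_id %in% dup, ]
    split <- split(dupRows, dupRows$gene_id)
    conflicting <- vapply(split, function(d) nrow(unique(d)) > 1L, logical(1))
    if (any(conflicting)) {
      stop("conflicting duplicate records for gene(s): ",
           paste(names(split)[conflicting], collapse = ", "))
    }
    records <- records[!duplicated(records$gene_id), , drop = FALSE]
  }

  stages <- data.frame(stage = character(0), n_in = integer(0),
                       n_removed = integer(0), n_out = integer(0))
  note <- function(stage, nIn, nOut) {
    rbind(stages, data.frame(stage = stage, n_in = nIn,
                             n_removed = nIn - nOut, n_out = nOut))
  }

  n0 <- nrow(records)
  records <- filterGenomeHits(records, maxHits)
  stages <- note("genome_hits", n0, nrow(records))

  n1 <- nrow(records)
  records <- records[.flPass(records, flMin), , drop = FALSE]
  stages <- note("full_length", n1, nrow(records))

  n2 <- nrow(records)
  keep <- records$category != "TF" | records$mapman_validated
  records <- records[keep, , drop = FALSE]
  stages <- note("mapman_tf", n2, nrow(records))

  n3 <- nrow(records)
  expressed <- filterLeafExpression(counts, minCount, occupancy)
  records <- records[records$gene_id %in% expressed, , drop = FALSE]
  stages <- note("leaf_expression", n3, nrow(records))

  report <- new("FilterReport", stages = stages, survivors = records$gene_id)
  list(database = records, report = report)
}

#' @describeIn FilterReport-class per-stage attrition table.
#' @param object,x a `FilterReport`.
#' @export
filterStages <- function(x) {
  stopifnot(is(x, "FilterReport"))
  x@stages
}

#' @describeIn FilterReport-class gene identifiers surviving all stages.
#' @export
survivors <- function(x) {
  stopifnot(is(x, "FilterReport"))
  x@survivors
}
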