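#' Guilt-by-association mining of developmental genes in modules
#'
#' Searches the queried clusters for genes carrying a GO term (exact-term
#' match; ancestor propagation is the annotation producer's responsibility)
#' whose profiles sit close to the cluster core, i.e. with score to core at
#' or above `minScore`. The default floor of 0.893 restricts hits to genes
#' tightly correlated with the centroid.
#'
#' @param result a [ClusterResult-class].
#' @param annotation annotation data.frame with `gene_id` and a `go_terms`
#'   column (semicolon-separated GO identifiers).
#' @param clusters integer cluster indices to search (default: the two
#'   largest, i.e. the anticorrelated module pair under the canonical size
#'   ordering).
#' @param goTerm GO identifier to match (default `GO:0044767`,
#'   developmental process).
#' @param minScore inclusive score-to-core floor.
#' @return data.frame of hits (`gene_id`, `cluster`, `score_to_core`,
#'   `go_term`), sorted by cluster then decreasing score.
#' @export
selectDevelopmental <- function(result, annotation, clusters = c(1L, 2L),
                                goTerm = "GO:0044767", minScore = 0.893) {
  stopifnot(is(result, "ClusterResult"))
  if (!all(clusters %in% seq_len(result@k))) {
    stop("unknown cluster id(s): ",
         paste(setdiff(clusters, seq_len(result@k)), collapse = ", "))
  }
  terms <- strsplit(annotation$go_terms, ";", fixed = TRUE)
  tagged <- annotation$gene_id[vapply(terms, function(t) goTerm %in% t,
                                      logical(1))]
  assignment <- result@assignment
  hits <- names(assignment)[assignment %in% clusters &
                              names(assignment) %in% tagged]
  hits <- hits[result@scoreToCore[hits] >= minScore]
  out <- data.frame(gene_id = hits,
                    cluster = unname(assignment[hits]),
                    score_to_core = unname(result@scoreToCore[hits]),
                    go_term = rep(goTerm, length(hits)),
                    stringsAsFactors = FALSE)
  out[order(out$cluster, -out$score_to_core, out$gene_id), , drop = FALSE]
}

#' Genes consistently differentially expressed across comparisons
#'
#' Intersects per-comparison DEG tables: a gene qualifies iff it passes
#' `FDR <= fdrMax` and `|log2FC| >= minAbsLfc` with the same fold-change
#' sign in every comparison of every group-A cultivar against every group-B
#' cultivar in every year. Sign consistency is required because a gene
#' "always differentially expressed" between the two leaf types must not
#' flip direction between comparisons.
#'
#' @param tables named list of DEG data.frames (`gene`, `log2FC`, `FDR`)
#'   carrying `cultivar_a`, `cultivar_b` and `year` attributes, as produced
#'   by [simulateDegTables()] or read from disk.
#' @param groupA,groupB cultivar name vectors for the two leaf-shape groups.
#' @param years production years that must be covered.
#' @param fdrMax,minAbsLfc DEG thresholds.
#' @return Sorted character vector of consistently differential genes.
#' @export
consistentDegs <- function(tables, groupA, groupB, years,
                           fdrMax = 0.05, minAbsLfc = 1) {
  wanted <- expand.grid(a = groupA, b = groupB, year = years,
                        stringsAsFactors = FALSE)
  key <- function(a, b, y) paste(a, b, y, sep = "|")
  have <- vapply(tables, function(tab) {
    key(attr(tab, "cultivar_a"), attr(tab, "cultivar_b"), attr(tab, "year"))
  }, character(1))
  need <- key(wanted$a, wanted$b, wanted$year)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("incomplete comparison design; missing: ",
         paste(missing, collapse = "; "))
  }
  use <- tables[match(need, have)]
  passSets <- lapply(use, function(tab) {
    ok <- tab$FDR <= fdrMax & abs(tab$log2FC) >= minAbsLfc
    setNames(sign(tab$log2FC)[ok], tab$gene[ok])
  })
  shared <- Reduce(intersect, lapply(passSets, names))
  consistent <- vapply(shared, function(g) {
    s <- vapply(passSets, function(ps) ps[[g]], numeric(1))
    all(s == s[1L])
  }, logical(1))
  sort(shared[consistent])
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of each annotation term's overrepresented
#' membership in `geneSet` relative to `universe`, with Benjamini-Hochberg
#' adjustment across terms.
#'
#' @param geneSet character vector of genes of interest (subset of
#'   `universe`).
#' @param annotation data.frame with `gene_id` and semicolon-separated
#'   `go_terms`.
#' @param universe background gene set.
#' @return data.frame with one row per term present in the universe:
#'   `term`, `count` (in `geneSet`), `expected`, `p`, `padj`, sorted by `p`.
#' @export
termEnrichment <- function(geneSet, annotation, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(geneSet %in% universe)) stop("geneSet must be within universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  pairs <- data.frame(
    gene = rep(ann$gene_id, lengths(strsplit(ann$go_terms, ";", fixed = TRUE))),
    term = unlist(strsplit(ann$go_terms, ";", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  n <- length(geneSet)
  nUniv <- length(universe)
  byTerm <- split(pairs$gene, pairs$term)
  rows <- lapply(names(byTerm), function(term) {
    members <- byTerm[[term]]
    k <- length(members)
    x <- sum(geneSet %in% members)
    p <- phyper(x - 1, k, nUniv - k, n, lower.tail = FALSE)
    data.frame(term = term, count = x, expected = n * k / nUniv, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}
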