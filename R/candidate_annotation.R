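catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end))
}

#' Features within a window around a SNP
#'
#' Returns every catalog feature whose interval intersects the closed window
#' `[max(1, pos - window), pos + window]` on the SNP's linkage group
#' (GFF3-style 1-based inclusive coordinates). A linkage group absent from
#' the catalog yields an empty result with a warning.
#'
#' @param chrom,pos SNP coordinates.
#' @param catalog Feature catalog data frame (`id`, `type`, `chrom`,
#'   `start`, `end`), e.g. from [simulate_annotation()] or
#'   [read_features()].
#' @param window Half-window size in bp (default 100 kbp); `0` returns only
#'   features covering the SNP position.
#' @return The intersecting rows of `catalog`.
#' @export
features_in_window <- function(chrom, pos, catalog, window = 100000) {
  stopifnot(length(chrom) == 1, length(pos) == 1, window >= 0)
  if (!chrom %in% catalog$chrom) {
    warning("linkage group ", chrom, " not present in the feature catalog")
    return(catalog[0, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = max(1, pos - window),
                              end = pos + window))
  hits <- GenomicRanges::findOverlaps(q, catalog_granges(catalog))
  out <- catalog[sort(unique(S4Vectors::subjectHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collate candidate genes and CpG islands from a genome scan
#'
#' For every suggestive and highly-suggestive SNP, extracts the catalog
#' features within `window` bp on both sides and de-duplicates them into a
#' candidate set, keeping the SNP-to-feature provenance.
#'
#' @param scan A [genome_scan()] result (must contain a `class` column).
#' @param catalog Feature catalog data frame.
#' @param window Half-window in bp (default 100 kbp).
#' @param classes Scan classes that qualify a SNP.
#' @return An object of class `candidate_set`: list with `genes` (unique
#'   gene ids), `cpg_islands` (unique island ids), and `provenance`
#'   (data.frame `chrom`, `pos`, `feature_id`, `feature_type`).
#' @export
collate_candidates <- function(scan, catalog, window = 100000,
                               classes = c("suggestive",
                                           "highly_suggestive")) {
  stopifnot("class" %in% names(scan))
  q <- scan[as.character(scan$class) %in% classes, , drop = FALSE]
  empty <- data.frame(chrom = character(), pos = integer(),
                      feature_id = character(), feature_type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(q)) {
    return(structure(list(genes = character(), cpg_islands = character(),
                          provenance = empty), class = "candidate_set"))
  }
  known <- q$chrom %in% catalog$chrom
  if (!all(known)) {
    warning(sum(!known), " SNP(s) on linkage groups absent from the catalog")
    q <- q[known, , drop = FALSE]
  }
  if (!nrow(q)) {
    return(structure(list(genes = character(), cpg_islands = character(),
                          provenance = empty), class = "candidate_set"))
  }
  qgr <- GenomicRanges::GRanges(
    seqnames = q$chrom,
    ranges = IRanges::IRanges(start = pmax(1, q$pos - window),
                              end = q$pos + window))
  hits <- GenomicRanges::findOverlaps(qgr, catalog_granges(catalog))
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  prov <- data.frame(chrom = q$chrom[qi], pos = q$pos[qi],
                     feature_id = catalog$id[fi],
                     feature_type = catalog$type[fi],
                     stringsAsFactors = FALSE)
  prov <- prov[order(prov$chrom, prov$pos, prov$feature_id), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(
    genes = sort(unique(prov$feature_id[prov$feature_type == "gene"])),
    cpg_islands = sort(unique(prov$feature_id[prov$feature_type ==
                                                "CpG_island"])),
    provenance = prov
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d genes, %d CpG islands (from %d SNP-feature links)\n",
              length(x$genes), length(x$cpg_islands), nrow(x$provenance)))
  invisible(x)
}

#' Map gene identifiers through an ortholog table
#'
#' Translates candidate gene ids (e.g. seabass Ensembl genes) to
#' better-annotated ortholog ids (e.g. zebrafish) via a two-column lookup
#' table; the mapping is data, not computation. Unmapped genes are dropped.
#'
#' @param genes Character vector of gene ids.
#' @param orthologs Data frame with columns `gene` and `ortholog`.
#' @return Sorted unique ortholog ids of the mapped genes.
#' @export
map_orthologs <- function(genes, orthologs) {
  stopifnot(all(c("gene", "ortholog") %in% names(orthologs)))
  sort(unique(orthologs$ortholog[orthologs$gene %in% genes]))
}

#' Term enrichment of a candidate gene set
#'
#' One-sided (greater) Fisher exact test per term on the 2x2 table
#' (candidate vs not) x (annotated vs not) over the background universe,
#' with Benjamini-Hochberg correction across terms. The annotation table is
#' generic: any gene-to-term mapping (GO terms, pathways, ...) can be
#' supplied. Terms with zero annotated genes in the background are skipped.
#'
#' @param candidates Character vector of candidate genes (must be contained
#'   in `background`).
#' @param gene2term Data frame with columns `gene` and `term`.
#' @param background Character vector: the gene universe.
#' @return Data frame per term: `term`, `n_annotated` (in background),
#'   `n_candidate` (annotated candidates), `p`, `q`, ordered by `p`.
#' @export
term_enrichment <- function(candidates, gene2term, background) {
  stopifnot(all(c("gene", "term") %in% names(gene2term)))
  candidates <- unique(as.character(candidates))
  background <- unique(as.character(background))
  if (!all(candidates %in% background)) {
    stop("candidates must be a subset of the background universe",
         call. = FALSE)
  }
  empty <- data.frame(term = character(), n_annotated = integer(),
                      n_candidate = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(candidates)) return(empty)
  g2t <- gene2term[gene2term$gene %in% background, , drop = FALSE]
  if (!nrow(g2t)) return(empty)
  N <- length(background)
  n_cand <- length(candidates)
  terms <- sort(unique(g2t$term))
  m <- vapply(terms, function(t)
    length(unique(g2t$gene[g2t$term == t])), 1L)
  k <- vapply(terms, function(t)
    length(intersect(unique(g2t$gene[g2t$term == t]), candidates)), 1L)
  keep <- m > 0
  terms <- terms[keep]; m <- m[keep]; k <- k[keep]
  p <- stats::phyper(k - 1, m, N - m, n_cand, lower.tail = FALSE)
  out <- data.frame(term = terms, n_annotated = m, n_candidate = k,
                    p = unname(p), q = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
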