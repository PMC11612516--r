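#' Simulate a toy genome annotation (genes and CpG islands)
#'
#' Places non-overlapping gene features and interspersed CpG-island features
#' on the configured linkage groups, with 1-based inclusive coordinates and
#' stable identifiers. Genes never overlap each other; CpG islands are placed
#' independently (they may overlap genes, as real islands often sit in
#' promoters).
#'
#' @param config A [sim_config()] object (uses `n_lg`, `lg_length`,
#'   `seed`; annotation draws use `seed + 1` so counts and annotation are
#'   decoupled but jointly reproducible).
#' @param n_genes,n_cpg Total number of genes / CpG islands, spread evenly
#'   over linkage groups.
#' @param gene_length,cpg_length Length ranges (bp) sampled uniformly.
#' @return A feature catalog: data.frame with columns `id`,
#'   `type` (`"gene"` or `"CpG_island"`), `chrom`, `start`, `end`, sorted by
#'   `chrom` then `start`.
#' @export
simulate_annotation <- function(config, n_genes = 300, n_cpg = 60,
                                gene_length = c(2000, 20000),
                                cpg_length = c(500, 2000)) {
  stopifnot(inherits(config, "sim_config"), config$n_lg >= 1, n_genes >= 1)
  local_seed(config$seed + 1L, {
    lg_of_gene <- sort(rep_len(seq_len(config$n_lg), n_genes))
    lg_of_cpg <- if (n_cpg > 0) sort(rep_len(seq_len(config$n_lg), n_cpg)) else integer()
    rows <- list()
    for (l in seq_len(config$n_lg)) {
      g <- sum(lg_of_gene == l)
      if (g > 0) {
        len <- sample(gene_length[1]:gene_length[2], g, replace = TRUE)
        free <- config$lg_length - sum(len)
        if (free < g) stop("linkage group too short for requested genes",
                           call. = FALSE)
        # sorted gaps + cumulative lengths => non-overlapping ordered genes
        offs <- sort(sample.int(free, g))
        start <- offs + c(0L, cumsum(len[-g]))
        rows[[length(rows) + 1L]] <- data.frame(
          type = "gene", chrom = paste0("LG", l),
          start = start, end = start + len - 1L, stringsAsFactors = FALSE)
      }
      k <- sum(lg_of_cpg == l)
      if (k > 0) {
        len <- sample(cpg_length[1]:cpg_length[2], k, replace = TRUE)
        start <- vapply(len, function(x)
          sample.int(config$lg_length - x, 1L), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "CpG_island", chrom = paste0("LG", l),
          start = start, end = start + len - 1L, stringsAsFactors = FALSE)
      }
    }
    cat_ <- do.call(rbind, rows)
    cat_ <- cat_[order(cat_$chrom, cat_$start, cat_$type), , drop = FALSE]
    ng <- sum(cat_$type == "gene")
    nc <- sum(cat_$type == "CpG_island")
    cat_$id <- NA_character_
    cat_$id[cat_$type == "gene"] <- sprintf("gene_%04d", seq_len(ng))
    cat_$id[cat_$type == "CpG_island"] <- sprintf("cpg_%04d", seq_len(nc))
    rownames(cat_) <- NULL
    cat_[, c("id", "type", "chrom", "start", "end")]
  })
}
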