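#' Gene-gene functional interactome
#'
#' An undirected edge list with per-edge coupling probabilities (FunCoup
#' style), plus the gene universe used as the enrichment background. Edges
#' are canonicalized so `gene_a < gene_b`; self-loops and duplicate edges
#' are rejected.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `probability`.
#' @param genes Character vector: the gene universe (background for
#'   enrichment). Defaults to the genes present in `edges`.
#' @param candidates Optional candidate gene set carried through subgraph
#'   operations.
#' @return An object of class `interactome`.
#' @export
interactome <- function(edges, genes = NULL, candidates = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("gene_a", "gene_b", "probability") %in% names(edges)))
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  if (any(edges$probability < 0 | edges$probability > 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edges (up to orientation) are not allowed", call. = FALSE)
  }
  edges <- edges[order(a, b), c("gene_a", "gene_b", "probability")]
  rownames(edges) <- NULL
  genes <- sort(unique(c(genes %||% character(), a, b)))
  structure(list(edges = edges, genes = genes,
                 candidates = sort(unique(as.character(candidates %||% character())))),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d edges, %d-gene universe", nrow(x$edges),
              length(x$genes)))
  if (length(x$candidates)) cat(sprintf(", %d candidates", length(x$candidates)))
  cat("\n")
  invisible(x)
}

#' Genes present in a network's edge list
#'
#' @param net An [interactome].
#' @return Sorted character vector of genes with at least one edge.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "probability")], directed = FALSE)
}

#' Simulate an interactome with a planted candidate module
#'
#' Builds a background random graph whose edge coupling probabilities all lie
#' below 0.90 (so they are removed by the standard confidence filter), mixed
#' with a planted module whose internal edges carry probability at least
#' `p_within`. Used to validate the network-enrichment machinery: after
#' filtering at 0.90 only the planted module survives, and its enrichment
#' must beat the permutation null.
#'
#' @param genes Character vector: the gene universe.
#' @param planted_module Subset of `genes` forming the planted module
#'   (internally fully connected).
#' @param p_within Minimum coupling probability of planted edges; must be at
#'   least 0.90 so they survive the confidence filter.
#' @param p_background Background edge density (Erdos-Renyi).
#' @param seed RNG seed.
#' @return An [interactome] with the full `genes` universe.
#' @export
simulate_interactome <- function(genes, planted_module = character(),
                                 p_within = 0.95, p_background = 0.01,
                                 seed = 1) {
  genes <- as.character(genes)
  planted_module <- as.character(planted_module)
  if (!all(planted_module %in% genes)) {
    stop("planted_module must be a subset of the gene universe", call. = FALSE)
  }
  stopifnot(p_within >= 0.90, p_background >= 0, p_background < 1)
  local_seed(seed, {
    n <- length(genes)
    edges <- list()
    if (p_background > 0 && n >= 2) {
      n_bg <- stats::rbinom(1L, choose(n, 2), p_background)
      if (n_bg > 0) {
        # oversample index pairs, then dedupe; cheap at fixture scale
        m <- ceiling(n_bg * 1.5) + 10L
        i <- sample.int(n, m, replace = TRUE)
        j <- sample.int(n, m, replace = TRUE)
        lo <- pmin(i, j); hi <- pmax(i, j)
        ok <- lo != hi & !duplicated(paste(lo, hi))
        lo <- lo[ok][seq_len(min(n_bg, sum(ok)))]
        hi <- hi[ok][seq_len(min(n_bg, sum(ok)))]
        edges$background <- data.frame(
          gene_a = genes[lo], gene_b = genes[hi],
          probability = stats::runif(length(lo), 0.30, 0.8999),
          stringsAsFactors = FALSE)
      }
    }
    if (length(planted_module) >= 2) {
      pr <- t(utils::combn(planted_module, 2))
      edges$planted <- data.frame(
        gene_a = pr[, 1], gene_b = pr[, 2],
        probability = stats::runif(nrow(pr), p_within, 1),
        stringsAsFactors = FALSE)
    }
    e <- do.call(rbind, edges) %||% data.frame(
      gene_a = character(), gene_b = character(), probability = numeric())
    if (nrow(e)) {
      a <- pmin(e$gene_a, e$gene_b)
      b <- pmax(e$gene_a, e$gene_b)
      key <- paste(a, b)
      # planted edges win over coincident background edges
      e <- e[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    }
    interactome(e, genes = genes)
  })
}
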