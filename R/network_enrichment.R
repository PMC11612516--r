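#' Filter an interactome by coupling probability
#'
#' Keeps edges whose predicted coupling probability reaches `threshold`
#' (boundary inclusive: an edge at exactly 0.90 is retained). High-confidence
#' couplings of this kind are strong predictors of true functional
#' interactions. The gene universe is unchanged. Idempotent.
#'
#' @param net An [interactome].
#' @param threshold Minimum coupling probability (default 0.90).
#' @return A filtered [interactome].
#' @export
filter_by_probability <- function(net, threshold = 0.90) {
  stopifnot(inherits(net, "interactome"))
  interactome(net$edges[net$edges$probability >= threshold, , drop = FALSE],
              genes = net$genes, candidates = net$candidates)
}

#' Direct-interaction subgraph of a candidate gene set
#'
#' Keeps only edges with at least one candidate endpoint. Non-candidate
#' endpoints that remain become "intermediate partners".
#'
#' @param net A (probability-filtered) [interactome].
#' @param candidates Character vector of candidate genes.
#' @return An [interactome] whose `candidates` field records the candidate
#'   set (restricted to the universe).
#' @export
direct_interaction_subgraph <- function(net, candidates) {
  stopifnot(inherits(net, "interactome"))
  candidates <- unique(as.character(candidates))
  keep <- net$edges$gene_a %in% candidates | net$edges$gene_b %in% candidates
  interactome(net$edges[keep, , drop = FALSE], genes = net$genes,
              candidates = intersect(candidates, net$genes))
}

#' Intermediate partners of a candidate subgraph
#'
#' @param net A [direct_interaction_subgraph()] result.
#' @return Non-candidate genes carrying at least one edge.
#' @export
partners <- function(net) {
  stopifnot(inherits(net, "interactome"))
  setdiff(network_genes(net), net$candidates)
}

#' Prune intermediate partners by candidate connectivity
#'
#' Retains an intermediate partner iff it has at least `k` distinct
#' candidate neighbors (its "degree connectivity" towards the candidate
#' set); candidate-candidate edges are always kept, and candidates without
#' any remaining edge drop out of the network. `k = 1` leaves the subgraph's
#' partners unchanged, and the network at `k + 1` is always a subgraph of
#' the network at `k`.
#'
#' With `mode = "total"` the partner's total degree in the subgraph is used
#' instead of its distinct-candidate-neighbor count.
#'
#' @param net A [direct_interaction_subgraph()] result.
#' @param k Degree threshold (>= 1).
#' @param mode `"candidate"` (default) or `"total"`.
#' @return A pruned [interactome].
#' @export
prune_partners <- function(net, k, mode = c("candidate", "total")) {
  stopifnot(inherits(net, "interactome"))
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  e <- net$edges
  cand <- net$candidates
  a_cand <- e$gene_a %in% cand
  b_cand <- e$gene_b %in% cand
  # partner-candidate incidences (edges with exactly one candidate endpoint)
  pc_partner <- c(e$gene_a[!a_cand & b_cand], e$gene_b[a_cand & !b_cand])
  pc_cand <- c(e$gene_b[!a_cand & b_cand], e$gene_a[a_cand & !b_cand])
  if (!length(pc_partner)) {
    score <- stats::setNames(integer(0), character(0))
  } else if (mode == "candidate") {
    score <- tapply(pc_cand, pc_partner, function(x) length(unique(x)))
  } else {
    all_part <- c(e$gene_a[!a_cand], e$gene_b[!b_cand])
    score <- table(all_part)[unique(pc_partner)]
  }
  keep_partner <- names(score)[score >= k]
  keep_edge <- (a_cand & b_cand) |
    (a_cand & e$gene_b %in% keep_partner) |
    (b_cand & e$gene_a %in% keep_partner)
  interactome(e[keep_edge, , drop = FALSE], genes = net$genes,
              candidates = cand)
}

#' Fisher enrichment of candidates in a gene network
#'
#' One-sided (greater) Fisher exact p-value for the 2x2 classification of
#' the `N`-gene universe by network membership and candidacy
#' (hypergeometric upper tail).
#'
#' @param network_genes Character vector of genes in the network.
#' @param candidates Character vector of candidate genes.
#' @param N Universe size (background; defaults elsewhere to the number of
#'   annotated genes in the genome).
#' @return The enrichment p-value.
#' @export
enrichment_fisher <- function(network_genes, candidates, N) {
  network_genes <- unique(as.character(network_genes))
  candidates <- unique(as.character(candidates))
  n_union <- length(union(network_genes, candidates))
  if (N < n_union) {
    stop("universe size N smaller than |network union candidates|",
         call. = FALSE)
  }
  x <- length(intersect(network_genes, candidates))
  stats::phyper(x - 1, length(candidates), N - length(candidates),
                length(network_genes), lower.tail = FALSE)
}

#' Degree-connectivity sweep with per-step enrichment
#'
#' Iteratively increases the partner degree threshold `k`, pruning the
#' candidate subgraph with [prune_partners()] at each step and recording the
#' network size and its candidate enrichment p-value
#' ([enrichment_fisher()]). Stops early once the network is empty (an empty
#' network at `k = 1` is recorded as a single row with p = 1, which is what
#' an empty candidate set produces). Network sizes are non-increasing in
#' `k`.
#'
#' @param net A [direct_interaction_subgraph()] result.
#' @param k_max Largest degree threshold to visit.
#' @param N Universe size; defaults to the interactome's gene universe.
#' @param mode Partner-degree mode, see [prune_partners()].
#' @return Data frame per visited `k`: `k`, `n_genes`, `n_candidates`
#'   (candidates inside the network), `p`.
#' @export
degree_sweep <- function(net, k_max = 10, N = NULL, mode = "candidate") {
  stopifnot(inherits(net, "interactome"), k_max >= 1)
  N <- N %||% length(net$genes)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    pruned <- prune_partners(net, k, mode = mode)
    g <- network_genes(pruned)
    if (!length(g)) {
      if (k == 1L) {
        rows[[k]] <- data.frame(k = 1L, n_genes = 0L, n_candidates = 0L,
                                p = 1)
      }
      break
    }
    rows[[k]] <- data.frame(
      k = k, n_genes = length(g),
      n_candidates = length(intersect(g, net$candidates)),
      p = enrichment_fisher(g, net$candidates, N))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Permutation null for the degree-sweep enrichment
#'
#' Repeats the degree sweep for random candidate sets of size `n` drawn
#' uniformly without replacement from the gene universe, giving the null
#' distribution of enrichment p-values at every degree threshold. Sweeps
#' that leave the network empty at some `k` contribute p = 1 there (no
#' enrichment is observable in an empty network).
#'
#' @param net A probability-filtered [interactome] (the universe to draw
#'   from and to build subgraphs in).
#' @param n Candidate-set size of each random draw.
#' @param k_max Largest degree threshold.
#' @param n_perm Number of permutations (the reference analysis uses 1000).
#' @param seed Optional RNG seed.
#' @param N Universe size; defaults to the interactome's gene universe.
#' @param mode Partner-degree mode, see [prune_partners()].
#' @return List with `p` (an `n_perm x k_max` matrix of null p-values),
#'   `summary` (data.frame `k`, `p_median`, `p_q05`), and `minima`
#'   (per-permutation minimum p over `k`).
#' @export
permutation_null <- function(net, n, k_max = 10, n_perm = 1000, seed = NULL,
                             N = NULL, mode = "candidate") {
  stopifnot(inherits(net, "interactome"), n_perm >= 1)
  N <- N %||% length(net$genes)
  if (n > length(net$genes)) {
    stop("candidate-set size exceeds the gene universe", call. = FALSE)
  }
  p <- local_seed(seed, {
    out <- matrix(1, n_perm, k_max)
    for (i in seq_len(n_perm)) {
      draw <- sample(net$genes, n)
      curve <- degree_sweep(direct_interaction_subgraph(net, draw),
                            k_max = k_max, N = N, mode = mode)
      if (!is.null(curve) && nrow(curve)) out[i, curve$k] <- curve$p
    }
    out
  })
  summary <- data.frame(
    k = seq_len(k_max),
    p_median = apply(p, 2, stats::median),
    p_q05 = apply(p, 2, stats::quantile, probs = 0.05, type = 1)
  )
  list(p = p, summary = summary, minima = apply(p, 1, min))
}

#' Largest connected component of a network
#'
#' @param net An [interactome] (typically a pruned candidate subgraph).
#' @return The [interactome] restricted to the component with most nodes;
#'   ties are broken by the lexicographically smallest node id. An empty
#'   network is returned unchanged.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "interactome"))
  if (!nrow(net$edges)) return(net)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # among maximal components, take the one holding the smallest node id
    firsts <- vapply(best, function(b)
      min(names(comp$membership)[comp$membership == b]), "")
    best <- best[order(firsts)][1]
  }
  nodes <- names(comp$membership)[comp$membership == best]
  keep <- net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes
  interactome(net$edges[keep, , drop = FALSE], genes = net$genes,
              candidates = net$candidates)
}

#' Degree and radiality of every network node
#'
#' Degree is the number of directly connected nodes. Radiality is a
#' closeness-like centrality computed within each connected component:
#' `radiality(v) = sum_u (diam + 1 - d(v, u)) / (n_comp - 1)` over all other
#' nodes `u` of the component, where `d` is the unweighted shortest-path
#' length and `diam` the component diameter. A singleton component has
#' radiality 0 by convention.
#'
#' @param net An [interactome].
#' @return Data frame per node: `gene`, `degree`, `radiality`, `component`,
#'   `is_candidate`.
#' @export
topology_indices <- function(net) {
  stopifnot(inherits(net, "interactome"))
  if (!nrow(net$edges)) {
    return(data.frame(gene = character(), degree = integer(),
                      radiality = numeric(), component = integer(),
                      is_candidate = logical(), stringsAsFactors = FALSE))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  rad <- stats::setNames(numeric(length(deg)), names(deg))
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    if (length(nodes) == 1) { rad[nodes] <- 0; next }
    d <- igraph::distances(g, v = nodes, to = nodes)
    diam <- max(d)
    rad[nodes] <- (rowSums(diam + 1 - d) - (diam + 1)) / (length(nodes) - 1)
  }
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    radiality = unname(rad[names(deg)]),
                    component = as.integer(comp$membership[names(deg)]),
                    is_candidate = names(deg) %in% net$candidates,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the consensus network from sweep and permutation results
#'
#' Picks the smallest degree threshold `k` at which the observed enrichment
#' p-value falls below the permutation null's 5th percentile while the null
#' median has become non-significant (> `alpha`), i.e. the point where
#' random gene sets have collapsed to non-significance but the observed
#' candidates have not. If no `k` qualifies, the `k` minimizing the observed
#' p is used. Returns the largest connected component of the pruned network
#' at the selected `k`.
#'
#' @param net A [direct_interaction_subgraph()] result.
#' @param curve A [degree_sweep()] result for `net`.
#' @param null A [permutation_null()] result on the same universe.
#' @param alpha Significance level for the null median (default 0.05).
#' @param mode Partner-degree mode.
#' @return List with `k` (selected threshold) and `network` (the largest
#'   component [interactome] at that `k`).
#' @export
select_consensus_network <- function(net, curve, null, alpha = 0.05,
                                     mode = "candidate") {
  stopifnot(inherits(net, "interactome"))
  s <- null$summary[match(curve$k, null$summary$k), ]
  qualifying <- which(curve$p < s$p_q05 & s$p_median > alpha)
  k <- if (length(qualifying)) curve$k[min(qualifying)] else
    curve$k[which.min(curve$p)]
  list(k = k,
       network = largest_component(prune_partners(net, k, mode = mode)))
}
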