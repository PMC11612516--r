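# Shared fixture builders. Everything is generated in code; no stored data.

# pool_counts from a list of L x 4 base-count matrices (one per track)
make_counts <- function(chrom, pos, ref, mats, pools, replicates = NULL) {
  L <- length(pos)
  replicates <- replicates %||% rep("r1", length(mats))
  counts <- array(0L, dim = c(L, length(mats), 4))
  for (t in seq_along(mats)) counts[, t, ] <- mats[[t]]
  pool_counts(
    data.frame(chrom = chrom, pos = pos, ref = ref,
               stringsAsFactors = FALSE),
    counts,
    data.frame(pool = pools, replicate = replicates,
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# snp_table straight from ref/alt count matrices
make_snp_table <- function(ref_count, alt_count, pools,
                           chrom = NULL, pos = NULL,
                           ref = "A", alt = "C") {
  L <- nrow(ref_count)
  colnames(ref_count) <- pools
  colnames(alt_count) <- pools
  structure(list(
    sites = data.frame(
      chrom = chrom %||% rep("LG1", L),
      pos = pos %||% seq_len(L) * 100L,
      ref = rep_len(ref, L), alt = rep_len(alt, L),
      stringsAsFactors = FALSE),
    ref_count = ref_count, alt_count = alt_count, pools = pools),
    class = "snp_table")
}

toy_design <- function(pools, groups) {
  data.frame(pool = pools, group = groups, stringsAsFactors = FALSE)
}

# exact occupancy pmf: P(distinct = k) after d uniform draws from n boxes.
# Independent dynamic-programming oracle for the representation module.
occupancy_pmf <- function(n, d) {
  p <- c(1, rep(0, n))
  for (step in seq_len(d)) {
    k <- 0:n
    stay <- p * (k / n)
    grow <- c(0, p[-(n + 1)] * ((n - k[-(n + 1)]) / n))
    p <- stay + grow
  }
  p
}

# small planted-module interactome fixture used by several network tests
planted_network_fixture <- function(n_genes = 200, module_size = 12,
                                    p_background = 0.05, seed = 404) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  module <- genes[seq_len(module_size)]
  net <- simulate_interactome(genes, planted_module = module,
                              p_within = 0.95,
                              p_background = p_background, seed = seed)
  list(genes = genes, module = module, net = net)
}
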