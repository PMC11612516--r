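#' Simulate Pool-Seq read counts with ground truth
#'
#' Generates pooled read counts for a farmed-vs-wild study design under a
#' Balding--Nichols drift model with optional selection at a subset of loci,
#' together with a truth table for parameter-recovery tests.
#'
#' For each site, an ancestral frequency `p0` is drawn from the configured
#' Beta distribution truncated to `[0.05, 0.95]`. Each population's allele
#' frequency is drawn from `Beta(p(1-c)/c, (1-p)(1-c)/c)` with `c` the
#' group's drift intensity and `p = p0`, except in farmed pools at selected
#' loci where `p = clamp(p0 +/- delta, 0.01, 0.99)` (shift direction fixed
#' per locus). Sampling is two-stage: `2N` allele copies are drawn
#' binomially per pool (finite-pool variance), then each technical
#' replicate's read depth is Poisson with mean
#' `mean_depth * replicate_fraction` and alternate reads are binomial in the
#' pool's copy frequency. All draws are bit-reproducible given
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{counts}{A [pool_counts] object with two technical-replicate
#'       tracks per pool.}
#'     \item{truth}{Data frame per site: `chrom`, `pos`, `ref`, `alt`,
#'       `selected` flag, and the true group frequency means `p_wild`,
#'       `p_farmed`.}
#'     \item{design}{Data frame mapping `pool` to `group`
#'       (`farmed`/`wild`).}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    L <- config$n_sites
    J <- config$n_farmed + config$n_wild
    pools <- c(sprintf("f%02d", seq_len(config$n_farmed)),
               sprintf("w%02d", seq_len(config$n_wild)))
    group <- rep(c("farmed", "wild"), c(config$n_farmed, config$n_wild))
    drift <- ifelse(group == "farmed", config$drift_farmed, config$drift_wild)

    # site coordinates: spread over linkage groups, unique sorted positions
    lg <- sort(rep_len(seq_len(config$n_lg), L))
    chrom <- paste0("LG", lg)
    pos <- integer(L)
    for (l in unique(lg)) {
      idx <- which(lg == l)
      pos[idx] <- sort(sample.int(config$lg_length, length(idx)))
    }
    ref <- sample(BASES, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")

    # ancestral frequencies, truncated Beta via inverse-CDF
    a <- config$ancestral_beta[1]
    b <- config$ancestral_beta[2]
    lo <- stats::pbeta(0.05, a, b)
    hi <- stats::pbeta(0.95, a, b)
    p0 <- stats::qbeta(stats::runif(L, lo, hi), a, b)

    selected <- rep(FALSE, L)
    p_farmed <- p0
    if (config$n_selected > 0) {
      sel <- sample.int(L, config$n_selected)
      selected[sel] <- TRUE
      sgn <- sample(c(-1, 1), config$n_selected, replace = TRUE)
      p_farmed[sel] <- pmin(pmax(p0[sel] + sgn * config$selection_shift,
                                 0.01), 0.99)
    }

    counts <- array(0L, dim = c(L, 2L * J, 4L))
    tracks <- data.frame(pool = rep(pools, each = 2L),
                         replicate = rep(c("r1", "r2"), J),
                         stringsAsFactors = FALSE)
    ref_i <- match(ref, BASES)
    alt_i <- match(alt, BASES)
    rep_mean <- config$mean_depth * config$replicate_fraction
    for (j in seq_len(J)) {
      m <- if (group[j] == "farmed") p_farmed else p0
      c_ <- drift[j]
      p_pop <- stats::rbeta(L, m * (1 - c_) / c_, (1 - m) * (1 - c_) / c_)
      n2 <- 2L * config$pool_sizes[j]
      copy_freq <- stats::rbinom(L, n2, p_pop) / n2
      for (r in 1:2) {
        t <- 2L * (j - 1L) + r
        depth <- stats::rpois(L, rep_mean)
        alt_reads <- stats::rbinom(L, depth, copy_freq)
        counts[cbind(seq_len(L), t, alt_i)] <- alt_reads
        counts[cbind(seq_len(L), t, ref_i)] <-
          counts[cbind(seq_len(L), t, ref_i)] + (depth - alt_reads)
      }
    }

    sites <- data.frame(chrom = chrom, pos = pos, ref = ref,
                        stringsAsFactors = FALSE)
    list(
      counts = pool_counts(sites, counts, tracks),
      truth = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         selected = selected, p_wild = p0,
                         p_farmed = p_farmed, stringsAsFactors = FALSE),
      design = data.frame(pool = pools, group = group,
                          stringsAsFactors = FALSE)
    )
  })
}
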