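#' Configuration for the Pool-Seq simulator
#'
#' Describes the study design emulated by [simulate_counts()]: a set of farmed
#' and natural-origin (wild) population pools genotyped by pooled sequencing.
#' Defaults mirror a Mediterranean seabass domestication design: 12 farmed and
#' 8 wild pools of 11--25 diploid individuals each, with farmed populations
#' having drifted much more from the common ancestor than wild ones (small
#' effective sizes under captive breeding), and a minority of loci whose
#' farmed allele frequencies are additionally displaced by selection.
#'
#' Drift follows the Balding--Nichols parameterization: population allele
#' frequency `p_j ~ Beta(p(1-c)/c, (1-p)(1-c)/c)`, where `p` is the ancestral
#' (or selection-shifted) frequency and `c` plays the role of the population's
#' FST to the ancestor.
#'
#' @param n_farmed,n_wild Number of farmed / wild pools.
#' @param pool_sizes Diploid individuals per pool, farmed pools first. A
#'   scalar is recycled; `NULL` uses the default mixed design (mostly 25, a
#'   few pools of 11--12).
#' @param n_sites Number of simulated variable sites.
#' @param n_selected Number of sites with a selection-displaced farmed mean.
#' @param ancestral_beta Length-2 shape parameters of the ancestral allele
#'   frequency Beta distribution, truncated to `[0.05, 0.95]`.
#' @param drift_wild,drift_farmed Balding--Nichols drift intensity `c` in
#'   (0, 1) for each group (approximately the group's FST to the ancestor).
#' @param selection_shift Mean allele-frequency displacement `delta` of the
#'   farmed group at selected loci, in `[0, 1]`; the direction is randomized
#'   per locus.
#' @param mean_depth Expected total read depth per site per pool (summed over
#'   the two technical replicates when `replicate_fraction = 0.5`).
#' @param replicate_fraction Fraction of `mean_depth` assigned to each of the
#'   two technical replicates, in (0, 1].
#' @param n_lg Number of linkage groups.
#' @param lg_length Length of each linkage group in bp.
#' @param seed Integer RNG seed; every generator is bit-reproducible given it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [simulate_annotation()],
#'   [simulate_interactome()]
#' @export
sim_config <- function(n_farmed = 12, n_wild = 8, pool_sizes = NULL,
                       n_sites = 5000, n_selected = 25,
                       ancestral_beta = c(0.7, 0.7),
                       drift_wild = 0.01, drift_farmed = 0.1,
                       selection_shift = 0.4, mean_depth = 60,
                       replicate_fraction = 0.5,
                       n_lg = 24, lg_length = 2e6, seed = 1) {
  n_farmed <- as.integer(n_farmed)
  n_wild <- as.integer(n_wild)
  if (is.null(pool_sizes)) {
    farmed_sizes <- rep_len(c(12L, rep(25L, 11L)), n_farmed)
    wild_sizes <- rep_len(c(25L, 11L, 25L, 12L, 25L, 25L, 25L, 25L), n_wild)
    pool_sizes <- c(farmed_sizes, wild_sizes)
  } else {
    pool_sizes <- as.integer(rep_len(pool_sizes, n_farmed + n_wild))
  }
  cfg <- list(
    n_farmed = n_farmed, n_wild = n_wild, pool_sizes = pool_sizes,
    n_sites = as.integer(n_sites), n_selected = as.integer(n_selected),
    ancestral_beta = as.numeric(ancestral_beta),
    drift_wild = drift_wild, drift_farmed = drift_farmed,
    selection_shift = selection_shift, mean_depth = mean_depth,
    replicate_fraction = replicate_fraction,
    n_lg = as.integer(n_lg), lg_length = as.integer(lg_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_farmed < 1 || cfg$n_wild < 1) {
    stop("need at least one farmed and one wild pool", call. = FALSE)
  }
  if (any(cfg$pool_sizes < 1)) stop("pool_sizes must be >= 1", call. = FALSE)
  if (cfg$n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (cfg$n_selected < 0 || cfg$n_selected > cfg$n_sites) {
    stop("n_selected must lie in [0, n_sites]", call. = FALSE)
  }
  if (length(cfg$ancestral_beta) != 2 || any(cfg$ancestral_beta <= 0)) {
    stop("ancestral_beta must be two positive shape parameters", call. = FALSE)
  }
  for (nm in c("drift_wild", "drift_farmed")) {
    c_ <- cfg[[nm]]
    if (!is.numeric(c_) || c_ <= 0 || c_ >= 1) {
      stop(nm, " must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$selection_shift < 0 || cfg$selection_shift > 1) {
    stop("selection_shift must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  if (cfg$replicate_fraction <= 0 || cfg$replicate_fraction > 1) {
    stop("replicate_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$n_lg < 1) stop("n_lg must be >= 1", call. = FALSE)
  if (cfg$lg_length < cfg$n_sites) {
    stop("lg_length too small for the requested number of sites", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pool-Seq simulation config\n")
  cat(sprintf("  pools: %d farmed + %d wild (sizes %s)\n", x$n_farmed, x$n_wild,
              paste(range(x$pool_sizes), collapse = "-")))
  cat(sprintf("  sites: %d (%d selected, delta = %g)\n",
              x$n_sites, x$n_selected, x$selection_shift))
  cat(sprintf("  drift: farmed %g, wild %g; depth %g x %g per replicate\n",
              x$drift_farmed, x$drift_wild,
              x$mean_depth, x$replicate_fraction))
  cat(sprintf("  genome: %d LGs of %d bp; seed %d\n",
              x$n_lg, x$lg_length, x$seed))
  invisible(x)
}
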