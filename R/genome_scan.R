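#' Pairwise FST from two allele frequencies
#'
#' Classical heterozygosity estimator: `FST = (hT - hS) / hT` with
#' `hT = 2 * pbar * (1 - pbar)`, `pbar = (pA + pB) / 2`, and `hS` the mean of
#' the two within-population heterozygosities `2 p (1 - p)`. Returns 0 where
#' `hT = 0` (both populations fixed for the same allele). Vectorized over
#' sites.
#'
#' @param pA,pB Allele frequency vectors in `[0, 1]`.
#' @return FST values in `[0, 1]`.
#' @export
pairwise_fst <- function(pA, pB) {
  stopifnot(length(pA) == length(pB),
            all(pA >= 0 & pA <= 1), all(pB >= 0 & pB <= 1))
  pbar <- (pA + pB) / 2
  hT <- 2 * pbar * (1 - pbar)
  hS <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
  ifelse(hT == 0, 0, (hT - hS) / hT)
}

check_design <- function(freqs, design, min_per_group = 1L) {
  stopifnot(is.data.frame(design),
            all(c("pool", "group") %in% names(design)),
            all(design$group %in% c("farmed", "wild")))
  if (!all(rownames(freqs) %in% design$pool)) {
    stop("populations missing from the design table", call. = FALSE)
  }
  grp <- design$group[match(rownames(freqs), design$pool)]
  if (sum(grp == "farmed") < min_per_group ||
      sum(grp == "wild") < min_per_group) {
    stop("each group needs at least ", min_per_group, " population(s)",
         call. = FALSE)
  }
  grp
}

#' Mean farmed-vs-wild FST per SNP
#'
#' Averages [pairwise_fst()] over all farmed x wild population pairs,
#' site by site.
#'
#' @param freqs Allele frequency matrix `(pools, sites)` with pool rownames.
#' @param design Data frame with columns `pool` and `group`
#'   (`"farmed"`/`"wild"`).
#' @return Numeric vector of per-SNP mean cross-group FST.
#' @export
mean_cross_group_fst <- function(freqs, design) {
  grp <- check_design(freqs, design)
  farmed <- which(grp == "farmed")
  wild <- which(grp == "wild")
  acc <- numeric(ncol(freqs))
  for (i in farmed) for (j in wild) {
    acc <- acc + pairwise_fst(freqs[i, ], freqs[j, ])
  }
  unname(acc / (length(farmed) * length(wild)))
}

# Vectorized-by-site two-sided Fisher exact p for 2x2 tables
# [[a, b], [c, d]] (rows: alleles; cols: groups), by the point-probability
# rule: sum of hypergeometric probabilities not exceeding the observed one.
fisher2x2 <- function(a, b, c_, d,
                      alternative = c("two.sided", "greater"),
                      warn_empty = TRUE) {
  alternative <- match.arg(alternative)
  n <- length(a)
  p <- numeric(n)
  empty <- (a + b == 0) | (c_ + d == 0) | (a + c_ == 0) | (b + d == 0)
  if (warn_empty && any(empty)) {
    warning("empty margin in ", sum(empty), " table(s); p set to 1")
  }
  rel_tol <- 1 + 1e-7
  for (i in seq_len(n)) {
    if (empty[i]) { p[i] <- 1; next }
    m <- a[i] + b[i]          # row-1 total
    nn <- c_[i] + d[i]        # row-2 total
    k <- a[i] + c_[i]         # column-1 total
    lo <- max(0L, k - nn)
    hi <- min(m, k)
    dd <- stats::dhyper(lo:hi, m, nn, k)
    if (alternative == "two.sided") {
      p[i] <- min(1, sum(dd[dd <= dd[a[i] - lo + 1L] * rel_tol]))
    } else {
      p[i] <- min(1, sum(dd[(lo:hi) >= a[i]]))
    }
  }
  p
}

#' Fisher exact test of group allele-count differences per SNP
#'
#' For every SNP, read counts are summed within the farmed and wild groups
#' and the 2x2 table (ref, alt) x (farmed, wild) is tested with a two-sided
#' Fisher exact test using the point-probability rule (sum over all tables
#' with hypergeometric probability not exceeding the observed table's).
#' An empty margin yields p = 1 with a warning.
#'
#' @param snps A [call_biallelic()] result.
#' @param design Design data frame (`pool`, `group`).
#' @return Numeric vector of two-sided p-values, one per SNP.
#' @export
fisher_group_test <- function(snps, design) {
  stopifnot(inherits(snps, "snp_table"))
  if (!nrow(snps$sites)) return(numeric())
  grp <- design$group[match(snps$pools, design$pool)]
  if (anyNA(grp)) stop("pools missing from the design table", call. = FALSE)
  f <- grp == "farmed"
  w <- grp == "wild"
  fisher2x2(rowSums(snps$ref_count[, f, drop = FALSE]),
            rowSums(snps$ref_count[, w, drop = FALSE]),
            rowSums(snps$alt_count[, f, drop = FALSE]),
            rowSums(snps$alt_count[, w, drop = FALSE]))
}

#' Scaled covariance matrix of population allele frequencies
#'
#' Moment-based estimate of the matrix Omega used to whiten population
#' allele frequencies before computing the XtX statistic. For each site the
#' frequencies are centered on the across-population mean and standardized
#' by its binomial scale: `z[j, l] = (p[j, l] - pi[l]) / sqrt(pi[l] (1 -
#' pi[l]))`; monomorphic sites (`pi` of 0 or 1) are skipped. Then
#' `Omega = Z Z' / L + lambda I` with `lambda = 1e-6 * trace(Z Z' / L)`,
#' which guarantees strict positive definiteness.
#'
#' @param freqs Allele frequency matrix `(pools, sites)`.
#' @param lambda_scale Ridge fraction of the trace (default `1e-6`).
#' @return A symmetric positive-definite `J x J` matrix with pool dimnames.
#' @export
estimate_omega <- function(freqs, lambda_scale = 1e-6) {
  stopifnot(is.matrix(freqs), nrow(freqs) >= 2)
  z <- standardized_freqs(freqs)
  keep <- !is.na(z[1, ])
  if (!any(keep)) stop("no polymorphic sites to estimate Omega", call. = FALSE)
  zk <- z[, keep, drop = FALSE]
  omega <- zk %*% t(zk) / ncol(zk)
  lambda <- lambda_scale * sum(diag(omega))
  omega <- omega + diag(max(lambda, .Machine$double.eps), nrow(freqs))
  dimnames(omega) <- list(rownames(freqs), rownames(freqs))
  omega
}

# J x L standardized deviations; columns at monomorphic sites are NA
standardized_freqs <- function(freqs) {
  pi_ <- colMeans(freqs)
  scale_ <- sqrt(pi_ * (1 - pi_))
  bad <- pi_ <= 0 | pi_ >= 1
  z <- sweep(freqs, 2, pi_, "-")
  z <- sweep(z, 2, ifelse(bad, 1, scale_), "/")
  z[, bad] <- NA_real_
  z
}

#' XtX differentiation statistic per SNP
#'
#' Computes `xtx_l = z_l' Omega^{-1} z_l` for every site, where `z_l` is the
#' standardized frequency deviation vector of [estimate_omega()] and Omega
#' the scaled covariance of population allele frequencies. Whitening by
#' Omega makes the statistic robust to shared demography; under neutrality
#' it is calibrated against a chi-squared distribution with J (number of
#' populations) degrees of freedom, from which the upper-tail p-value is
#' taken. Monomorphic sites yield `NA`.
#'
#' @param freqs Allele frequency matrix `(pools, sites)`.
#' @param omega Omega matrix from [estimate_omega()].
#' @return Data frame with columns `xtx` and `p`.
#' @export
xtx_stat <- function(freqs, omega) {
  stopifnot(is.matrix(freqs), nrow(freqs) == nrow(omega))
  J <- nrow(freqs)
  z <- standardized_freqs(freqs)
  na_site <- is.na(z[1, ])
  z0 <- z
  z0[, na_site] <- 0
  w <- tryCatch(solve(omega, z0),
                error = function(e) stop(
                  "Omega is singular; re-estimate with a larger ",
                  "regularization (lambda_scale)", call. = FALSE))
  xtx <- colSums(z0 * w)
  xtx[na_site] <- NA_real_
  data.frame(xtx = unname(xtx),
             p = stats::pchisq(unname(xtx), df = J, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#'
#' @param pvals Numeric p-values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("p-values must not contain NA/NaN", call. = FALSE)
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus outlier classification
#'
#' A SNP is `highly_suggestive` when its adjusted p-value is below `q_high`
#' in both scan tracks (Fisher and XtX); `suggestive` when it is below
#' `q_high` in one track and below `q_sugg` in the other; `none` otherwise.
#' The rule is monotone: decreasing either q-value never demotes the class.
#'
#' @param fisher_q,xtx_q Adjusted p-values of the two tracks.
#' @param q_high Consensus threshold (default `1e-5`).
#' @param q_sugg Relaxed threshold (default `1e-3`).
#' @return Factor with levels `none`, `suggestive`, `highly_suggestive`.
#' @export
classify_consensus <- function(fisher_q, xtx_q, q_high = 1e-5,
                               q_sugg = 1e-3) {
  stopifnot(length(fisher_q) == length(xtx_q))
  high <- fisher_q < q_high & xtx_q < q_high
  sugg <- !high & ((fisher_q < q_high & xtx_q < q_sugg) |
                     (xtx_q < q_high & fisher_q < q_sugg))
  factor(ifelse(high, "highly_suggestive",
                ifelse(sugg, "suggestive", "none")),
         levels = c("none", "suggestive", "highly_suggestive"))
}

#' Principal component analysis of population allele frequencies
#'
#' Column-centers the `(pools, sites)` frequency matrix and decomposes it by
#' SVD. Explained-variance fractions are the squared singular values over
#' their sum.
#'
#' @param freqs Allele frequency matrix `(pools, sites)`.
#' @return List with `coordinates` (pools x PCs) and `explained`
#'   (variance fractions, summing to 1 over the retained PCs).
#' @export
population_pca <- function(freqs) {
  stopifnot(is.matrix(freqs), nrow(freqs) >= 2)
  x <- scale(freqs, center = TRUE, scale = FALSE)
  total <- sum(x^2)
  if (total == 0) {
    warning("zero total variance; all explained fractions are 0")
    k <- min(nrow(freqs), ncol(freqs))
    return(list(
      coordinates = matrix(0, nrow(freqs), k,
                           dimnames = list(rownames(freqs),
                                           paste0("PC", seq_len(k)))),
      explained = rep(0, k)))
  }
  sv <- svd(x)
  coords <- sv$u %*% diag(sv$d, length(sv$d))
  dimnames(coords) <- list(rownames(freqs),
                           paste0("PC", seq_along(sv$d)))
  list(coordinates = coords, explained = sv$d^2 / sum(sv$d^2))
}

#' Run the full per-SNP genome scan
#'
#' Computes, for every SNP: the mean farmed-vs-wild FST, the pooled
#' two-sided Fisher exact p, the Omega-corrected XtX statistic and its
#' chi-squared p, Benjamini-Hochberg q-values per track (applied separately
#' genome-wide, mirroring two independently run programs), and the
#' consensus class.
#'
#' @param snps A [call_biallelic()] result.
#' @param design Design data frame (`pool`, `group`).
#' @param q_high,q_sugg Consensus thresholds, see [classify_consensus()].
#' @return Data frame (one row per SNP): `chrom`, `pos`, `ref`, `alt`,
#'   `mean_fst`, `fisher_p`, `fisher_q`, `xtx`, `xtx_p`, `xtx_q`, `class`;
#'   the Omega matrix is attached as attribute `"omega"`.
#' @export
genome_scan <- function(snps, design, q_high = 1e-5, q_sugg = 1e-3) {
  stopifnot(inherits(snps, "snp_table"))
  if (!nrow(snps$sites)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      mean_fst = numeric(), fisher_p = numeric(),
                      fisher_q = numeric(), xtx = numeric(),
                      xtx_p = numeric(), xtx_q = numeric(),
                      class = factor(character(),
                                     levels = c("none", "suggestive",
                                                "highly_suggestive")),
                      stringsAsFactors = FALSE)
    return(out)
  }
  freqs <- allele_freq_matrix(snps)
  check_design(freqs, design, min_per_group = 2L)
  mean_fst <- mean_cross_group_fst(freqs, design)
  fisher_p <- fisher_group_test(snps, design)
  omega <- estimate_omega(freqs)
  xt <- xtx_stat(freqs, omega)
  if (anyNA(xt$p)) {
    stop("monomorphic sites in SNP table; re-run call_biallelic()",
         call. = FALSE)
  }
  fisher_q <- bh_adjust(fisher_p)
  xtx_q <- bh_adjust(xt$p)
  out <- data.frame(
    chrom = snps$sites$chrom, pos = snps$sites$pos,
    ref = snps$sites$ref, alt = snps$sites$alt,
    mean_fst = mean_fst, fisher_p = fisher_p, fisher_q = fisher_q,
    xtx = xt$xtx, xtx_p = xt$p, xtx_q = xtx_q,
    class = classify_consensus(fisher_q, xtx_q, q_high, q_sugg),
    stringsAsFactors = FALSE
  )
  attr(out, "omega") <- omega
  out
}
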