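#' Call biallelic SNPs from merged pooled counts
#'
#' Applies the minor-allele-frequency screen and the biallelic rule to
#' depth-filtered, replicate-merged counts. Allele frequencies are computed
#' from read counts summed across all populations (`maf_scope = "global"`,
#' the default dataset-wide screen); alleles with frequency strictly below
#' `maf` are excluded (so a frequency of exactly 1% survives), and a site is
#' emitted iff exactly two alleles remain. The reference base is kept as the
#' ref allele when it survives, otherwise ref/alt are assigned by descending
#' global count with ties broken in base order A < C < G < T.
#'
#' With `maf_scope = "per_population"` an allele is retained when its
#' frequency reaches `maf` in at least one population.
#'
#' @param x A merged [pool_counts] object (one track per pool).
#' @param maf Minor-allele frequency threshold (default 0.01).
#' @param maf_scope `"global"` or `"per_population"`; see Details.
#' @return An object of class `snp_table`: list with `sites`
#'   (`chrom`, `pos`, `ref`, `alt`), integer matrices `ref_count` and
#'   `alt_count` of dimension `(sites, pools)`, and `pools`.
#' @export
call_biallelic <- function(x, maf = 0.01,
                           maf_scope = c("global", "per_population")) {
  stopifnot(inherits(x, "pool_counts"), maf >= 0, maf < 0.5)
  maf_scope <- match.arg(maf_scope)
  L <- nrow(x$sites)
  J <- nrow(x$tracks)
  # per-site per-base totals across pools: L x 4
  global <- rowSums(aperm(x$counts, c(1, 3, 2)), dims = 2)
  tot <- rowSums(global)
  if (maf_scope == "global") {
    freq <- global / pmax(tot, 1)
    keep_allele <- freq >= maf & global > 0
  } else {
    depth_jt <- rowSums(x$counts, dims = 2)           # L x J
    keep_allele <- matrix(FALSE, L, 4)
    for (b in 1:4) {
      fb <- x$counts[, , b] / pmax(depth_jt, 1)
      keep_allele[, b] <- apply(fb >= maf, 1, any) & global[, b] > 0
    }
  }
  n_alleles <- rowSums(keep_allele)
  emit <- which(n_alleles == 2L)
  if (!length(emit)) {
    return(snp_table_empty(x$tracks$pool))
  }
  ka <- keep_allele[emit, , drop = FALSE]
  first <- max.col(ka, ties.method = "first")
  last <- max.col(ka, ties.method = "last")
  b1 <- BASES[first]
  b2 <- BASES[last]
  cnt1 <- global[cbind(emit, first)]
  cnt2 <- global[cbind(emit, last)]
  refb <- x$sites$ref[emit]
  # ref allele: the reference base when it survived; otherwise the
  # higher-count allele (ties already broken by base order via first/last)
  ref_allele <- ifelse(refb == b1 | refb == b2, refb,
                       ifelse(cnt2 > cnt1, b2, b1))
  alt_allele <- ifelse(ref_allele == b1, b2, b1)
  Lk <- length(emit)
  ref_count <- matrix(
    x$counts[cbind(rep(emit, J), rep(seq_len(J), each = Lk),
                   rep(match(ref_allele, BASES), J))], Lk, J)
  alt_count <- matrix(
    x$counts[cbind(rep(emit, J), rep(seq_len(J), each = Lk),
                   rep(match(alt_allele, BASES), J))], Lk, J)
  pools <- x$tracks$pool
  colnames(ref_count) <- pools
  colnames(alt_count) <- pools
  structure(list(
    sites = data.frame(chrom = x$sites$chrom[emit], pos = x$sites$pos[emit],
                       ref = ref_allele, alt = alt_allele,
                       stringsAsFactors = FALSE),
    ref_count = ref_count, alt_count = alt_count, pools = pools
  ), class = "snp_table")
}

snp_table_empty <- function(pools) {
  m <- matrix(integer(), 0, length(pools),
              dimnames = list(NULL, pools))
  structure(list(
    sites = data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       stringsAsFactors = FALSE),
    ref_count = m, alt_count = m, pools = pools
  ), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d biallelic SNPs x %d pools\n",
              nrow(x$sites), length(x$pools)))
  invisible(x)
}

#' Population-by-site alternate allele frequency matrix
#'
#' @param snps A [call_biallelic()] result.
#' @return Numeric matrix of dimension `(pools, sites)` with entries
#'   `alt_count / (ref_count + alt_count)`.
#' @export
allele_freq_matrix <- function(snps) {
  stopifnot(inherits(snps, "snp_table"))
  depth <- snps$ref_count + snps$alt_count
  if (nrow(depth) && any(depth == 0)) {
    stop("zero depth encountered; apply filter_depth() before calling SNPs",
         call. = FALSE)
  }
  f <- t(snps$alt_count / depth)
  rownames(f) <- snps$pools
  f
}
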