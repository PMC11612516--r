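#' Per-position pooled read counts
#'
#' Container for bam-readcount-style data: for every genomic position, the
#' number of reads supporting each base (A, C, G, T) in every
#' population-replicate track. This is the raw input of the pipeline.
#'
#' @param sites A data.frame with columns `chrom`, `pos` (1-based), `ref`
#'   (reference base, one of A/C/G/T).
#' @param counts An integer array of dimension `(sites, tracks, 4)`; the third
#'   dimension is ordered A, C, G, T.
#' @param tracks A data.frame with columns `pool` and `replicate` describing
#'   the second array dimension.
#'
#' @return An object of class `pool_counts`.
#' @export
pool_counts <- function(sites, counts, tracks) {
  sites <- as.data.frame(sites)
  tracks <- as.data.frame(tracks)
  stopifnot(
    all(c("chrom", "pos", "ref") %in% names(sites)),
    all(c("pool", "replicate") %in% names(tracks)),
    length(dim(counts)) == 3,
    dim(counts)[1] == nrow(sites),
    dim(counts)[2] == nrow(tracks),
    dim(counts)[3] == 4
  )
  if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (!all(sites$ref %in% BASES)) {
    stop("reference bases must be one of A/C/G/T", call. = FALSE)
  }
  if (any(counts < 0)) stop("read counts must be >= 0", call. = FALSE)
  dimnames(counts) <- list(NULL, NULL, BASES)
  structure(
    list(sites = sites[, c("chrom", "pos", "ref")],
         counts = counts, tracks = tracks),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d sites x %d tracks (%d pools)\n",
              nrow(x$sites), nrow(x$tracks), length(unique(x$tracks$pool))))
  invisible(x)
}

#' Total read depth per site and track
#'
#' @param x A [pool_counts] object.
#' @return An integer matrix `(sites, tracks)` of base-summed depths.
#' @export
site_depths <- function(x) {
  stopifnot(inherits(x, "pool_counts"))
  d <- rowSums(x$counts, dims = 2)
  colnames(d) <- paste(x$tracks$pool, x$tracks$replicate, sep = ".")
  d
}

#' Combine pool_counts objects over tracks
#'
#' Binds the track dimension of several count sets that describe the same
#' sites (for example, one file per technical replicate). Sites must match
#' exactly; a conflicting reference base at any site is an error.
#'
#' @param ... [pool_counts] objects sharing the same site table.
#' @return A single [pool_counts] object.
#' @export
combine_pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "pool_counts")) {
    xs <- xs[[1]]
  }
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "pool_counts")))
  ref <- xs[[1]]$sites
  for (x in xs[-1]) {
    if (!identical(x$sites[, c("chrom", "pos")], ref[, c("chrom", "pos")])) {
      stop("site keys differ between count sets", call. = FALSE)
    }
    bad <- which(x$sites$ref != ref$ref)
    if (length(bad)) {
      stop(sprintf("conflicting reference base at %s:%d ('%s' vs '%s')",
                   ref$chrom[bad[1]], ref$pos[bad[1]],
                   ref$ref[bad[1]], x$sites$ref[bad[1]]), call. = FALSE)
    }
  }
  counts <- do.call(abind3, lapply(xs, `[[`, "counts"))
  tracks <- do.call(rbind, lapply(xs, `[[`, "tracks"))
  rownames(tracks) <- NULL
  pool_counts(ref, counts, tracks)
}

# bind 3-d arrays along the second dimension
abind3 <- function(...) {
  arrs <- list(...)
  L <- dim(arrs[[1]])[1]
  ntr <- vapply(arrs, function(a) dim(a)[2], 1L)
  out <- array(0L, dim = c(L, sum(ntr), 4))
  at <- 0L
  for (a in arrs) {
    out[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  out
}

#' Merge technical replicates by summing base counts
#'
#' Collapses the track dimension to one track per population by base-wise
#' addition of read counts, emulating the merging of technical replicates
#' before genotyping. The operation is invariant to replicate order.
#'
#' @param x A [pool_counts] object (or a list of them sharing sites, which is
#'   combined first).
#' @return A [pool_counts] object with one track per pool
#'   (`replicate = "merged"`).
#' @export
merge_replicates <- function(x) {
  if (is.list(x) && !inherits(x, "pool_counts")) x <- combine_pool_counts(x)
  stopifnot(inherits(x, "pool_counts"))
  pools <- unique(x$tracks$pool)
  L <- nrow(x$sites)
  out <- array(0L, dim = c(L, length(pools), 4))
  for (t in seq_len(nrow(x$tracks))) {
    j <- match(x$tracks$pool[t], pools)
    out[, j, ] <- out[, j, ] + x$counts[, t, ]
  }
  pool_counts(x$sites, out,
              data.frame(pool = pools, replicate = "merged",
                         stringsAsFactors = FALSE))
}

#' Filter sites by minimum read depth in every pool
#'
#' Retains a site only if its total (base-summed) depth reaches `min_depth`
#' in every track, so that downstream between-group tests have every pool
#' genotyped. Intended for merged counts; the rule is applied per track.
#'
#' @param x A [pool_counts] object.
#' @param min_depth Minimum inclusive depth (default 25, the threshold
#'   justified by [representation_summary()] for pools of 25 individuals).
#' @return A [pool_counts] object restricted to passing sites.
#' @export
filter_depth <- function(x, min_depth = 25) {
  stopifnot(inherits(x, "pool_counts"), min_depth >= 0)
  d <- rowSums(x$counts, dims = 2)
  keep <- rowSums(d >= min_depth) == ncol(d)
  pool_counts(x$sites[keep, , drop = FALSE],
              x$counts[keep, , , drop = FALSE], x$tracks)
}
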