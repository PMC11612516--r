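# Readers and writers for the pipeline's plain-text formats. Every writer
# stamps a '#'-prefixed header with the tool version (and, where relevant,
# the configuration hash and seed); readers skip such comments.

#' Write pooled read counts as TSV
#'
#' Long format: one row per site x track with columns `chrom`, `pos`, `ref`,
#' `pool`, `replicate`, `A`, `C`, `G`, `T`.
#'
#' @param x A [pool_counts] object.
#' @param path Output file.
#' @param comments Header comment lines.
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(x, path, comments = output_header()) {
  stopifnot(inherits(x, "pool_counts"))
  L <- nrow(x$sites)
  Tn <- nrow(x$tracks)
  df <- data.frame(
    chrom = rep(x$sites$chrom, Tn), pos = rep(x$sites$pos, Tn),
    ref = rep(x$sites$ref, Tn),
    pool = rep(x$tracks$pool, each = L),
    replicate = rep(x$tracks$replicate, each = L),
    A = as.vector(x$counts[, , "A"]), C = as.vector(x$counts[, , "C"]),
    G = as.vector(x$counts[, , "G"]), T = as.vector(x$counts[, , "T"]),
    stringsAsFactors = FALSE)
  write_tsv_commented(df, path, comments)
}

#' Read pooled read counts from TSV
#'
#' Accepts the long format written by [write_pool_counts()].
#'
#' @param path Input file.
#' @return A [pool_counts] object.
#' @export
read_pool_counts <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("chrom", "pos", "ref", "pool", "replicate", "A", "C", "G", "T")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$replicate <- as.character(df$replicate)
  tracks <- unique(df[, c("pool", "replicate")])
  rownames(tracks) <- NULL
  key <- paste(df$pool, df$replicate, sep = "\r")
  tkey <- paste(tracks$pool, tracks$replicate, sep = "\r")
  first <- df[key == tkey[1], c("chrom", "pos", "ref")]
  L <- nrow(first)
  counts <- array(0L, dim = c(L, nrow(tracks), 4))
  for (t in seq_len(nrow(tracks))) {
    sub <- df[key == tkey[t], , drop = FALSE]
    if (nrow(sub) != L ||
        !identical(sub$chrom, first$chrom) || !identical(sub$pos, first$pos)) {
      stop("track ", tkey[t], " does not share the site table", call. = FALSE)
    }
    bad <- which(sub$ref != first$ref)
    if (length(bad)) {
      stop(sprintf("conflicting reference base at %s:%d in %s",
                   first$chrom[bad[1]], first$pos[bad[1]], path),
           call. = FALSE)
    }
    counts[, t, ] <- as.matrix(sub[, BASES])
  }
  pool_counts(first, counts, tracks)
}

#' Read a bam-readcount-style file for one track
#'
#' Parses lines of the form `chrom pos ref depth base:count[:...] ...`,
#' keeping the A/C/G/T counts (the first two colon-separated subfields of
#' each base field).
#'
#' @param path Input file.
#' @param pool,replicate Track labels to attach.
#' @return A [pool_counts] object with a single track.
#' @export
read_bam_readcount <- function(path, pool, replicate = "r1") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  L <- length(parts)
  sites <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    ref = toupper(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(L, 1L, 4L))
  for (i in seq_len(L)) {
    for (field in parts[[i]][-(1:4)]) {
      sub <- strsplit(field, ":", fixed = TRUE)[[1]]
      b <- match(toupper(sub[1]), BASES)
      if (!is.na(b)) counts[i, 1L, b] <- as.integer(sub[2])
    }
  }
  pool_counts(sites, counts,
              data.frame(pool = pool, replicate = replicate,
                         stringsAsFactors = FALSE))
}

#' Write a SNP table as TSV
#'
#' Long format: one row per SNP x pool with columns `chrom`, `pos`, `ref`,
#' `alt`, `pool`, `ref_count`, `alt_count`.
#'
#' @param snps A `snp_table` from [call_biallelic()].
#' @param path Output file.
#' @param comments Header comment lines.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path, comments = output_header()) {
  stopifnot(inherits(snps, "snp_table"))
  L <- nrow(snps$sites)
  J <- length(snps$pools)
  df <- data.frame(
    chrom = rep(snps$sites$chrom, J), pos = rep(snps$sites$pos, J),
    ref = rep(snps$sites$ref, J), alt = rep(snps$sites$alt, J),
    pool = rep(snps$pools, each = L),
    ref_count = as.vector(snps$ref_count),
    alt_count = as.vector(snps$alt_count), stringsAsFactors = FALSE)
  write_tsv_commented(df, path, comments)
}

#' Read a SNP table written by [write_snp_table()]
#'
#' @param path Input file.
#' @return A `snp_table` object.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("chrom", "pos", "ref", "alt", "pool", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("SNP table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pools <- unique(df$pool)
  if (!nrow(df)) return(snp_table_empty(pools))
  first <- df[df$pool == pools[1], c("chrom", "pos", "ref", "alt")]
  L <- nrow(first)
  rc <- matrix(0L, L, length(pools), dimnames = list(NULL, pools))
  ac <- rc
  for (j in seq_along(pools)) {
    sub <- df[df$pool == pools[j], , drop = FALSE]
    stopifnot(nrow(sub) == L)
    rc[, j] <- sub$ref_count
    ac[, j] <- sub$alt_count
  }
  rownames(first) <- NULL
  structure(list(sites = first, ref_count = rc, alt_count = ac,
                 pools = pools), class = "snp_table")
}

#' Write merged counts in PoPoolation2 sync format
#'
#' One line per site: `chrom pos ref` followed by one
#' `A:T:C:G:N:del` colon-separated count column per pool (N and del are 0
#' here, as the container holds A/C/G/T only).
#'
#' @param x A merged [pool_counts] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "pool_counts"))
  if (!nrow(x$sites)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- vapply(seq_len(nrow(x$tracks)), function(t) {
    paste(x$counts[, t, "A"], x$counts[, t, "T"], x$counts[, t, "C"],
          x$counts[, t, "G"], 0L, 0L, sep = ":")
  }, character(nrow(x$sites)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(x$sites))
  lines <- do.call(paste, c(list(x$sites$chrom, x$sites$pos, x$sites$ref),
                            split(cols, col(cols)), list(sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a design table (pool to group)
#'
#' @param path TSV with columns `pool` and `group` (`farmed`/`wild`).
#' @return The design data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("pool", "group") %in% names(df))) {
    stop("design file must have columns 'pool' and 'group'", call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("farmed", "wild"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write or read a feature catalog as GFF3
#'
#' `write_features()` exports the catalog (genes and CpG islands) as GFF3
#' with the feature id in the `ID` attribute; `read_features()` imports a
#' GFF3 file and returns the catalog rows of the requested feature types.
#' Coordinates are 1-based inclusive on both sides.
#'
#' @param catalog Feature catalog data frame (`id`, `type`, `chrom`,
#'   `start`, `end`).
#' @param path GFF3 file.
#' @param types Feature types to keep on import.
#' @return `write_features()`: `path`, invisibly. `read_features()`: the
#'   catalog data frame, sorted by `chrom`, `start`.
#' @export
write_features <- function(catalog, path) {
  gr <- catalog_granges(catalog)
  S4Vectors::mcols(gr)$type <- catalog$type
  S4Vectors::mcols(gr)$ID <- catalog$id
  S4Vectors::mcols(gr)$source <- "poolscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, types = c("gene", "CpG_island")) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    id = as.character(S4Vectors::mcols(gr)$ID),
    type = as.character(S4Vectors::mcols(gr)$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  df <- df[df$type %in% types, , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an interaction TSV
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `probability`.
#' @param genes Optional gene universe to attach (enrichment background).
#' @return An [interactome].
#' @export
read_interactome <- function(path, genes = NULL) {
  df <- read_tsv_commented(path)
  if (!all(c("gene_a", "gene_b", "probability") %in% names(df))) {
    stop("interaction file must have columns gene_a, gene_b, probability",
         call. = FALSE)
  }
  interactome(df, genes = genes)
}

#' Write an interactome's edges as TSV
#'
#' @param net An [interactome].
#' @param path Output file.
#' @param comments Header comment lines.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path, comments = output_header()) {
  stopifnot(inherits(net, "interactome"))
  write_tsv_commented(net$edges, path, comments)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene` and `term`.
#' @return The annotation data frame.
#' @export
read_gene2term <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("gene", "term") %in% names(df))) {
    stop("annotation file must have columns 'gene' and 'term'",
         call. = FALSE)
  }
  df
}

#' Read an ortholog mapping table
#'
#' @param path TSV with columns `gene` and `ortholog`.
#' @return The mapping data frame.
#' @export
read_orthologs <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("gene", "ortholog") %in% names(df))) {
    stop("ortholog file must have columns 'gene' and 'ortholog'",
         call. = FALSE)
  }
  df
}

#' Export a network for Cytoscape
#'
#' `write_sif()` writes the simple interaction format (`gene_a pp gene_b`);
#' `write_graphml()` writes GraphML via igraph, carrying the edge
#' probability attribute.
#'
#' @param net An [interactome].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  writeLines(paste(net$edges$gene_a, "pp", net$edges$gene_b, sep = "\t"),
             path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  if (!nrow(net$edges)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    g <- as_igraph(net)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
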