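#' Pipeline configuration
#'
#' Bundles input paths and every analysis threshold for [run_pipeline()].
#' Defaults are the reference constants of the analysis: minimum depth 25,
#' MAF 1%, 100 kbp windows, coupling probability 0.90, consensus thresholds
#' `1e-5` / `1e-3`, 1000 permutations.
#'
#' @param counts Path to a counts TSV ([write_pool_counts()] format).
#' @param design Path to a design TSV (`pool`, `group`).
#' @param annotation Optional path to a GFF3 feature file.
#' @param interactome Optional path to an interaction TSV.
#' @param gene2term Optional path to a gene-to-term TSV.
#' @param orthologs Optional path to an ortholog TSV.
#' @param out_dir Output directory (created if missing).
#' @param min_depth,maf,window,prob_threshold,q_high,q_sugg,k_max,n_perm
#'   Analysis thresholds.
#' @param seed RNG seed recorded in every output header and used for the
#'   permutation null.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, annotation = NULL,
                            interactome = NULL, gene2term = NULL,
                            orthologs = NULL, out_dir = "poolscan_out",
                            min_depth = 25, maf = 0.01, window = 100000,
                            prob_threshold = 0.90, q_high = 1e-5,
                            q_sugg = 1e-3, k_max = 10, n_perm = 1000,
                            seed = 1) {
  stopifnot(min_depth >= 0, maf >= 0, maf < 0.5, window >= 0,
            prob_threshold >= 0, prob_threshold <= 1,
            q_high > 0, q_high < 1, q_sugg > 0, q_sugg < 1,
            k_max >= 1, n_perm >= 1)
  structure(list(
    counts = counts, design = design, annotation = annotation,
    interactome = interactome, gene2term = gene2term,
    orthologs = orthologs, out_dir = out_dir,
    min_depth = min_depth, maf = maf, window = window,
    prob_threshold = prob_threshold, q_high = q_high, q_sugg = q_sugg,
    k_max = k_max, n_perm = n_perm, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Schema checks for every configured input file: required columns, group
#' labels, GFF3 coordinate sanity (1-based, `end >= start`, naming the
#' offending record), interaction probabilities in `[0, 1]`. Fatal
#' violations are collected in `errors`; milder observations in `warnings`.
#'
#' @param config A [pipeline_config()].
#' @return List with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errors <- character()
  warnings <- character()
  note <- function(x) errors <<- c(errors, x)

  for (slot in c("counts", "design")) {
    if (is.null(config[[slot]]) || !file.exists(config[[slot]])) {
      note(sprintf("%s file missing: %s", slot,
                   config[[slot]] %||% "<unset>"))
    }
  }
  for (slot in c("annotation", "interactome", "gene2term", "orthologs")) {
    if (!is.null(config[[slot]]) && !file.exists(config[[slot]])) {
      note(sprintf("%s file missing: %s", slot, config[[slot]]))
    }
  }
  if (!length(errors)) {
    cdf <- tryCatch(read_tsv_commented(config$counts), error = function(e) e)
    if (inherits(cdf, "error")) {
      note(paste("counts unreadable:", conditionMessage(cdf)))
    } else {
      miss <- setdiff(c("chrom", "pos", "ref", "pool", "replicate", BASES),
                      names(cdf))
      if (length(miss)) {
        note(paste("counts missing column(s):",
                   paste(miss, collapse = ", ")))
      } else {
        if (any(cdf$pos < 1)) note("counts: positions below 1")
        if (any(as.matrix(cdf[, BASES]) < 0)) note("counts: negative counts")
      }
    }
    ddf <- tryCatch(read_design(config$design), error = function(e) e)
    if (inherits(ddf, "error")) {
      note(paste("design invalid:", conditionMessage(ddf)))
    } else {
      for (g in c("farmed", "wild")) {
        if (sum(ddf$group == g) < 2) {
          warnings <- c(warnings, sprintf(
            "fewer than 2 '%s' pools; pairwise statistics need >= 2", g))
        }
      }
      if (!inherits(cdf, "error") && "pool" %in% names(cdf)) {
        unknown <- setdiff(unique(cdf$pool), ddf$pool)
        if (length(unknown)) {
          note(paste("counts contain pools absent from the design:",
                     paste(unknown, collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(config$annotation) && file.exists(config$annotation)) {
    lines <- readLines(config$annotation)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    for (i in body) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 9) {
        note(sprintf("GFF3 line %d: fewer than 9 columns", i))
        next
      }
      s <- suppressWarnings(as.integer(f[4]))
      e <- suppressWarnings(as.integer(f[5]))
      if (is.na(s) || is.na(e)) {
        note(sprintf("GFF3 line %d: non-numeric coordinates", i))
      } else if (s < 1) {
        note(sprintf("GFF3 line %d (%s): start below 1", i, f[1]))
      } else if (e < s) {
        note(sprintf("GFF3 line %d (%s %s:%s-%s): end < start",
                     i, f[3], f[1], f[4], f[5]))
      }
    }
  }
  if (!is.null(config$interactome) && file.exists(config$interactome)) {
    idf <- tryCatch(read_tsv_commented(config$interactome),
                    error = function(e) e)
    if (inherits(idf, "error") ||
        !all(c("gene_a", "gene_b", "probability") %in% names(idf))) {
      note("interactome: missing gene_a/gene_b/probability columns")
    } else if (any(idf$probability < 0 | idf$probability > 1)) {
      bad <- which(idf$probability < 0 | idf$probability > 1)[1]
      note(sprintf("interactome row %d: probability %s outside [0, 1]",
                   bad, idf$probability[bad]))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full Pool-Seq domestication scan pipeline
#'
#' Executes, in order: SNP calling (replicate merging, depth filter, MAF and
#' biallelic screens), the genome scan (mean FST, Fisher, Omega/XtX, BH,
#' consensus classes, PCA), candidate annotation (when a GFF3 is
#' configured), and network enrichment (when an interactome is configured).
#' Each stage writes its outputs under `config$out_dir` with a header
#' recording the tool version, configuration hash and seed; a JSON manifest
#' summarizes per-stage input hashes, row counts and wall time. Fully
#' deterministic given `config$seed` (stage outputs of a rerun are
#' byte-identical).
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  chk <- validate_inputs(config)
  if (length(chk$errors)) {
    stop("invalid inputs:\n  ", paste(chk$errors, collapse = "\n  "),
         call. = FALSE)
  }
  for (w in chk$warnings) warning(w, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash covers the analysis identity, not where outputs land
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  hdr <- output_header(seed = config$seed, cfg_hash = hash)
  manifest <- list(tool = "poolscan",
                   version = as.character(utils::packageVersion("poolscan")),
                   config_hash = hash, seed = config$seed, stages = list())
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, inputs, n_in, n_out, params, secs) {
    manifest$stages[[name]] <<- list(
      inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      rows_in = n_in, rows_out = n_out, params = params,
      wall_time_s = round(secs, 3))
  }
  msg <- function(...) message(sprintf(...))

  ## stage 1: SNP calling ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  raw <- read_pool_counts(config$counts)
  design <- read_design(config$design)
  merged <- merge_replicates(raw)
  deep <- filter_depth(merged, config$min_depth)
  snps <- call_biallelic(deep, maf = config$maf)
  write_snp_table(snps, out("snps.tsv"), hdr)
  write_sync(deep, out("counts.sync"))
  msg("snp_calling: %d positions -> %d depth-passing -> %d biallelic SNPs",
      nrow(raw$sites), nrow(deep$sites), nrow(snps$sites))
  stage("snp_calling", c(config$counts, config$design), nrow(raw$sites),
        nrow(snps$sites),
        list(min_depth = config$min_depth, maf = config$maf),
        proc.time()[["elapsed"]] - t0)

  ## stage 2: genome scan ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (nrow(snps$sites)) {
    scan <- genome_scan(snps, design, config$q_high, config$q_sugg)
    freqs <- allele_freq_matrix(snps)
    pca <- population_pca(freqs)
    pca_df <- data.frame(pool = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE,
                         stringsAsFactors = FALSE)
    pca_df$group <- design$group[match(pca_df$pool, design$pool)]
    explained <- data.frame(component = seq_along(pca$explained),
                            explained = pca$explained)
  } else {
    scan <- genome_scan(snps, design)  # empty frame
    pca_df <- data.frame(pool = character(), group = character())
    explained <- data.frame(component = integer(), explained = numeric())
  }
  write_tsv_commented(scan, out("scan.tsv"), hdr)
  write_tsv_commented(pca_df, out("pca.tsv"), hdr)
  write_tsv_commented(explained, out("pca_explained.tsv"), hdr)
  msg("genome_scan: %d SNPs, %d suggestive, %d highly suggestive",
      nrow(scan), sum(scan$class == "suggestive"),
      sum(scan$class == "highly_suggestive"))
  stage("genome_scan", out("snps.tsv"), nrow(snps$sites), nrow(scan),
        list(q_high = config$q_high, q_sugg = config$q_sugg),
        proc.time()[["elapsed"]] - t0)

  ## stage 3: candidate annotation ------------------------------------------
  candidates <- character()
  catalog <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$annotation)) {
    catalog <- read_features(config$annotation)
    cand <- collate_candidates(scan, catalog, window = config$window)
    candidates <- cand$genes
    cand_df <- data.frame(
      feature_id = c(cand$genes, cand$cpg_islands),
      type = rep(c("gene", "CpG_island"),
                 c(length(cand$genes), length(cand$cpg_islands))),
      stringsAsFactors = FALSE)
    write_tsv_commented(cand_df, out("candidates.tsv"), hdr)
    write_tsv_commented(cand$provenance, out("candidate_provenance.tsv"),
                        hdr)
    if (!is.null(config$orthologs)) {
      candidates <- map_orthologs(candidates,
                                  read_orthologs(config$orthologs))
    }
    if (!is.null(config$gene2term)) {
      g2t <- read_gene2term(config$gene2term)
      background <- if (!is.null(config$orthologs)) {
        sort(unique(read_orthologs(config$orthologs)$ortholog))
      } else {
        sort(unique(catalog$id[catalog$type == "gene"]))
      }
      enr <- term_enrichment(intersect(candidates, background), g2t,
                             background)
      write_tsv_commented(enr, out("term_enrichment.tsv"), hdr)
    }
    msg("candidate_annotation: %d genes, %d CpG islands",
        length(cand$genes), length(cand$cpg_islands))
    stage("candidate_annotation", config$annotation, nrow(scan),
          length(cand$genes) + length(cand$cpg_islands),
          list(window = config$window), proc.time()[["elapsed"]] - t0)
  }

  ## stage 4: network enrichment --------------------------------------------
  if (!is.null(config$interactome)) {
    t0 <- proc.time()[["elapsed"]]
    universe <- if (!is.null(catalog)) {
      sort(unique(catalog$id[catalog$type == "gene"]))
    } else {
      NULL
    }
    net <- read_interactome(config$interactome, genes = universe)
    net <- filter_by_probability(net, config$prob_threshold)
    sub <- direct_interaction_subgraph(net, candidates)
    curve <- degree_sweep(sub, k_max = config$k_max)
    null <- permutation_null(net, n = max(length(candidates), 1L),
                             k_max = config$k_max, n_perm = config$n_perm,
                             seed = config$seed)
    sel <- select_consensus_network(sub, curve, null)
    final <- sel$network
    topo <- topology_indices(final)
    write_tsv_commented(curve, out("enrichment_curve.tsv"), hdr)
    write_tsv_commented(null$summary, out("permutation_summary.tsv"), hdr)
    write_tsv_commented(topo, out("topology.tsv"), hdr)
    write_sif(final, out("network.sif"))
    write_graphml(final, out("network.graphml"))
    msg("network_enrichment: selected k=%d, %d genes in final component",
        sel$k, length(network_genes(final)))
    stage("network_enrichment", config$interactome, nrow(net$edges),
          length(network_genes(final)),
          list(prob_threshold = config$prob_threshold,
               k_max = config$k_max, n_perm = config$n_perm,
               selected_k = sel$k),
          proc.time()[["elapsed"]] - t0)
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
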