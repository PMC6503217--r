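# End-to-end orchestration: simulate (or read) -> filter -> markers/distance
# -> ANI -> continuum/clusters -> pangenome/profiles -> replicon families ->
# Ks contrasts, with every stage's outputs persisted under one run directory
# and a machine-readable report.

.required_blocks <- c("input", "filter", "markers", "ani", "continuum",
                      "pangenome", "replicon_families", "ks")

#' Run the full analysis pipeline from one configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with one
#' block per stage: `input` (either `simulate:` parameters for
#' [sim_config()] or `fasta:`/`gene_table:` paths), `filter`, `markers`,
#' `ani`, `continuum`, `pangenome`, `replicon_families` and `ks`. Missing
#' blocks are an error naming the block; empty blocks take the stage
#' defaults. All stage outputs are written as TSV/Newick under `outdir`, and
#' the returned report carries per-stage counts, thresholds, a file manifest
#' with md5 checksums, and the seed registry: identical configs reproduce
#' identical checksums.
#' @param config path to a YAML config, or a named list
#' @param outdir run directory (created)
#' @param seed optional seed overriding the config's
#' @return a `pipeline_report` list
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing <- setdiff(.required_blocks, names(config))
  if (length(missing) > 0) {
    stop(sprintf("config is missing block(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), thresholds = list(), seeds = list())
  stage_dir <- function(name) {
    p <- file.path(outdir, name)
    dir.create(p, showWarnings = FALSE)
    p
  }

  # stage 1: input
  inp <- config$input
  if (!is.null(inp$simulate)) {
    args <- inp$simulate
    if (!is.null(seed)) args$seed <- seed
    cfg <- do.call(sim_config, args)
    sim <- evolve_collection(cfg)
    genomes <- sim$genomes
    truth <- sim$truth
    d1 <- stage_dir("01_input")
    write_genome_collection(genomes, d1)
    ape::write.tree(truth$tree, file.path(d1, "true_tree.nwk"))
    write_matrix(truth$true_pairwise_distance,
                 file.path(d1, "true_distances.tsv"))
    report$seeds$simulate <- cfg$seed
  } else {
    genomes <- read_genome_collection(inp$fasta, inp$gene_table)
    truth <- NULL
    d1 <- stage_dir("01_input")
  }
  report$stages$input <- list(n_genomes = length(genomes),
                              n_genes = nrow(gene_table(genomes)))

  # stage 2: filter
  fargs <- config$filter
  fr <- do.call(filter_collection, c(list(genomes), fargs))
  genomes <- genomes[genome_ids(genomes) %in% fr$kept]
  d2 <- stage_dir("02_filter")
  write.table(fr$excluded, file.path(d2, "excluded.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(fr$kept, file.path(d2, "kept.txt"))
  report$stages$filter <- list(kept = length(fr$kept),
                               excluded = nrow(fr$excluded))
  report$thresholds$filter <- list(min_draft_length = fr$min_draft_length)

  # stage 3: markers, congruence filter, distances, tree
  margs <- config$markers
  markers <- do.call(extract_markers, c(list(genomes), margs[
    intersect(names(margs), c("role_tag", "min_identity", "min_cov_largest"))]))
  markers <- lapply(markers, trim_columns)
  fargs2 <- margs[intersect(names(margs), c("max_rf_quantile", "min_len"))]
  mf <- do.call(filter_markers, c(list(markers), fargs2))
  gdist <- pairwise_distance(mf$supermatrix)
  tree <- nj_tree(gdist)
  d3 <- stage_dir("03_markers")
  write_matrix(gdist, file.path(d3, "genetic_distance.tsv"), saturated_ok = TRUE)
  ape::write.tree(tree, file.path(d3, "marker_nj_tree.nwk"))
  writeLines(mf$dropped, file.path(d3, "dropped_markers.txt"))
  report$stages$markers <- list(
    extracted = length(markers), retained = length(mf$retained),
    dropped = length(mf$dropped),
    supermatrix_columns = nchar(mf$supermatrix$seqs[[1]]))

  # stage 4: ANI
  aargs <- config$ani
  am <- do.call(ani_matrix, c(list(genomes), aargs))
  d4 <- stage_dir("04_ani")
  write_matrix(am$ani, file.path(d4, "ani.tsv"))
  write_matrix(am$gcov, file.path(d4, "gcov.tsv"))
  write.table(am$pairs, file.path(d4, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  report$stages$ani <- list(n_pairs = nrow(am$pairs))

  # stage 5: continuum + clusters + histogram
  cargs <- config$continuum
  pt <- pair_table(am$ani, am$gcov, gdist)
  sp <- spearman_cor(pt$ani_pct, pt$genetic_distance)
  cl <- call_clusters(am$ani, am$gcov,
                      ani_min = cargs$ani_min %||% 96,
                      gcov_min = cargs$gcov_min %||% 90)
  hist <- ani_histogram(pt$ani_pct)
  prof <- if (nrow(pt) >= 10)
    continuum_profile(pt, window = cargs$window %||% 0.005) else NULL
  d5 <- stage_dir("05_continuum")
  write.table(pt, file.path(d5, "pair_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(hist, file.path(d5, "ani_histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(prof)) {
    write.table(prof, file.path(d5, "continuum_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  memb <- data.frame(genome_id = names(cl$membership),
                     cluster = cl$membership, stringsAsFactors = FALSE)
  write.table(memb, file.path(d5, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  report$stages$continuum <- list(spearman_rho = sp$rho, p_value = sp$p_value,
                                  n_clusters = length(cl$clusters))
  report$thresholds$clusters <- list(ani_min = cl$ani_min,
                                     gcov_min = cl$gcov_min)

  # stage 6: pangenome
  pargs <- config$pangenome
  gt <- gene_table(genomes)
  prot <- split(setNames(gt$protein, gt$gene_id), gt$genome_id)
  graph <- bdbh(prot)
  bfams <- bdbh_families(graph)
  sim_g <- .collection_similarity_graph(gt)
  mfams <- mcl_cluster(sim_g, inflation = pargs$inflation %||% 1.5)
  fams <- family_table_from_clusters(mfams, graph$gene_genomes)
  cc <- consensus_core(bfams, mfams, graph$gene_genomes, genome_ids(genomes))
  pa <- presence_absence(fams, genome_ids(genomes))
  curves <- pangenome_curves(pa, n_perm = pargs$n_perm %||% 20,
                             seed = pargs$seed %||% 1L)
  ordering <- order_profiles(pa)
  d6 <- stage_dir("06_pangenome")
  write.table(fams, file.path(d6, "families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(family_id = rownames(pa), as.data.frame(pa)),
              file.path(d6, "presence_absence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(curves$medians, file.path(d6, "rarefaction.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(ordering$tree, file.path(d6, "profile_upgma.nwk"))
  report$stages$pangenome <- list(
    n_families = length(mfams), consensus_core = length(unique(cc$family_id)),
    heaps_gamma = curves$fits$gamma)

  # stage 7: replicon families
  rargs <- config$replicon_families
  repp <- extract_rep_proteins(genomes)
  rf <- family_clusters(repp, genomes, inflation = rargs$inflation %||% 1.5)
  d7 <- stage_dir("07_replicon_families")
  write.table(rf$assignments, file.path(d7, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (fam in names(rf$trees)) {
    if (!is.null(rf$trees[[fam]])) {
      ape::write.tree(rf$trees[[fam]], file.path(d7, paste0(fam, ".nwk")))
    }
  }
  report$stages$replicon_families <- list(
    n_rep_proteins = nrow(repp),
    n_repC_clusters = length(rf$families[["repC"]]),
    n_repB_clusters = length(rf$families[["repB"]]))

  # stage 8: Ks contrasts over all pairs with psyms
  kargs <- config$ks
  ids <- genome_ids(genomes)
  contrasts <- list()
  pairs_idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs_idx))) {
    i <- pairs_idx[r, 1]; j <- pairs_idx[r, 2]
    cc8 <- tryCatch(compartment_contrast(
      genomes[[i]], genomes[[j]],
      transfer_ratio_max = kargs$transfer_ratio_max %||% 0.2,
      min_chr_ks = kargs$min_chr_ks %||% 0.1,
      min_pairs = kargs$min_pairs %||% 10),
      error = function(e) NULL)
    if (!is.null(cc8)) {
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        genome_a = cc8$genome_a, genome_b = cc8$genome_b,
        median_ks_chr = cc8$median_ks_chr, median_ks_psym = cc8$median_ks_psym,
        ratio = cc8$ratio, transfer_flag = cc8$transfer_flag,
        reverse_flag = cc8$reverse_flag, stringsAsFactors = FALSE)
    }
  }
  ks_tab <- if (length(contrasts) > 0) do.call(rbind, contrasts) else NULL
  d8 <- stage_dir("08_ks")
  if (!is.null(ks_tab)) {
    write.table(ks_tab, file.path(d8, "compartment_contrasts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report$stages$ks <- list(
    n_pairs = if (is.null(ks_tab)) 0L else nrow(ks_tab),
    n_flagged = if (is.null(ks_tab)) 0L else sum(ks_tab$transfer_flag %in% TRUE))

  # manifest
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  report$manifest <- data.frame(
    file = sub(paste0("^", outdir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  jsonlite::write_json(report[c("stages", "thresholds", "seeds")],
                       file.path(outdir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# similarity graph over all genes of a collection (for collection-level MCL)
.collection_similarity_graph <- function(gt, min_identity = 50,
                                         min_coverage = 50, min_score = 50) {
  prot <- setNames(gt$protein, gt$gene_id)
  protein_similarity_graph(prot, min_identity, min_coverage, min_score)
}
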