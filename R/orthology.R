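# Protein-level homology: local alignment, bidirectional best hits (BDBH),
# Markov clustering (MCL), and the consensus core (families on which BDBH and
# MCL agree exactly, one member per genome).

#' Local protein alignment (Smith-Waterman, BLOSUM62, affine gaps)
#'
#' Identity is computed over aligned columns (gap columns included, as in
#' BLAST); coverage of each sequence is its aligned span over its length. A
#' gap of length L costs `gap_open + L * gap_extend`.
#' @param a,b protein strings (standard 20-letter alphabet plus X)
#' @param gap_open,gap_extend affine gap penalties
#' @return a `protein_hit`: list(score, pct_identity, query_cov, target_cov,
#'   matches, align_len, qstart, qend, tstart, tend, qpos, tpos) with
#'   coordinates 0-based and `qpos`/`tpos` the aligned residue index pairs
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty protein sequence")
  r <- .cpp_sw_align(.encode_protein(a), .encode_protein(b), .blosum62_26(),
                     as.integer(gap_open), as.integer(gap_extend))
  class(r) <- "protein_hit"
  r
}

# batch score/identity/coverage matrices between two protein vectors;
# `prefilter` skips the DP for long pairs sharing no 6-mer (such pairs cannot
# plausibly pass the 50/50 gates) - exact behaviour for short sequences
.sw_matrices <- function(qs, ts, gap_open = 11, gap_extend = 1,
                         prefilter = TRUE, prefilter_min_len = 100L) {
  enc_q <- lapply(qs, .encode_protein)
  enc_t <- lapply(ts, .encode_protein)
  m <- .cpp_sw_batch(enc_q, enc_t, .blosum62_26(),
                     as.integer(gap_open), as.integer(gap_extend),
                     isTRUE(prefilter), as.integer(prefilter_min_len))
  for (nm in names(m)) dimnames(m[[nm]]) <- list(names(qs), names(ts))
  m
}

# best hit per query given the threshold gates; ties broken by higher
# identity, then lexicographic target id
.best_hits <- function(m, qs_len, ts_len, min_identity, min_coverage,
                       min_score, cov_of_largest = FALSE) {
  score <- m$score; ident <- m$pct_identity
  qcov <- m$query_cov; tcov <- m$target_cov
  if (cov_of_largest) {
    # aligned span over the larger of the two lengths
    qspan <- sweep(qcov / 100, 1, qs_len, `*`)
    covL <- 100 * qspan / outer(qs_len, ts_len, pmax)
    pass <- ident >= min_identity & covL >= min_coverage & score >= min_score
  } else {
    pass <- ident >= min_identity & qcov >= min_coverage &
      tcov >= min_coverage & score >= min_score
  }
  out <- rep(NA_character_, nrow(score))
  names(out) <- rownames(score)
  tnames <- colnames(score)
  ord_t <- order(tnames)
  for (i in seq_len(nrow(score))) {
    ok <- which(pass[i, ])
    if (length(ok) == 0) next
    s <- score[i, ok]
    best <- ok[s == max(s)]
    if (length(best) > 1) {
      id2 <- ident[i, best]
      best <- best[id2 == max(id2)]
      if (length(best) > 1) best <- best[order(tnames[best])][1]
    }
    out[i] <- tnames[best]
  }
  out
}

#' Bidirectional best hits across a set of proteomes
#'
#' For every ordered genome pair, each protein's best hit above the gates
#' (identity, coverage of each sequence, raw score floor standing in for an
#' e-value cutoff) is found; an edge is kept iff the best hits are reciprocal.
#' @param proteomes named list (genome id -> named character vector of
#'   proteins, names = gene ids, unique across the collection)
#' @param min_identity percent identity gate
#' @param min_coverage percent coverage gate (of each sequence, or of the
#'   largest when `cov_of_largest`)
#' @param min_score raw-score floor (BLOSUM62 half-bits); the default of 50
#'   was calibrated on shuffled-sequence nulls so random hits at typical
#'   bacterial protein lengths pass with probability < 1e-6
#' @param cov_of_largest use aligned span over the larger protein (the
#'   60/60-of-largest marker-extraction convention)
#' @return a `bdbh_graph`: list with `edges` (data.frame gene_a, gene_b,
#'   genome_a, genome_b) and `gene_genomes` (named vector gene -> genome)
#' @export
bdbh <- function(proteomes, min_identity = 50, min_coverage = 50,
                 min_score = 50, cov_of_largest = FALSE) {
  if (length(proteomes) < 2) stop("need at least 2 proteomes")
  gids <- names(proteomes)
  gene_genomes <- unlist(lapply(gids, function(g)
    setNames(rep(g, length(proteomes[[g]])), names(proteomes[[g]]))))
  edges <- list()
  for (i in seq_along(gids)) {
    for (j in seq_along(gids)) {
      if (j <= i) next
      a <- proteomes[[i]]; b <- proteomes[[j]]
      if (length(a) == 0 || length(b) == 0) next
      m <- .sw_matrices(a, b)
      mt <- list(score = t(m$score), pct_identity = t(m$pct_identity),
                 query_cov = t(m$target_cov), target_cov = t(m$query_cov))
      ba <- .best_hits(m, nchar(a), nchar(b), min_identity, min_coverage,
                       min_score, cov_of_largest)
      bb <- .best_hits(mt, nchar(b), nchar(a), min_identity, min_coverage,
                       min_score, cov_of_largest)
      for (qa in names(ba)) {
        tb <- ba[[qa]]
        if (!is.na(tb) && !is.na(bb[[tb]]) && bb[[tb]] == qa) {
          edges[[length(edges) + 1L]] <- data.frame(
            gene_a = qa, gene_b = tb, genome_a = gids[i], genome_b = gids[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(gene_a = character(), gene_b = character(),
               genome_a = character(), genome_b = character(),
               stringsAsFactors = FALSE)
  rc_log("bdbh: %d genomes, %d reciprocal edges (id>=%g, cov>=%g, score>=%g)",
         length(gids), nrow(edges), min_identity, min_coverage, min_score)
  structure(list(edges = edges, gene_genomes = gene_genomes),
            class = "bdbh_graph")
}

#' Connected components of a BDBH graph as gene families
#' @param graph a `bdbh_graph`
#' @return list of character vectors (gene ids per family), singletons
#'   included, ordered by first gene id
#' @export
bdbh_families <- function(graph) {
  genes <- names(graph$gene_genomes)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  fams <- split(names(comp), comp)
  fams <- lapply(fams, sort)
  fams[order(vapply(fams, `[`, character(1), 1))]
}

#' Markov clustering of a weighted similarity graph
#'
#' Column-stochastic matrix iterated by expansion (matrix squaring) and
#' inflation (elementwise power, then renormalisation) with pruning, until the
#' maximum entry change falls below 1e-9 or `max_iter` is reached. Self loops
#' equal to each node's maximum incident weight (minimum 1) are added, the
#' standard regularisation that damps oscillation and guarantees attractors.
#' Clusters are the connected components of the converged
#' non-zero structure; the result is invariant to node order.
#' @param graph symmetric non-negative similarity matrix with dimnames, or a
#'   data.frame (from, to, weight)
#' @param inflation inflation exponent (GET_HOMOLOGS-style default 1.5)
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with attribute `converged = FALSE` and a warning
#' @param prune_threshold entries below this are zeroed each iteration
#' @return list of character vectors (node labels per cluster), ordered by
#'   first label; attribute `converged`
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 200,
                        prune_threshold = 1e-5) {
  if (is.data.frame(graph)) {
    nodes <- sort(unique(c(graph[[1]], graph[[2]])))
    m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(graph))) {
      w <- if (ncol(graph) >= 3) graph[[3]][r] else 1
      m[graph[[1]][r], graph[[2]][r]] <- w
      m[graph[[2]][r], graph[[1]][r]] <- w
    }
    graph <- m
  }
  if (any(graph < 0)) stop("weights must be non-negative")
  nodes <- rownames(graph)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(graph)))
  n <- nrow(graph)
  if (n == 1) {
    out <- list(nodes)
    attr(out, "converged") <- TRUE
    return(out)
  }
  # canonical node order for determinism, restored at output via labels
  ord <- order(nodes)
  M <- Matrix::Matrix(graph[ord, ord], sparse = TRUE)
  Matrix::diag(M) <- 0
  loops <- pmax(apply(graph[ord, ord], 1, max), 1)
  Matrix::diag(M) <- loops
  colnorm <- function(m) {
    cs <- Matrix::colSums(m)
    cs[cs == 0] <- 1
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- colnorm(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2@x <- M2@x ^ inflation            # inflation
    M2 <- colnorm(M2)
    M2@x[M2@x < prune_threshold] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- colnorm(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-9) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge; returning current clustering")
  adj <- (M + Matrix::t(M)) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lab <- sort(nodes)
  fams <- split(lab, comp)
  fams <- lapply(fams, sort)
  fams <- fams[order(vapply(fams, `[`, character(1), 1))]
  names(fams) <- NULL
  attr(fams, "converged") <- converged
  fams
}

#' Similarity graph of proteins for MCL (alignment-score weighted)
#'
#' All-vs-all local alignment; edges where both the identity and the coverage
#' of each sequence pass the gates, weighted by alignment score.
#' @param proteins named character vector
#' @param min_identity,min_coverage,min_score gates as in [bdbh()]
#' @return symmetric numeric matrix
#' @export
protein_similarity_graph <- function(proteins, min_identity = 50,
                                     min_coverage = 50, min_score = 50) {
  m <- .sw_matrices(proteins, proteins)
  pass <- m$pct_identity >= min_identity & m$query_cov >= min_coverage &
    m$target_cov >= min_coverage & m$score >= min_score
  w <- m$score * pass
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

#' Consensus core families (BDBH and MCL agree, one member per genome)
#'
#' A family is consensus-core iff some BDBH family and some MCL cluster
#' contain the identical gene set and that set has exactly one member per
#' genome in the collection.
#' @param bdbh_clusters,mcl_clusters lists of gene-id vectors over the same
#'   gene universe
#' @param gene_genomes named vector gene id -> genome id
#' @param genomes character vector of all genome ids in the collection
#' @return a `family_table` data.frame (family_id, gene_id, genome_id) with
#'   attribute `flags` (per-family data.frame: family_id, core, single_copy)
#' @export
consensus_core <- function(bdbh_clusters, mcl_clusters, gene_genomes,
                           genomes) {
  key <- function(v) paste(sort(v), collapse = "\r")
  mcl_keys <- vapply(mcl_clusters, key, character(1))
  rows <- list(); flags <- list()
  k <- 0L
  for (cl in bdbh_clusters) {
    if (!key(cl) %in% mcl_keys) next
    gg <- gene_genomes[cl]
    if (length(cl) != length(genomes) || !setequal(gg, genomes) ||
        anyDuplicated(gg) > 0) next
    k <- k + 1L
    fid <- sprintf("CC%04d", k)
    rows[[k]] <- data.frame(family_id = fid, gene_id = sort(cl),
                            genome_id = unname(gene_genomes[sort(cl)]),
                            stringsAsFactors = FALSE)
    flags[[k]] <- data.frame(family_id = fid, core = TRUE, single_copy = TRUE,
                             stringsAsFactors = FALSE)
  }
  out <- if (k > 0) do.call(rbind, rows) else
    data.frame(family_id = character(), gene_id = character(),
               genome_id = character(), stringsAsFactors = FALSE)
  attr(out, "flags") <- if (k > 0) do.call(rbind, flags) else
    data.frame(family_id = character(), core = logical(),
               single_copy = logical(), stringsAsFactors = FALSE)
  rc_log("consensus_core: %d BDBH families, %d MCL clusters, %d consensus-core",
         length(bdbh_clusters), length(mcl_clusters), k)
  class(out) <- c("family_table", class(out))
  out
}

#' Gene families from a clustering, as a long family table
#' @param clusters list of gene-id vectors
#' @param gene_genomes named vector gene id -> genome id
#' @return `family_table` data.frame (family_id, gene_id, genome_id)
#' @export
family_table_from_clusters <- function(clusters, gene_genomes) {
  rows <- lapply(seq_along(clusters), function(i) {
    gl <- sort(clusters[[i]])
    data.frame(family_id = sprintf("F%05d", i), gene_id = gl,
               genome_id = unname(gene_genomes[gl]), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(family_id = character(), gene_id = character(),
               genome_id = character(), stringsAsFactors = FALSE)
  class(out) <- c("family_table", class(out))
  out
}
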