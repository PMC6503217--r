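# Pangenome profiling: presence/absence matrices, rarefaction curves with
# Heaps'-law and exponential-decay fits, symbiotic-reference mapping, and
# Bray-Curtis profile ordering.

#' Presence/absence (or copy-count) matrix from a family table
#' @param families a `family_table` (family_id, gene_id, genome_id)
#' @param genomes character vector of genome ids (matrix columns)
#' @param counts return copy counts instead of 0/1
#' @return integer matrix, families x genomes
#' @export
presence_absence <- function(families, genomes, counts = FALSE) {
  fams <- sort(unique(families$family_id))
  m <- matrix(0L, length(fams), length(genomes),
              dimnames = list(fams, genomes))
  if (nrow(families) > 0) {
    tab <- table(families$family_id, families$genome_id)
    m[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  if (!counts) m <- (m > 0L) + 0L
  m
}

#' Pangenome rarefaction curves with Heaps' law and core-decay fits
#'
#' For each of `n_perm` random genome orderings, core(n) = families present in
#' all of the first n genomes and pan(n) = families present in any of them.
#' Medians across permutations are fitted: pan to Heaps' law K * n^gamma
#' (gamma > 0 indicates an open pangenome), core to A * exp(-n / tau) + C.
#' @param pa presence/absence matrix (families x genomes)
#' @param n_perm number of genome-order permutations
#' @param seed RNG seed for the permutations
#' @return list with `curves` (per-permutation core/pan matrices), `medians`
#'   (data.frame n, core, pan) and `fits` (K, gamma, A, tau, C)
#' @export
pangenome_curves <- function(pa, n_perm = 20, seed = 1L) {
  ng <- ncol(pa)
  if (ng < 2) stop("need at least 2 genomes")
  pa <- pa > 0
  core_m <- pan_m <- matrix(NA_real_, n_perm, ng)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(ng)
      seen_all <- rep(TRUE, nrow(pa))
      seen_any <- rep(FALSE, nrow(pa))
      for (n in seq_len(ng)) {
        col <- pa[, ord[n]]
        seen_all <- seen_all & col
        seen_any <- seen_any | col
        core_m[p, n] <- sum(seen_all)
        pan_m[p, n] <- sum(seen_any)
      }
    }
  })
  med <- data.frame(n = seq_len(ng),
                    core = apply(core_m, 2, median),
                    pan = apply(pan_m, 2, median))
  fits <- .fit_curves(med)
  rc_log("pangenome_curves: %d families, %d genomes, %d permutations, gamma=%.3f",
         nrow(pa), ng, n_perm, fits$gamma)
  list(curves = list(core = core_m, pan = pan_m), medians = med, fits = fits)
}

.fit_curves <- function(med) {
  # Heaps: least squares on logs as the starting point, refined by nls
  ok <- med$pan > 0
  lfit <- stats::lm(log(pan) ~ log(n), data = med[ok, ])
  K0 <- exp(unname(coef(lfit)[1])); g0 <- unname(coef(lfit)[2])
  heaps <- tryCatch(
    minpack.lm::nlsLM(pan ~ K * n^gamma, data = med,
                      start = list(K = K0, gamma = g0)),
    error = function(e) NULL)
  if (!is.null(heaps)) {
    K <- coef(heaps)[["K"]]; gamma <- coef(heaps)[["gamma"]]
  } else {
    K <- unname(K0); gamma <- unname(g0)
  }
  C0 <- min(med$core); A0 <- max(med$core) - C0
  decay <- tryCatch(
    minpack.lm::nlsLM(core ~ A * exp(-n / tau) + C, data = med,
                      start = list(A = max(A0, 1), tau = max(med$n) / 3,
                                   C = C0)),
    error = function(e) NULL)
  if (!is.null(decay)) {
    A <- coef(decay)[["A"]]; tau <- coef(decay)[["tau"]]; C <- coef(decay)[["C"]]
  } else {
    A <- A0; tau <- NA_real_; C <- C0
  }
  list(K = K, gamma = gamma, A = A, tau = tau, C = C)
}

#' Map symbiotic reference proteins onto pangenome families
#'
#' References are first made non-redundant by MCL over their similarity graph
#' at the usual 50/50 gates (one representative per cluster, lexicographically
#' first id); each representative is then mapped to genes by reciprocal best
#' hit, and the hit gene's family defines the reference's presence profile
#' across genomes.
#' @param families a `family_table` over the collection's genes
#' @param gene_proteins named character vector gene id -> protein
#' @param gene_genomes named character vector gene id -> genome id
#' @param symbiotic_refs named character vector of reference proteins
#' @param genomes character vector of genome ids
#' @param min_identity,min_coverage,min_score gates as in [bdbh()]
#' @return binary matrix, non-redundant references x genomes; attribute
#'   `representatives` lists the reference clusters
#' @export
map_symbiotic <- function(families, gene_proteins, gene_genomes,
                          symbiotic_refs, genomes, min_identity = 50,
                          min_coverage = 50, min_score = 50) {
  if (length(symbiotic_refs) == 0) stop("empty reference set")
  if (length(symbiotic_refs) > 1) {
    g <- protein_similarity_graph(symbiotic_refs, min_identity, min_coverage,
                                  min_score)
    cl <- mcl_cluster(g)
  } else {
    cl <- list(names(symbiotic_refs))
  }
  reps <- vapply(cl, function(x) sort(x)[1], character(1))
  refp <- symbiotic_refs[reps]
  fam_of_gene <- setNames(families$family_id, families$gene_id)
  m_rg <- .sw_matrices(refp, gene_proteins)
  m_gr <- list(score = t(m_rg$score), pct_identity = t(m_rg$pct_identity),
               query_cov = t(m_rg$target_cov), target_cov = t(m_rg$query_cov))
  best_r <- .best_hits(m_rg, nchar(refp), nchar(gene_proteins),
                       min_identity, min_coverage, min_score)
  best_g <- .best_hits(m_gr, nchar(gene_proteins), nchar(refp),
                       min_identity, min_coverage, min_score)
  profile <- matrix(0L, length(reps), length(genomes),
                    dimnames = list(reps, genomes))
  for (r in reps) {
    gbest <- best_r[[r]]
    if (is.na(gbest)) next
    if (is.na(best_g[[gbest]]) || best_g[[gbest]] != r) next
    fam <- fam_of_gene[[gbest]]
    if (is.na(fam)) next
    present <- unique(families$genome_id[families$family_id == fam])
    profile[r, genomes %in% present] <- 1L
  }
  rc_log("map_symbiotic: %d refs -> %d non-redundant, %d mapped",
         length(symbiotic_refs), length(reps), sum(rowSums(profile) > 0))
  attr(profile, "representatives") <- cl
  profile
}

#' Bray-Curtis dissimilarity between two non-negative profiles
#' @param x,y equal-length non-negative numeric vectors
#' @return dissimilarity in [0, 1]
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (any(x < 0) || any(y < 0)) stop("profiles must be non-negative")
  s <- sum(x + y)
  if (s == 0) stop("Bray-Curtis undefined for two all-zero profiles")
  sum(abs(x - y)) / s
}

#' Order genome profiles by UPGMA on Bray-Curtis dissimilarity
#'
#' @param pa presence/absence matrix (families x genomes, >= 2 columns)
#' @return list with `order` (genome ids, dendrogram leaf order), `hclust`
#'   (the UPGMA tree) and `tree` (as an ape phylo)
#' @export
order_profiles <- function(pa) {
  if (ncol(pa) < 2) stop("need at least 2 columns")
  pa <- pa[, order(colnames(pa)), drop = FALSE]  # deterministic tie-breaking
  n <- ncol(pa)
  d <- matrix(0, n, n, dimnames = list(colnames(pa), colnames(pa)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(pa[, i], pa[, j])
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  list(order = colnames(pa)[hc$order], hclust = hc,
       tree = ape::as.phylo(hc), dissimilarity = d)
}
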