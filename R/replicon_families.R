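# Plasmid/chromid family assignment from Rep-protein clustering, and
# whole-replicon conservation from registered matches.

#' Extract Rep proteins (replication/partition machinery) per replicon
#' @param genomes list of `genome_record`s
#' @param tags Rep role tags to collect
#' @return data.frame (gene_id, genome_id, replicon_id, kind, tag, protein);
#'   replicons without Rep genes simply do not appear (they are reported
#'   unassigned by [family_clusters()])
#' @export
extract_rep_proteins <- function(genomes, tags = c("repC", "repB")) {
  gt <- gene_table(genomes)
  rows <- list()
  for (tag in tags) {
    sel <- gt[vapply(strsplit(gt$role_tags, ","), function(x) tag %in% x,
                     logical(1)), , drop = FALSE]
    if (nrow(sel) > 0) {
      rows[[tag]] <- data.frame(gene_id = sel$gene_id,
                                genome_id = sel$genome_id,
                                replicon_id = sel$replicon_id,
                                kind = sel$kind, tag = tag,
                                protein = sel$protein, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(), genome_id = character(),
               replicon_id = character(), kind = character(), tag = character(),
               protein = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rc_log("extract_rep_proteins: %d Rep proteins (%s)", nrow(out),
         paste(tags, collapse = ", "))
  out
}

#' Cluster Rep proteins into replicon families
#'
#' Builds the score-weighted similarity graph of each Rep protein set at the
#' 50/50 gates, applies MCL, and assigns every replicon the cluster of its Rep
#' protein (primary family by repC; repB recorded alongside; replicons with
#' several Rep paralogs get the family of their lexicographically first gene
#' as primary and the rest as secondary). A per-family NJ tree (Poisson
#' protein distance) is computed for families with >= 3 members.
#' @param rep_proteins output of [extract_rep_proteins()]
#' @param genomes list of `genome_record`s (to report unassigned replicons)
#' @param inflation MCL inflation
#' @param min_identity,min_coverage,min_score similarity gates
#' @return list with `assignments` (data.frame replicon_id, genome_id, kind,
#'   repC_family, repB_family, secondary), `families` (per-tag list of member
#'   tables), `trees` (per-family phylo or NULL), `within_identity` (per-family
#'   mean pairwise percent identity)
#' @export
family_clusters <- function(rep_proteins, genomes = NULL, inflation = 1.5,
                            min_identity = 50, min_coverage = 50,
                            min_score = 50) {
  if (nrow(rep_proteins) == 0) stop("no Rep proteins supplied")
  out_fam <- list(); trees <- list(); within <- list()
  gene_cluster <- list()
  for (tag in sort(unique(rep_proteins$tag))) {
    sel <- rep_proteins[rep_proteins$tag == tag, , drop = FALSE]
    prot <- setNames(sel$protein, sel$gene_id)
    if (length(prot) > 1) {
      g <- protein_similarity_graph(prot, min_identity, min_coverage, min_score)
      cl <- mcl_cluster(g, inflation = inflation)
    } else cl <- list(names(prot))
    names(cl) <- sprintf("%s-MCL%02d", tag, seq_along(cl))
    out_fam[[tag]] <- cl
    for (fam in names(cl)) {
      members <- cl[[fam]]
      for (gid in members) gene_cluster[[gid]] <- fam
      if (length(members) >= 3) {
        m <- .sw_matrices(prot[members], prot[members])
        p <- 1 - m$pct_identity / 100
        d <- -log(pmax(1 - p, 0.02))
        diag(d) <- 0
        d <- (d + t(d)) / 2
        trees[[fam]] <- nj_tree(d)
      } else trees[[fam]] <- NULL
      if (length(members) >= 2) {
        m <- .sw_matrices(prot[members], prot[members])
        ut <- upper.tri(m$pct_identity)
        within[[fam]] <- mean(m$pct_identity[ut])
      } else within[[fam]] <- NA_real_
    }
  }
  # per-replicon assignment
  reps <- unique(rep_proteins[, c("replicon_id", "genome_id", "kind")])
  assign_tag <- function(rid, tag) {
    sel <- rep_proteins[rep_proteins$replicon_id == rid &
                        rep_proteins$tag == tag, , drop = FALSE]
    if (nrow(sel) == 0) return(list(primary = NA_character_, secondary = character(0)))
    gl <- sort(sel$gene_id)
    fams <- vapply(gl, function(g) gene_cluster[[g]], character(1))
    list(primary = fams[1], secondary = unique(fams[-1]))
  }
  assignments <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    rid <- reps$replicon_id[i]
    ac <- assign_tag(rid, "repC"); ab <- assign_tag(rid, "repB")
    data.frame(replicon_id = rid, genome_id = reps$genome_id[i],
               kind = reps$kind[i], repC_family = ac$primary,
               repB_family = ab$primary,
               secondary = paste(c(ac$secondary, ab$secondary), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(genomes)) {
    for (g in genomes) for (r in g$replicons) {
      if (!r$replicon_id %in% assignments$replicon_id) {
        assignments <- rbind(assignments, data.frame(
          replicon_id = r$replicon_id, genome_id = g$genome_id, kind = r$kind,
          repC_family = NA_character_, repB_family = NA_character_,
          secondary = "", stringsAsFactors = FALSE))
      }
    }
  }
  assignments <- assignments[order(assignments$replicon_id), , drop = FALSE]
  rownames(assignments) <- NULL
  rc_log("family_clusters: %d repC clusters, %d repB clusters",
         length(out_fam[["repC"]]), length(out_fam[["repB"]]))
  list(assignments = assignments, families = out_fam, trees = trees,
       within_identity = unlist(within))
}

#' Fraction of a replicon covered by registered matches against another
#'
#' Runs [register_matches()] and returns the merged-interval coverage of `a`.
#' @param a,b `replicon_record`s (or DNA strings)
#' @param min_match_len minimum match length, bp
#' @return fraction of `a` covered, in [0, 1]
#' @export
replicon_conservation <- function(a, b, min_match_len = 300) {
  sa <- if (is.character(a)) a else a$sequence
  m <- register_matches(a, b, min_match_len = min_match_len)
  if (nrow(m) == 0) return(0)
  iv <- m[order(m$start_a), c("start_a", "end_a")]
  covered <- 0; cur_s <- iv$start_a[1]; cur_e <- iv$end_a[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_a[i] <= cur_e) cur_e <- max(cur_e, iv$end_a[i]) else {
      covered <- covered + cur_e - cur_s
      cur_s <- iv$start_a[i]; cur_e <- iv$end_a[i]
    }
  }
  covered <- covered + cur_e - cur_s
  covered / nchar(sa)
}
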