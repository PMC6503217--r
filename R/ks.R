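# Synonymous substitution rates (Nei-Gojobori 1986) and the
# chromosome-versus-symbiotic-plasmid contrast that flags recent plasmid
# acquisition.
#
# NG86: each codon position contributes a synonymous-site fraction (the
# share of the three possible single-base changes that are synonymous;
# changes to stop codons count as nonsynonymous). Differences between codons
# are classified by averaging over all mutational pathways between them,
# excluding pathways that pass through stop codons (all pathways if none
# avoid stops). pS = Sd / S is Jukes-Cantor corrected:
# Ks = -(3/4) ln(1 - 4 pS / 3).

.codon_strings <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0)) # order irrelevant, all 64
}

.ng86_tables <- function() {
  if (!is.null(.rc$ng86)) return(.rc$ng86)
  gc <- .genetic_code()
  codons <- names(gc)
  aa <- gc[codons]
  n <- length(codons)
  # synonymous sites per codon (sum over 3 positions)
  syn_sites <- setNames(numeric(n), codons)
  bases <- c("T", "C", "A", "G")
  for (cd in codons) {
    if (aa[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(bases, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- nb
        if (aa[[mut]] != "*" && aa[[mut]] == aa[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }
  # pairwise Sd / Nd by pathway averaging
  sd_t <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_t <- matrix(0, n, n, dimnames = list(codons, codons))
  classify_step <- function(from, to) {
    # single-base step; synonymous iff both sense and same aa
    if (aa[[from]] == "*" || aa[[to]] == "*") return(c(0, 1))
    if (aa[[from]] == aa[[to]]) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      c1 <- codons[i]; c2 <- codons[j]
      if (aa[[c1]] == "*" || aa[[c2]] == "*") next
      diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      k <- length(diffpos)
      if (k == 0) next
      perms <- if (k == 1) list(diffpos) else
        if (k == 2) list(diffpos, rev(diffpos)) else
          lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                 function(p) diffpos[p])
      paths <- list()
      for (perm in perms) {
        cur <- c1
        steps <- list()
        ok <- TRUE
        for (pos in perm) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (gc[[nxt]] == "*" && nxt != c2) ok <- FALSE
          steps[[length(steps) + 1L]] <- c(cur, nxt)
          cur <- nxt
        }
        paths[[length(paths) + 1L]] <- list(steps = steps, ok = ok)
      }
      usable <- Filter(function(p) p$ok, paths)
      if (length(usable) == 0) usable <- paths
      acc <- c(0, 0)
      for (p in usable) {
        for (st in p$steps) acc <- acc + classify_step(st[1], st[2])
      }
      acc <- acc / length(usable)
      sd_t[i, j] <- sd_t[j, i] <- acc[1]
      nd_t[i, j] <- nd_t[j, i] <- acc[2]
    }
  }
  .rc$ng86 <- list(syn_sites = syn_sites, sd = sd_t, nd = nd_t)
  .rc$ng86
}

#' Synonymous substitution rate Ks by Nei-Gojobori (1986)
#'
#' Input must be codon-aligned CDS of equal length without internal stop
#' codons (use [codon_align()] to back-map a protein alignment first).
#' @param cds_a,cds_b aligned DNA strings (length divisible by 3)
#' @return list(ks, ps, S, Sd, saturated); `ks` is NA when the Jukes-Cantor
#'   argument is non-positive (saturated pair)
#' @export
ks_ng86 <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS lengths differ")
  n <- nchar(cds_a)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  tb <- .ng86_tables()
  ca <- substring(toupper(cds_a), seq(1, n, 3), seq(3, n, 3))
  cb <- substring(toupper(cds_b), seq(1, n, 3), seq(3, n, 3))
  sa <- tb$syn_sites[ca]; sb <- tb$syn_sites[cb]
  if (any(is.na(sa)) || any(is.na(sb))) stop("internal stop codon in input")
  S <- (sum(sa) + sum(sb)) / 2
  Sd <- sum(tb$sd[cbind(ca, cb)])
  ps <- Sd / S
  arg <- 1 - 4 * ps / 3
  ks <- if (arg <= 0) NA_real_ else -0.75 * log(arg)
  list(ks = ks, ps = ps, S = S, Sd = Sd, saturated = arg <= 0)
}

#' Codon-align two CDS via their protein local alignment
#'
#' Aligns the translated proteins (Smith-Waterman) and back-maps the matched
#' residue pairs to codons, returning equal-length gap-free codon-aligned CDS
#' (gapped columns are dropped, as NG86 requires).
#' @param cds_a,cds_b coding sequences (coding strand)
#' @return list(cds_a, cds_b, n_codons) or NULL when the proteins produce no
#'   alignment
#' @export
codon_align <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  if (grepl("\\*", pa) || grepl("\\*", pb)) stop("internal stop codon in input")
  hit <- align_proteins(pa, pb)
  if (length(hit$qpos) == 0) return(NULL)
  qs <- hit$qpos * 3 + 1
  ts <- hit$tpos * 3 + 1
  a <- paste(substring(cds_a, qs, qs + 2), collapse = "")
  b <- paste(substring(cds_b, ts, ts + 2), collapse = "")
  list(cds_a = a, cds_b = b, n_codons = length(qs))
}

#' Pair homologous genes between two genomes, split by compartment
#'
#' BDBH (50/50 gates) over the two full proteomes; reciprocal pairs are kept
#' when both genes lie on the chromosome (chromosome pairs) or both on the
#' symbiotic plasmid (psym pairs). Pairs straddling compartments are excluded
#' and logged.
#' @param a,b `genome_record`s; at least one must carry a psym
#' @param min_identity,min_coverage,min_score BDBH gates
#' @return list(chromosome = data.frame(gene_a, gene_b), psym = data.frame,
#'   n_cross_compartment)
#' @export
pair_homologs_by_compartment <- function(a, b, min_identity = 50,
                                         min_coverage = 50, min_score = 50) {
  kinds_a <- vapply(a$replicons, function(r) r$kind, character(1))
  kinds_b <- vapply(b$replicons, function(r) r$kind, character(1))
  if (!"psym" %in% c(kinds_a, kinds_b)) {
    stop(sprintf("neither genome ('%s', '%s') carries a psym replicon",
                 a$genome_id, b$genome_id))
  }
  gt <- gene_table(list(a, b))
  compart <- setNames(gt$kind, gt$gene_id)
  cds_of <- setNames(gt$cds, gt$gene_id)
  prot <- split(setNames(gt$protein, gt$gene_id), gt$genome_id)
  graph <- bdbh(prot, min_identity, min_coverage, min_score)
  e <- graph$edges
  if (nrow(e) == 0) {
    return(list(chromosome = data.frame(gene_a = character(), gene_b = character()),
                psym = data.frame(gene_a = character(), gene_b = character()),
                n_cross_compartment = 0L, cds = cds_of))
  }
  ka <- compart[e$gene_a]; kb <- compart[e$gene_b]
  both_chr <- ka == "chromosome" & kb == "chromosome"
  both_psym <- ka == "psym" & kb == "psym"
  cross <- ka != kb
  rc_log("pair_homologs: %d chromosome pairs, %d psym pairs, %d cross-compartment excluded",
         sum(both_chr), sum(both_psym), sum(cross))
  list(chromosome = e[both_chr, c("gene_a", "gene_b"), drop = FALSE],
       psym = e[both_psym, c("gene_a", "gene_b"), drop = FALSE],
       n_cross_compartment = sum(cross),
       cds = cds_of)
}

#' Chromosome-versus-psym synonymous rate contrast for a genome pair
#'
#' Computes Ks for every homologous pair in each compartment, summarises by
#' the median of unsaturated values, and flags recent psym transfer when the
#' psym/chromosome Ks ratio falls below `transfer_ratio_max` while the
#' chromosomal median exceeds `min_chr_ks` (the guard that keeps very recent
#' splits, where both compartments are near zero, unflagged). The reverse
#' pattern (psym median much larger, dissimilar evolutionary lines) is also
#' reported.
#' @param a,b `genome_record`s
#' @param transfer_ratio_max flag transfers below this psym/chromosome ratio
#' @param min_chr_ks required chromosomal median Ks
#' @param min_pairs minimum unsaturated Ks values per compartment; below it
#'   the flag is "indeterminate"
#' @param ... gates passed to [pair_homologs_by_compartment()]
#' @return a `compartment_contrast`: list with per-compartment Ks vectors,
#'   medians, ratio, transfer_flag (TRUE/FALSE/NA = indeterminate),
#'   reverse_flag, and counts
#' @export
compartment_contrast <- function(a, b, transfer_ratio_max = 0.2,
                                 min_chr_ks = 0.1, min_pairs = 10, ...) {
  ph <- pair_homologs_by_compartment(a, b, ...)
  ks_of <- function(pairs) {
    out <- numeric(0)
    for (i in seq_len(nrow(pairs))) {
      al <- tryCatch(codon_align(ph$cds[[pairs$gene_a[i]]],
                                 ph$cds[[pairs$gene_b[i]]]),
                     error = function(e) NULL)
      if (is.null(al)) next
      k <- ks_ng86(al$cds_a, al$cds_b)
      if (!k$saturated) out <- c(out, k$ks)
    }
    out
  }
  ks_chr <- ks_of(ph$chromosome)
  ks_psym <- ks_of(ph$psym)
  med_chr <- if (length(ks_chr) > 0) median(ks_chr) else NA_real_
  med_psym <- if (length(ks_psym) > 0) median(ks_psym) else NA_real_
  indet <- length(ks_chr) < min_pairs || length(ks_psym) < min_pairs
  ratio <- if (!is.na(med_chr) && med_chr > 0) med_psym / med_chr else NA_real_
  transfer <- if (indet) NA else
    isTRUE(ratio < transfer_ratio_max) && isTRUE(med_chr > min_chr_ks)
  reverse <- if (indet) NA else
    isTRUE(ratio > 1 / transfer_ratio_max) && isTRUE(med_psym > min_chr_ks)
  rc_log("compartment_contrast %s-%s: median Ks chr=%.4f psym=%.4f ratio=%.3f flag=%s",
         a$genome_id, b$genome_id, med_chr, med_psym, ratio,
         as.character(transfer))
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 ks_values_chromosome = ks_chr, ks_values_psym = ks_psym,
                 median_ks_chr = med_chr, median_ks_psym = med_psym,
                 ratio = ratio, transfer_flag = transfer,
                 reverse_flag = reverse,
                 n_cross_compartment = ph$n_cross_compartment),
            class = "compartment_contrast")
}
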