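# Shared fixtures and independent oracles. Everything is generated in code;
# expensive simulations are cached for the duration of the test run.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# single-chromosome genome wrapper
mk_genome <- function(id, seq, status = "complete", genes = list()) {
  genome_record(id, status,
                list(replicon_record(paste0(id, "_chr"), "chromosome", seq,
                                     genes)))
}

# genome carrying all nod/nif tags (for the collection filter tests)
mk_tagged_genome <- function(id, len = 4000, status = "complete",
                             tags = c("nodA", "nodB", "nodC",
                                      "nifH", "nifD", "nifK"),
                             seed = 1) {
  set.seed(seed)
  seq <- rand_dna(len)
  genes <- lapply(seq_along(tags), function(i) {
    gene_record(paste0(id, "_t", i), (i - 1) * 120, (i - 1) * 120 + 90,
                "+", role_tags = tags[i])
  })
  mk_genome(id, seq, status, genes)
}

# JC69-mutated copy of a DNA string at distance d
jc_mutate <- function(seq, d, seed = 1) {
  set.seed(seed)
  v <- rhizocontinuum:::encode_dna(seq)
  rhizocontinuum:::decode_dna(rhizocontinuum:::mutate_jc69(v, d))
}

jc_identity_pct <- function(d) 100 * (0.25 + 0.75 * exp(-4 * d / 3))

# ultrametric caterpillar tree whose leaf pairs span the given distances
ladder_newick <- function(ds, subs_rate) {
  h <- ds / (2 * subs_rate)
  n <- length(ds) + 1
  lab <- sprintf("g%02d", seq_len(n))
  sub <- sprintf("(%s:%.8f,%s:%.8f)", lab[1], h[1], lab[2], h[1])
  for (i in seq_along(ds)[-1]) {
    sub <- sprintf("(%s:%.8f,%s:%.8f)", sub, h[i] - h[i - 1], lab[i + 1], h[i])
  }
  paste0(sub, ";")
}

# k clades of `m` leaves: star within (pairwise d_within), star between
clade_newick <- function(d_within, d_between, k = 3, m = 3,
                         subs_rate = 0.05) {
  hw <- d_within / (2 * subs_rate)
  hb <- d_between / (2 * subs_rate)
  clades <- vapply(seq_len(k), function(i) {
    tips <- paste0("c", i, letters[seq_len(m)], ":", hw / 1)
    paste0("(", paste(tips, collapse = ","), "):", hb - hw)
  }, character(1))
  paste0("(", paste(clades, collapse = ","), ");")
}

# small default-ish simulator config scaled for tests
test_config <- function(...) {
  args <- list(
    n_genomes = 6, subs_rate = 0.04, n_core_genes = 15, n_marker_genes = 8,
    n_accessory_pool = 30, gain_rate = 0.3, loss_rate = 1,
    mean_gene_len = 120, chromosome_length = 30000,
    plasmid_plan = list(list(kind = "plasmid", n_genes = 5, length = 8000),
                        list(kind = "psym", n_genes = 9, length = 12000)),
    seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

sim_small <- function() cached("sim_small", evolve_collection(test_config()))

# ---- independent oracles ------------------------------------------------

# full-matrix local affine-gap DP (Gotoh), independent of the C++ kernel
sw_oracle_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- X <- Y <- matrix(0, n + 1, m + 1)
  X[] <- -Inf; Y[] <- -Inf
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + B[av[i], bv[j]],
                             X[i + 1, j + 1], Y[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# brute-force reciprocal best hits over toy proteomes
bdbh_oracle <- function(proteomes, min_identity = 50, min_coverage = 50,
                        min_score = 50) {
  gids <- names(proteomes)
  edges <- list()
  hit_tab <- function(q, ts) {
    do.call(rbind, lapply(names(ts), function(t) {
      h <- align_proteins(q, ts[[t]])
      data.frame(target = t, score = h$score, identity = h$pct_identity,
                 qcov = h$query_cov, tcov = h$target_cov,
                 stringsAsFactors = FALSE)
    }))
  }
  best_of <- function(q, ts) {
    tab <- hit_tab(q, ts)
    tab <- tab[tab$identity >= min_identity & tab$qcov >= min_coverage &
               tab$tcov >= min_coverage & tab$score >= min_score, ,
               drop = FALSE]
    if (nrow(tab) == 0) return(NA_character_)
    tab <- tab[order(-tab$score, -tab$identity, tab$target), , drop = FALSE]
    tab$target[1]
  }
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (j <= i) next
    A <- proteomes[[i]]; B <- proteomes[[j]]
    for (qa in names(A)) {
      tb <- best_of(A[[qa]], B)
      if (is.na(tb)) next
      back <- best_of(B[[tb]], A)
      if (!is.na(back) && back == qa) {
        edges[[length(edges) + 1L]] <- c(qa, tb)
      }
    }
  }
  if (length(edges) == 0) return(character(0))
  sort(vapply(edges, function(e) paste(sort(e), collapse = "|"), character(1)))
}

edge_keys <- function(graph) {
  if (nrow(graph$edges) == 0) return(character(0))
  sort(apply(graph$edges[, c("gene_a", "gene_b")], 1, function(e)
    paste(sort(e), collapse = "|")))
}

# exhaustive bipartition sets via subset enumeration (n <= 8 leaves)
splits_oracle <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  rooted <- ape::root(tree, outgroup = ref, resolve.root = TRUE)
  others <- setdiff(tips, ref)
  out <- character(0)
  for (k in 2:(length(tips) - 2)) {
    sets <- utils::combn(others, k, simplify = FALSE)
    for (s in sets) {
      if (ape::is.monophyletic(rooted, s)) {
        out <- c(out, paste(sort(s), collapse = "|"))
      }
    }
  }
  unique(out)
}

rf_oracle <- function(t1, t2) {
  s1 <- splits_oracle(t1); s2 <- splits_oracle(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# adjusted Rand index between two labelings (same names)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# cluster membership vector from a list of clusters
membership_of <- function(clusters) {
  out <- character(0)
  for (i in seq_along(clusters)) {
    out[clusters[[i]]] <- paste0("k", i)
  }
  out
}
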