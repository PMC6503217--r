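# Protein homology layer: alignment vs an exhaustive DP oracle, BDBH vs
# brute-force enumeration, MCL reference cases, consensus core semantics.

test_that("local alignment scores match the full-matrix DP oracle", {
  set.seed(5)
  for (i in 1:8) {
    a <- rand_protein(sample(20:60, 1))
    b <- rand_protein(sample(20:60, 1))
    expect_equal(align_proteins(a, b)$score, sw_oracle_score(a, b))
  }
  # and on related sequences
  p <- rand_protein(80, seed = 6)
  q <- paste0(substr(p, 1, 40), rand_protein(40, seed = 7))
  expect_equal(align_proteins(p, q)$score, sw_oracle_score(p, q))
})

test_that("self alignment is perfect; all-negative pairs align empty", {
  p <- rand_protein(50, seed = 8)
  h <- align_proteins(p, p)
  expect_equal(h$pct_identity, 100)
  expect_equal(h$query_cov, 100)
  expect_equal(h$target_cov, 100)
  h0 <- align_proteins("KKKKK", "DDDDD")  # K/D scores negative under BLOSUM62
  expect_equal(h0$score, 0)
  expect_equal(h0$align_len, 0)
  expect_error(align_proteins("MK2L", "MKL"), "illegal")
  expect_error(align_proteins("", "MKL"), "empty")
})

test_that("BDBH equals brute-force reciprocal-best enumeration on toy proteomes", {
  set.seed(11)
  for (rep in 1:6) {
    n_genomes <- sample(2:4, 1)
    base <- lapply(1:sample(3:6, 1), function(i) rand_protein(sample(40:80, 1)))
    proteomes <- list()
    for (g in seq_len(n_genomes)) {
      genes <- vapply(seq_along(base), function(i) {
        v <- strsplit(base[[i]], "")[[1]]
        nmut <- rbinom(1, length(v), 0.1)
        pos <- sample(seq_along(v), nmut)
        v[pos] <- sample(c("A","R","N","D","G","S","T","V"), nmut, replace = TRUE)
        paste(v, collapse = "")
      }, character(1))
      names(genes) <- paste0("G", g, "_p", seq_along(base))
      proteomes[[paste0("G", g)]] <- genes
    }
    # drop a random gene sometimes, duplicate one as a paralog sometimes
    if (runif(1) < 0.5) proteomes[[1]] <- proteomes[[1]][-1]
    if (runif(1) < 0.5) {
      proteomes[[2]] <- c(proteomes[[2]],
                          setNames(proteomes[[2]][1], paste0(names(proteomes[[2]])[1], "dup")))
    }
    expect_equal(edge_keys(bdbh(proteomes)), bdbh_oracle(proteomes))
  }
})

test_that("identical proteomes pair perfectly; weak hits make no edge", {
  genes <- setNames(vapply(1:4, function(i) rand_protein(60, seed = 20 + i),
                           character(1)), paste0("p", 1:4))
  proteomes <- list(A = setNames(genes, paste0("A_", names(genes))),
                    B = setNames(genes, paste0("B_", names(genes))))
  g <- bdbh(proteomes)
  expect_equal(nrow(g$edges), 4)
  expect_equal(sub("A_", "", g$edges$gene_a), sub("B_", "", g$edges$gene_b))
  # a pair at ~40% identity fails the 50% gate
  a <- rand_protein(60, seed = 30)
  v <- strsplit(a, "")[[1]]
  set.seed(31)
  pos <- sample(60, 36)
  v[pos] <- sample(setdiff(LETTERS[1:20], "J"), 36, replace = TRUE)
  weak <- list(A = c(x = a), B = c(y = paste(v, collapse = "")))
  expect_equal(nrow(bdbh(weak)$edges), 0)
})

test_that("MCL recovers reference clusterings and ignores node order", {
  cliq <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  cliq[1:2, 1:2] <- 1; cliq[3:5, 3:5] <- 1; diag(cliq) <- 0
  expect_equal(mcl_cluster(cliq), list(c("a", "b"), c("c", "d", "e")),
               ignore_attr = TRUE)
  barbell <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (e in list(c(1,2), c(1,3), c(2,3), c(4,5), c(4,6), c(5,6))) {
    barbell[e[1], e[2]] <- barbell[e[2], e[1]] <- 10
  }
  barbell[3, 4] <- barbell[4, 3] <- 1
  expect_equal(mcl_cluster(barbell, inflation = 1.5),
               list(c("a", "b", "c"), c("d", "e", "f")), ignore_attr = TRUE)
  expect_equal(mcl_cluster(matrix(0, 1, 1, dimnames = list("z", "z"))),
               list("z"), ignore_attr = TRUE)
  expect_error(mcl_cluster(-barbell), "non-negative")
  # permutation invariance on random graphs
  set.seed(3)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    g <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    ne <- sample(3:(n * 2), 1)
    for (k in seq_len(ne)) {
      ij <- sample(n, 2)
      g[ij[1], ij[2]] <- g[ij[2], ij[1]] <- sample(1:10, 1)
    }
    perm <- sample(n)
    c1 <- mcl_cluster(g)
    c2 <- mcl_cluster(g[perm, perm])
    expect_identical(c1, c2)
  }
})

test_that("consensus core keeps only families where both methods agree, one copy per genome", {
  gene_genomes <- c(A_x = "A", B_x = "B", C_x = "C",
                    A_y = "A", B_y = "B", C_y = "C",
                    A_z = "A", B_z = "B")
  genomes <- c("A", "B", "C")
  bd <- list(c("A_x", "B_x", "C_x"), c("A_y", "B_y", "C_y"), c("A_z", "B_z"))
  # y split differently by MCL; z missing genome C
  mc <- list(c("A_x", "B_x", "C_x"), c("A_y", "B_y"), list("C_y")[[1]],
             c("A_z", "B_z"))
  cc <- consensus_core(bd, mc, gene_genomes, genomes)
  expect_equal(unique(cc$family_id), "CC0001")
  expect_setequal(cc$gene_id, c("A_x", "B_x", "C_x"))
})

test_that("clustering recovers the simulator's family table exactly", {
  sim <- sim_small()
  gt <- gene_table(sim$genomes)
  prot <- split(setNames(gt$protein, gt$gene_id), gt$genome_id)
  graph <- bdbh(prot)
  simg <- protein_similarity_graph(setNames(gt$protein, gt$gene_id))
  mfams <- mcl_cluster(simg)
  fams <- family_table_from_clusters(mfams, graph$gene_genomes)
  truth <- setNames(gt$family_truth, gt$gene_id)
  pred <- setNames(fams$family_id, fams$gene_id)[names(truth)]
  expect_equal(ari(pred, truth), 1)
  # consensus core contains every never-lost family
  cc <- consensus_core(bdbh_families(graph), mfams, graph$gene_genomes,
                       genome_ids(sim$genomes))
  persistent <- rownames(sim$truth$family_table)[
    rowSums(sim$truth$family_table) == length(sim$genomes) &
      !grepl("^acc", rownames(sim$truth$family_table))]
  expect_gte(length(unique(cc$family_id)), length(persistent))
})

test_that("Bray-Curtis follows its definition and rejects degenerate input", {
  expect_equal(bray_curtis(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(bray_curtis(c(2, 3), c(2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("profile ordering is deterministic and joins identical columns first", {
  set.seed(9)
  pa <- matrix(rbinom(60, 1, 0.5), 12, 5,
               dimnames = list(paste0("f", 1:12), paste0("g", 1:5)))
  pa[, 2] <- pa[, 1]  # identical pair
  op <- order_profiles(pa)
  h <- op$hclust
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("g1", "g2"))
  expect_equal(h$height[1], 0)
  expect_identical(op$order, order_profiles(pa)$order)
})

test_that("the k-mer prefilter never changes batch alignment results on family data", {
  sim <- sim_small()
  gt <- gene_table(sim$genomes)
  prot <- setNames(gt$protein, gt$gene_id)[1:60]
  m1 <- rhizocontinuum:::.sw_matrices(prot, prot, prefilter = TRUE)
  m2 <- rhizocontinuum:::.sw_matrices(prot, prot, prefilter = FALSE)
  pass1 <- m1$pct_identity >= 50 & m1$query_cov >= 50 & m1$target_cov >= 50 &
    m1$score >= 50
  pass2 <- m2$pct_identity >= 50 & m2$query_cov >= 50 & m2$target_cov >= 50 &
    m2$score >= 50
  expect_identical(pass1, pass2)
  expect_identical(m1$score[pass1], m2$score[pass2])
})
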