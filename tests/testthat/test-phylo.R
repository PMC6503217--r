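# Marker phylogenetics: trimming, corrected distances, NJ, RF, and the
# congruence filter.

mk_marker <- function(seqs, id = "m1") {
  structure(list(family_id = id, seqs = seqs), class = "marker_alignment")
}

test_that("complete deletion removes exactly the gapped columns", {
  seqs <- c(g1 = "MKLVITGAQW", g2 = "MKLVITGAQW", g3 = "MKLVIT-AQW")
  tr <- trim_columns(mk_marker(seqs))
  expect_equal(unname(nchar(tr$seqs)), rep(9, 3))
  expect_equal(attr(tr, "kept_columns"), setdiff(1:10, 7))
  # gap-free input unchanged
  clean <- c(g1 = "MKLVIT", g2 = "MKLVIA")
  expect_equal(trim_columns(mk_marker(clean))$seqs, clean)
  # random alignments: retained columns equal a direct recount
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(sample(c("A", "R", "N", "-"), 60, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 4, 15)
    seqs <- setNames(apply(m, 1, paste, collapse = ""), paste0("g", 1:4))
    expected <- sum(colSums(m == "-") == 0)
    if (expected == 0) {
      expect_error(trim_columns(mk_marker(seqs)), "all columns")
    } else {
      expect_equal(unname(nchar(trim_columns(mk_marker(seqs))$seqs[1])), expected)
    }
  }
  all_gap <- c(g1 = "M-", g2 = "M-", g3 = "--")
  expect_error(trim_columns(mk_marker(all_gap)), "all columns")
})

test_that("corrected distances follow their closed forms and flag saturation", {
  seqs <- c(a = "MKLVITGAQW", b = "MKLVITGAQW")
  d0 <- pairwise_distance(mk_marker(seqs)$seqs)
  expect_equal(d0["a", "b"], 0)
  # p = 0.1 over 10 sites: one difference
  seqs2 <- c(a = "MKLVITGAQW", b = "MKLVITGAQY")
  dk <- pairwise_distance(seqs2, model = "kimura-protein")
  expect_equal(dk["a", "b"], -log(1 - 0.1 - 0.01 / 5), tolerance = 1e-12)
  dp <- pairwise_distance(seqs2, model = "poisson")
  expect_equal(dp["a", "b"], -log(0.9), tolerance = 1e-12)
  # saturation: completely different rows under kimura
  seqs3 <- c(a = "AAAAAAAAAA", b = "RRRRRRRRRR")
  dsat <- pairwise_distance(seqs3, model = "kimura-protein")
  expect_true(is.na(dsat["a", "b"]))
  expect_true(attr(dsat, "saturated")["a", "b"])
  expect_error(pairwise_distance(c(a = "", b = "")), "empty")
})

test_that("distance estimates recover the simulated divergence", {
  cfg <- test_config(n_accessory_pool = 0, gain_rate = 0, loss_rate = 0,
                     n_core_genes = 20, n_marker_genes = 20,
                     mean_gene_len = 200, chromosome_length = 30000,
                     tree = sprintf("(gA:%f,gB:%f);", 0.025 / 0.04, 0.025 / 0.04))
  sim <- evolve_collection(cfg)
  mk <- extract_markers(sim$genomes)
  smx <- concat_markers(mk)
  d <- pairwise_distance(smx, model = "poisson")
  # protein Poisson distance of JC-translated sequences is monotone in the
  # nucleotide divergence; at d_nt = 0.05 the aa distance is near 0.075
  expect_gt(d["gA", "gB"], 0.03)
  expect_lt(d["gA", "gB"], 0.12)
})

test_that("NJ recovers additive matrices exactly", {
  tr4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D4 <- cophenetic(tr4)[LETTERS[1:4], LETTERS[1:4]]
  nt <- nj_tree(D4)
  expect_equal(rf_distance(nt, tr4), 0)
  expect_equal(cophenetic(nt)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)
  # 8-taxon additive matrix
  tr8 <- simulate_tree(8, 1, seed = 2)
  tr8$edge.length <- tr8$edge.length + 0.05
  D8 <- cophenetic(tr8)
  nt8 <- nj_tree(D8)
  expect_equal(rf_distance(nt8, tr8), 0)
  expect_equal(cophenetic(nt8)[rownames(D8), colnames(D8)], D8,
               tolerance = 1e-9)
  # agreement with the ape implementation on the same input
  expect_equal(rf_distance(nt8, ape::nj(D8)), 0)
  # three taxa: closed-form three-point solution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  expect_equal(cophenetic(t3)[rownames(D3), colnames(D3)], D3,
               tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "non-finite|at least 3")
})

test_that("NJ on an ultrametric matrix matches the UPGMA topology", {
  tr <- simulate_tree(10, 1, seed = 6)
  D <- cophenetic(tr)
  nj <- nj_tree(D)
  up <- ape::as.phylo(hclust(as.dist(D), method = "average"))
  expect_equal(rf_distance(nj, up), 0)
})

test_that("RF distance agrees with exhaustive bipartition enumeration", {
  t_a <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_b <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(t_a, t_a), 0)
  expect_equal(rf_distance(t_a, t_b), 2)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, tip.label = paste0("t", 1:n))
    t2 <- ape::rtree(n, tip.label = paste0("t", 1:n))
    expect_equal(rf_distance(t1, t2), rf_oracle(t1, t2))
  }
  t3 <- ape::rtree(5)
  t4 <- ape::rtree(6)
  expect_error(rf_distance(t3, t4), "leaf sets")
})

test_that("marker extraction drops missing and multi-copy families", {
  sim <- sim_small()
  mk <- extract_markers(sim$genomes)
  expect_length(mk, sim$truth$config$n_marker_genes)
  # delete the marker from one genome -> dropped from the universal set
  genomes2 <- sim$genomes
  fam_gone <- mk[[1]]$family_id
  g1 <- genomes2[[1]]
  for (ri in seq_along(g1$replicons)) {
    keep <- vapply(g1$replicons[[ri]]$genes,
                   function(g) !identical(g$family_truth, fam_gone), logical(1))
    g1$replicons[[ri]]$genes <- g1$replicons[[ri]]$genes[keep]
  }
  genomes2[[1]] <- g1
  mk2 <- extract_markers(genomes2)
  expect_length(mk2, length(mk) - 1)
  expect_false(fam_gone %in% vapply(mk2, `[[`, "", "family_id"))
  # duplicate a marker gene in one genome -> multi-copy, dropped
  genomes3 <- sim$genomes
  g1 <- genomes3[[1]]
  dup <- g1$replicons[[1]]$genes[[1]]
  dup$gene_id <- paste0(dup$gene_id, "_dup")
  g1$replicons[[1]]$genes <- c(g1$replicons[[1]]$genes, list(dup))
  genomes3[[1]] <- g1
  mk3 <- extract_markers(genomes3)
  expect_length(mk3, length(mk) - 1)
  expect_error(extract_markers(sim$genomes, role_tag = "no_such_tag"), "tag")
})

test_that("concatenation order affects neither distances nor trees", {
  sim <- sim_small()
  mk <- extract_markers(sim$genomes)
  d1 <- pairwise_distance(concat_markers(mk))
  d2 <- pairwise_distance(concat_markers(rev(mk)))
  expect_equal(d1, d2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the congruence filter keeps clean markers and drops a planted transfer", {
  cfg <- test_config(n_genomes = 8, subs_rate = 0.05, n_core_genes = 12,
                     n_marker_genes = 12, n_accessory_pool = 0, gain_rate = 0,
                     loss_rate = 0, mean_gene_len = 300,
                     chromosome_length = 25000, seed = 17)
  sim <- evolve_collection(cfg)
  mk <- extract_markers(sim$genomes)
  mf <- filter_markers(mk)
  expect_gte(length(mf$retained), 9)  # no planted incongruence: most retained
  # plant a marker transfer between distant leaves
  coph <- cophenetic(sim$truth$tree)
  ij <- which(coph == max(coph), arr.ind = TRUE)[1, ]
  donor <- rownames(coph)[ij[1]]; recip <- colnames(coph)[ij[2]]
  g2 <- plant_marker_hgt(sim$genomes, "core004", donor, recip)
  mf2 <- filter_markers(extract_markers(g2))
  expect_true("core004" %in% mf2$dropped)
  expect_error(filter_markers(mk, min_len = 10000), "length filter")
})
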