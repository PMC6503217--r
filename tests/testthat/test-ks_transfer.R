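# NG86 synonymous rates and the chromosome-vs-psym transfer contrast.

test_that("Ks is zero for identical CDS and validates its input", {
  cds <- "ATGGCTGGTCCAACG"
  k <- ks_ng86(cds, cds)
  expect_equal(k$ks, 0)
  expect_false(k$saturated)
  expect_error(ks_ng86("ATGGCT", "ATG"), "differ")
  expect_error(ks_ng86("ATGG", "ATGG"), "divisible")
  expect_error(ks_ng86("ATGTAAGGG", "ATGTAAGGG"), "stop")
})

test_that("the two-codon Leu case follows the hand computation (saturated)", {
  # TTT TTA vs TTT TTG: S(TTT)=1/3, S(TTA)=S(TTG)=2/3 -> S=1; the single
  # third-position difference is synonymous -> Sd=1, pS=1, JC argument < 0
  k <- ks_ng86("TTTTTA", "TTTTTG")
  expect_equal(k$S, 1)
  expect_equal(k$Sd, 1)
  expect_equal(k$ps, 1)
  expect_true(k$saturated)
  expect_true(is.na(k$ks))
})

test_that("Ks matches reference NG86 values", {
  # frozen from an independent NG86 implementation
  k1 <- ks_ng86("TTTGCATTAACGGGT", "TTTGCATTGACGGGT")
  expect_equal(k1$ks, 0.3040988311, tolerance = 1e-9)
  k2 <- ks_ng86("ATGGCTCCGACC", "ATGGCACCGACA")
  expect_equal(k2$ks, 1.6479184330, tolerance = 1e-9)
  k3 <- ks_ng86("ATGAAACGTGGTTGCTTA", "ATGAAGCGAGGATGCCTA")
  expect_true(k3$saturated)
})

test_that("NG86 recovers the generating synonymous divergence", {
  pairs <- simulate_syn_cds_pairs(100, 200, 0.2, seed = 3)
  est <- vapply(pairs, function(p) ks_ng86(p$cds_a, p$cds_b)$ks, numeric(1))
  expect_lt(abs(median(est) - 0.2) / 0.2, 0.05)
  expect_lt(abs(mean(est) - 0.2) / 0.2, 0.05)
})

test_that("codon alignment back-maps the protein alignment", {
  cds <- "ATGGCTGGTCCAACGAAACGT"
  al <- codon_align(cds, cds)
  expect_equal(al$cds_a, cds)
  expect_equal(al$n_codons, 7)
  al2 <- codon_align("ATGGCTGGTCCAACGAAACGT", "GCTGGTCCAACG")
  expect_equal(al2$cds_a, al2$cds_a)
  expect_equal(nchar(al2$cds_a), nchar(al2$cds_b))
  expect_equal(ks_ng86(al2$cds_a, al2$cds_b)$ks, 0)
})

test_that("homolog pairing is split by compartment and excludes cross pairs", {
  sim <- sim_small()
  a <- sim$genomes[[1]]
  # an identical copy under another id: every gene pairs with its twin
  a2 <- a
  a2$genome_id <- "twin"
  for (ri in seq_along(a2$replicons)) {
    a2$replicons[[ri]]$replicon_id <- paste0("twin_", ri)
    a2$replicons[[ri]]$genes <- lapply(a2$replicons[[ri]]$genes, function(g) {
      g$gene_id <- sub(a$genome_id, "twin", g$gene_id, fixed = TRUE)
      g
    })
  }
  ph <- pair_homologs_by_compartment(a, a2)
  gt <- gene_table(list(a))
  expect_equal(nrow(ph$chromosome), sum(gt$kind == "chromosome"))
  expect_equal(nrow(ph$psym), sum(gt$kind == "psym"))
  # a gene present only on one psym is unpaired
  b <- sim$genomes[[2]]
  pi_b <- which(vapply(b$replicons, function(r) r$kind == "psym", logical(1)))
  extra <- gene_record(paste0(b$genome_id, "_orphan"), 0, 90, "+",
                       cds = paste(rep("GCTGGTCCA", 10), collapse = ""),
                       role_tags = "symbiotic")
  b$replicons[[pi_b]]$genes <- c(b$replicons[[pi_b]]$genes, list(extra))
  ph2 <- pair_homologs_by_compartment(a, b)
  expect_false(paste0(b$genome_id, "_orphan") %in%
               c(ph2$psym$gene_a, ph2$psym$gene_b))
  # no psym anywhere -> error naming the genomes
  strip <- function(g) {
    g$replicons <- Filter(function(r) r$kind != "psym", g$replicons)
    g
  }
  expect_error(pair_homologs_by_compartment(strip(a), strip(b)),
               a$genome_id)
})

test_that("the contrast flags planted transfers and not null or recent-split pairs", {
  cfg <- test_config(n_accessory_pool = 0, gain_rate = 0, loss_rate = 0,
                     n_core_genes = 25, mean_gene_len = 200,
                     chromosome_length = 40000,
                     plasmid_plan = list(list(kind = "psym", n_genes = 14,
                                              length = 16000)))
  tp <- simulate_transfer_pair(cfg, split_distance = 0.3,
                               transfer_fraction = 0.1, seed = 5)
  cc <- compartment_contrast(tp$genomes[[1]], tp$genomes[[2]])
  expect_true(cc$transfer_flag)
  expect_lt(cc$ratio, 0.2)
  # null case: ratio near 1, no flag
  tp0 <- simulate_transfer_pair(cfg, split_distance = 0.3,
                                transfer_fraction = 1, seed = 5)
  cc0 <- compartment_contrast(tp0$genomes[[1]], tp0$genomes[[2]])
  expect_false(cc0$transfer_flag)
  expect_lt(abs(cc0$ratio - 1), 0.35)
  # both compartments near zero: the chromosomal guard keeps it unflagged
  tpr <- simulate_transfer_pair(cfg, split_distance = 0.02,
                                transfer_fraction = 1, seed = 6)
  ccr <- compartment_contrast(tpr$genomes[[1]], tpr$genomes[[2]])
  expect_false(ccr$transfer_flag)
  # insufficient pairs -> indeterminate
  cci <- compartment_contrast(tp$genomes[[1]], tp$genomes[[2]],
                              min_pairs = 1000)
  expect_true(is.na(cci$transfer_flag))
})

test_that("gene order never changes the compartment medians", {
  cfg <- test_config(n_accessory_pool = 0, gain_rate = 0, loss_rate = 0,
                     n_core_genes = 15, chromosome_length = 25000)
  tp <- simulate_transfer_pair(cfg, split_distance = 0.2,
                               transfer_fraction = 0.5, seed = 9)
  a <- tp$genomes[[1]]; b <- tp$genomes[[2]]
  cc1 <- compartment_contrast(a, b, min_pairs = 5)
  # shuffle gene order within replicons
  shuffle <- function(g, seed) {
    set.seed(seed)
    for (ri in seq_along(g$replicons)) {
      g$replicons[[ri]]$genes <- sample(g$replicons[[ri]]$genes)
    }
    g
  }
  cc2 <- compartment_contrast(shuffle(a, 1), shuffle(b, 2), min_pairs = 5)
  expect_equal(sort(cc1$ks_values_chromosome), sort(cc2$ks_values_chromosome))
  expect_equal(cc1$median_ks_chr, cc2$median_ks_chr)
  expect_equal(cc1$median_ks_psym, cc2$median_ks_psym)
})
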