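# Simulator ground-truth guarantees: determinism, JC69 closed forms,
# transfer semantics, gene-content equilibrium, Yule expectations.

test_that("identical configs give identical output", {
  cfg <- test_config(seed = 13, psym_transfer_rate = 0.5)
  s1 <- evolve_collection(cfg)
  s2 <- evolve_collection(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("true distances equal subs_rate times tree path length", {
  sim <- sim_small()
  coph <- cophenetic(sim$truth$tree)
  lab <- rownames(sim$truth$true_pairwise_distance)
  expect_equal(sim$truth$true_pairwise_distance,
               sim$truth$config$subs_rate * coph[lab, lab])
})

test_that("zero rates and zero branch lengths give identical genomes", {
  nwk <- "(gA:0,gB:0,gC:0);"
  cfg <- test_config(tree = nwk, subs_rate = 0, gain_rate = 0, loss_rate = 0,
                     n_accessory_pool = 0)
  sim <- evolve_collection(cfg)
  seqs <- lapply(sim$genomes, function(g)
    vapply(g$replicons, `[[`, "", "sequence"))
  expect_equal(unname(seqs[[1]]), unname(seqs[[2]]))
  expect_equal(unname(seqs[[1]]), unname(seqs[[3]]))
  expect_true(all(sim$truth$true_pairwise_distance == 0))
})

test_that("realized per-site identity follows the JC69 closed form", {
  # pair at true distance 0.05 over >= 10 kb of orthologous sequence
  cfg <- test_config(n_accessory_pool = 0, gain_rate = 0, loss_rate = 0,
                     tree = sprintf("(gA:%f,gB:%f);", 0.025 / 0.04, 0.025 / 0.04))
  sim <- evolve_collection(cfg)
  a <- sim$genomes[[1]]$replicons[[1]]$sequence
  b <- sim$genomes[[2]]$replicons[[1]]$sequence
  expect_gte(nchar(a), 10000)
  va <- rhizocontinuum:::encode_dna(a)
  vb <- rhizocontinuum:::encode_dna(b)
  pid <- mean(va == vb)
  expected <- 0.25 + 0.75 * exp(-4 * 0.05 / 3)
  se <- sqrt(expected * (1 - expected) / length(va))
  expect_lt(abs(pid - expected), 4 * se + 0.002)
})

test_that("psym transfer copies the donor replicon exactly at the event time", {
  cfg <- test_config(n_accessory_pool = 0, gain_rate = 0, loss_rate = 0)
  tp <- simulate_transfer_pair(cfg, split_distance = 0.2,
                               transfer_fraction = 0, seed = 4)
  psym <- function(g) Filter(function(r) r$kind == "psym", g$replicons)[[1]]
  chr <- function(g) Filter(function(r) r$kind == "chromosome", g$replicons)[[1]]
  # transfer at the present: psym sequences byte-identical, chromosomes not
  expect_identical(psym(tp$genomes[[1]])$sequence, psym(tp$genomes[[2]])$sequence)
  expect_false(identical(chr(tp$genomes[[1]])$sequence,
                         chr(tp$genomes[[2]])$sequence))
  expect_equal(nrow(tp$truth$transfer_events), 1)
  expect_equal(tp$truth$psym_divergence["gA", "gB"], 0)
  expect_equal(tp$truth$chromosome_divergence["gA", "gB"], 0.2)
})

test_that("no transfers at rate zero, and psym tracks the chromosome", {
  sim <- sim_small()  # psym_transfer_rate = 0
  expect_equal(nrow(sim$truth$transfer_events), 0)
  expect_equal(sim$truth$psym_divergence, sim$truth$chromosome_divergence)
})

test_that("accessory gene content sits at the gain/loss equilibrium", {
  # long branches: occupancy per pool family converges to g / (g + l)
  g <- 0.5; l <- 1
  cfg <- test_config(tree = "(gA:3,gB:3,gC:3,gD:3,gE:3,gF:3);",
                     gain_rate = g, loss_rate = l, n_accessory_pool = 80,
                     chromosome_length = 15000, mean_gene_len = 80, seed = 21)
  sim <- evolve_collection(cfg)
  pa <- sim$truth$family_table
  acc <- pa[grepl("^acc", rownames(pa)), , drop = FALSE]
  occupancy <- mean(acc)
  expected <- g / (g + l)
  n_cells <- 80 * 6
  se <- sqrt(expected * (1 - expected) / n_cells)
  expect_lt(abs(occupancy - expected), 4 * se + 0.02)
})

test_that("Yule trees are ultrametric, deterministic, and grow as exp(lambda t)", {
  expect_error(simulate_tree(1, 1), "n must be")
  t2 <- simulate_tree(2, 1, seed = 3)
  depths <- ape::node.depth.edgelength(t2)
  expect_equal(depths[1], depths[2])  # cherry: equal root-to-leaf paths
  a <- simulate_tree(16, 1, seed = 9)
  b <- simulate_tree(16, 1, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(ape::is.ultrametric(a, tol = 1e-8))
  # E[N(t)] = 2 exp(lambda t) from two starting lineages
  lambda <- 1; tstar <- 0.8
  counts <- vapply(1:400, function(s) {
    tr <- simulate_tree(40, lambda, seed = s)
    dep <- ape::node.depth.edgelength(tr)
    splits <- dep[(ape::Ntip(tr) + 1):length(dep)]  # internal node depths
    sum(splits <= tstar & splits > 1e-12) + 2
  }, numeric(1))
  expected <- 2 * exp(lambda * tstar)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05)
})

test_that("synonymous-only CDS pairs carry the requested divergence", {
  pairs <- simulate_syn_cds_pairs(40, 300, 0.2, seed = 8)
  # third positions only; first/second identical
  for (p in pairs[1:5]) {
    va <- rhizocontinuum:::encode_dna(p$cds_a)
    vb <- rhizocontinuum:::encode_dna(p$cds_b)
    i3 <- seq(3, length(va), by = 3)
    expect_identical(va[-i3], vb[-i3])
  }
  # realized third-position identity matches JC at d = 0.2
  pid <- mean(vapply(pairs, function(p) {
    va <- rhizocontinuum:::encode_dna(p$cds_a)
    vb <- rhizocontinuum:::encode_dna(p$cds_b)
    i3 <- seq(3, length(va), by = 3)
    mean(va[i3] == vb[i3])
  }, numeric(1)))
  expected <- 0.25 + 0.75 * exp(-4 * 0.2 / 3)
  expect_lt(abs(pid - expected), 0.01)
})
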