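# Fragment ANI engine: self-identity, JC69 agreement, random-pair behaviour,
# match registration, and binning.

test_that("self-comparison gives ANI 100 and near-complete coverage", {
  g <- mk_genome("s", rand_dna(120000, 1))
  r <- compute_ani(g, g)
  expect_equal(r$ani_pct, 100)
  expect_gte(r$gcov_pct, 99.9)
  expect_equal(r$n_fragments_retained, r$n_fragments_total)
})

test_that("ANI of a JC69 pair matches the closed form", {
  s <- rand_dna(150000, 2)
  g1 <- mk_genome("a", s)
  g2 <- mk_genome("b", jc_mutate(s, 0.02, seed = 3))
  r <- compute_ani(g1, g2)
  expect_lt(abs(r$ani_pct - jc_identity_pct(0.02)), 0.35)
  expect_gt(r$gcov_pct, 95)
})

test_that("unrelated sequences produce near-zero coverage", {
  g1 <- mk_genome("a", rand_dna(100000, 4))
  g2 <- mk_genome("b", rand_dna(100000, 5))
  r <- compute_ani(g1, g2)
  expect_lt(r$gcov_pct, 5)
})

test_that("fragment and input validation errors fire", {
  g <- mk_genome("a", rand_dna(5000, 6))
  expect_error(compute_ani(g, g, frag_len = 50), "frag_len")
  short <- mk_genome("s", rand_dna(700, 7))
  expect_warning(compute_ani(short, short), "single-fragment")
})

test_that("ani_matrix is symmetric with unit diagonal and flags failing pairs", {
  s <- rand_dna(60000, 8)
  gs <- list(mk_genome("g1", s), mk_genome("g2", s), mk_genome("g3", s))
  am <- ani_matrix(gs)
  expect_true(all(am$ani[upper.tri(am$ani)] == 100))
  expect_equal(am$ani, t(am$ani), tolerance = 1e-9)
  expect_equal(unname(diag(am$ani)), rep(100, 3))
  expect_error(ani_matrix(gs[1]), "at least 2")
})

test_that("a star tree yields equal pairwise ANI within tolerance", {
  cfg <- test_config(tree = "(gA:0.5,gB:0.5,gC:0.5,gD:0.5);",
                     subs_rate = 0.03, n_accessory_pool = 0, gain_rate = 0,
                     loss_rate = 0, chromosome_length = 60000, seed = 6)
  sim <- evolve_collection(cfg)
  am <- ani_matrix(sim$genomes)
  off <- am$ani[upper.tri(am$ani)]
  expect_lt(max(off) - min(off), 0.3)
})

test_that("register_matches finds whole, split, and absent homology", {
  p <- rand_dna(10000, 9)
  m <- register_matches(p, p)
  expect_equal(nrow(m), 1)
  expect_gte(m$length[1] / 10000, 0.99)
  expect_equal(m$pct_identity[1], 100)
  # 2 kb insertion splits the alignment in two
  ins <- paste0(substr(p, 1, 5000), rand_dna(2000, 10), substr(p, 5001, 10000))
  m2 <- register_matches(ins, p)
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$length > 4000))
  # unrelated sequences: nothing above 300 bp
  m3 <- register_matches(p, rand_dna(10000, 11))
  expect_equal(nrow(m3), 0)
  # reverse strand is searched
  m4 <- register_matches(revcomp(p), p)
  expect_equal(m4$strand[1], "-")
  expect_gte(m4$length[1] / 10000, 0.99)
})

test_that("ANI histogram bins half-open intervals and conserves counts", {
  h <- ani_histogram(c(95.0, 95.9, 97.1))
  expect_equal(h$count[h$bin_lo == 94], 2)
  expect_equal(h$count[h$bin_lo == 96], 1)
  h0 <- ani_histogram(numeric(0))
  expect_true(all(h0$count == 0))
  set.seed(1)
  v <- runif(200, 70, 99.9)
  expect_equal(sum(ani_histogram(v)$count), 200)
  expect_error(ani_histogram(c(95), bin_width = 0), "bin_width")
  expect_error(ani_histogram(c(101)), "0, 100")
})
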