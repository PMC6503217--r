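# Rep-protein extraction, family clustering, and whole-replicon conservation.

test_that("Rep extraction returns one protein per tagged plasmid and skips the chromosome", {
  sim <- sim_small()
  rp <- extract_rep_proteins(sim$genomes)
  n_plasmids <- sum(vapply(sim$genomes, function(g)
    sum(vapply(g$replicons, function(r) r$kind != "chromosome", logical(1))),
    numeric(1)))
  expect_equal(sum(rp$tag == "repC"), n_plasmids)
  expect_equal(sum(rp$tag == "repB"), n_plasmids)
  expect_false("chromosome" %in% rp$kind)
  # paralogous extra RepC copy is returned too
  g1 <- sim$genomes[[1]]
  pi <- which(vapply(g1$replicons, function(r) r$kind == "plasmid", logical(1)))[1]
  extra <- Filter(function(g) "repC" %in% g$role_tags, g1$replicons[[pi]]$genes)[[1]]
  extra$gene_id <- paste0(extra$gene_id, "_2")
  g1$replicons[[pi]]$genes <- c(g1$replicons[[pi]]$genes, list(extra))
  rp2 <- extract_rep_proteins(list(g1))
  expect_equal(sum(rp2$tag == "repC" & rp2$replicon_id == g1$replicons[[pi]]$replicon_id), 2)
})

test_that("independent Rep lineages cluster into their true families", {
  # 5 plasmid families x 4 genomes, each family an independent random protein
  set.seed(6)
  rows <- list()
  for (f in 1:5) {
    base <- rand_protein(180)
    for (g in 1:4) {
      v <- strsplit(base, "")[[1]]
      pos <- sample(180, 18)  # ~90% identity within family
      v[pos] <- sample(c("A","R","N","D","G"), 18, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%d_repC_F%d", g, f), genome_id = paste0("g", g),
        replicon_id = sprintf("g%d_p%d", g, f), kind = "plasmid", tag = "repC",
        protein = paste(v, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  rp <- do.call(rbind, rows)
  fc <- family_clusters(rp)
  expect_length(fc$families$repC, 5)
  truth <- sub(".*_F", "F", rp$gene_id)
  pred <- rep(NA_character_, nrow(rp))
  names(pred) <- rp$gene_id
  for (fam in names(fc$families$repC)) {
    pred[fc$families$repC[[fam]]] <- fam
  }
  expect_equal(ari(pred[rp$gene_id], truth), 1)
  # one family -> one cluster
  fc1 <- family_clusters(rp[truth == "F1", , drop = FALSE])
  expect_length(fc1$families$repC, 1)
})

test_that("RepC- and RepB-based assignments agree when both track the plasmid lineage", {
  sim <- sim_small()
  rp <- extract_rep_proteins(sim$genomes)
  fc <- family_clusters(rp, sim$genomes)
  a <- fc$assignments[!is.na(fc$assignments$repC_family), ]
  partC <- split(a$replicon_id, a$repC_family)
  partB <- split(a$replicon_id, a$repB_family)
  canon <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = "|"),
                                   character(1)))
  expect_equal(unname(canon(partC)), unname(canon(partB)))
  # chromosomes are reported unassigned
  chr <- fc$assignments[fc$assignments$kind == "chromosome", ]
  expect_true(all(is.na(chr$repC_family)))
})

test_that("replicon conservation separates within- from between-family pairs", {
  p <- rand_dna(20000, 31)
  expect_gte(replicon_conservation(p, p), 0.99)
  diverged <- jc_mutate(p, 0.02, seed = 32)
  expect_gt(replicon_conservation(p, diverged), 0.9)
  unrelated <- rand_dna(20000, 33)
  expect_lt(replicon_conservation(p, unrelated), 0.05)
})

test_that("within-family conservation exceeds between-family conservation on simulations", {
  sim <- sim_small()
  plasmids <- list()
  for (g in sim$genomes) for (r in g$replicons) {
    if (r$kind != "chromosome") plasmids[[r$replicon_id]] <- r
  }
  base_of <- function(id) sub("^g[0-9]+_", "", id)
  ids <- names(plasmids)[1:6]
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    cv <- replicon_conservation(plasmids[[ids[i]]], plasmids[[ids[j]]])
    if (base_of(ids[i]) == base_of(ids[j])) within <- c(within, cv)
    else between <- c(between, cv)
  }
  expect_gt(mean(within), mean(between))
})
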