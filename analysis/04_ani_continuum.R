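#!/usr/bin/env Rscript
# Stage 4: the ANI continuum and genomic clusters.
#
# Computes the pairwise ANI and genome-coverage matrices, joins them with the
# marker genetic distances, runs the Spearman correlation, bins ANI in 2%
# segments, smooths ANI against distance to locate the saturation asymptote,
# and calls genomic clusters at the ANI > 96% / Gcov > 90% rule.

suppressPackageStartupMessages(library(rhizocontinuum))
options(rhizocontinuum.verbose = TRUE)

col_dir <- "results/collection"
outdir <- "results/continuum"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genomes <- read_genome_collection(
  list.files(col_dir, pattern = "\\.fna$", full.names = TRUE),
  file.path(col_dir, "genes.tsv"))
kept <- readLines("results/filter/kept.txt")
genomes <- genomes[genome_ids(genomes) %in% kept]

am <- ani_matrix(genomes)
write_matrix(am$ani, file.path(outdir, "ani.tsv"))
write_matrix(am$gcov, file.path(outdir, "gcov.tsv"))
write.table(am$pairs, file.path(outdir, "ani_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gdist <- read_matrix("results/markers/genetic_distance.tsv")
pt <- pair_table(am$ani, am$gcov, gdist[rownames(am$ani), colnames(am$ani)])
write.table(pt, file.path(outdir, "pair_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sp_ani <- spearman_cor(pt$ani_pct, pt$genetic_distance)
sp_gcov <- spearman_cor(pt$gcov_pct, pt$genetic_distance)
sp_var <- spearman_cor(am$pairs$ani_pct, am$pairs$ani_weighted_pct)
cat(sprintf("Spearman rho (ANI vs genetic distance): %.3f (p = %.2e, n = %d pairs)\n",
            sp_ani$rho, sp_ani$p_value, sp_ani$n))
cat(sprintf("Spearman rho (Gcov vs genetic distance): %.3f\n", sp_gcov$rho))
cat(sprintf("Fragment-mean vs length-weighted ANI variant: rho = %.3f\n",
            sp_var$rho))

hist <- ani_histogram(pt$ani_pct, bin_width = 2, range = c(70, 100))
write.table(hist, file.path(outdir, "ani_histogram.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prof <- continuum_profile(pt, window = 0.005)
write.table(prof, file.path(outdir, "continuum_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cl <- call_clusters(am$ani, am$gcov, ani_min = 96, gcov_min = 90)
memb <- data.frame(genome_id = names(cl$membership), cluster = cl$membership)
write.table(memb, file.path(outdir, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Genomic clusters at ANI > 96 / Gcov > 90: %d (of which %d singletons).\n",
            length(cl$clusters), sum(lengths(cl$clusters) == 1)))
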