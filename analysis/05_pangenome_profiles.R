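#!/usr/bin/env Rscript
# Stage 5: consensus pangenome and symbiotic-gene profiles.
#
# Clusters all proteins by BDBH and by MCL, takes the consensus core
# (identical family in both, one copy per genome), builds the
# presence/absence matrix, fits the rarefaction curves (Heaps' law for the
# pangenome, exponential decay for the core), maps a symbiotic reference set
# onto the families, and orders the genome profiles by UPGMA on Bray-Curtis.

suppressPackageStartupMessages(library(rhizocontinuum))
options(rhizocontinuum.verbose = TRUE)

col_dir <- "results/collection"
outdir <- "results/pangenome"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genomes <- read_genome_collection(
  list.files(col_dir, pattern = "\\.fna$", full.names = TRUE),
  file.path(col_dir, "genes.tsv"))
kept <- readLines("results/filter/kept.txt")
genomes <- genomes[genome_ids(genomes) %in% kept]

gt <- gene_table(genomes)
proteomes <- split(setNames(gt$protein, gt$gene_id), gt$genome_id)
graph <- bdbh(proteomes, min_identity = 50, min_coverage = 50)
bfams <- bdbh_families(graph)
simg <- protein_similarity_graph(setNames(gt$protein, gt$gene_id))
mfams <- mcl_cluster(simg, inflation = 1.5)
fams <- family_table_from_clusters(mfams, graph$gene_genomes)
cc <- consensus_core(bfams, mfams, graph$gene_genomes, genome_ids(genomes))

write.table(fams, file.path(outdir, "families.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc, file.path(outdir, "consensus_core.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pa <- presence_absence(fams, genome_ids(genomes))
write.table(cbind(family_id = rownames(pa), as.data.frame(pa)),
            file.path(outdir, "presence_absence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pc <- pangenome_curves(pa, n_perm = 20, seed = 20260927L)
write.table(pc$medians, file.path(outdir, "rarefaction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
fits <- data.frame(parameter = c("K", "gamma", "A", "tau", "C"),
                   value = unlist(pc$fits))
write.table(fits, file.path(outdir, "curve_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# symbiotic reference set: the tagged symbiotic proteins of the first genome
# stand in for a curated nod/nif database
sym <- gt[grepl("symbiotic", gt$role_tags) & gt$genome_id == genome_ids(genomes)[1], ]
refs <- setNames(sym$protein, paste0("ref_", sym$family_truth))
profile <- map_symbiotic(fams, setNames(gt$protein, gt$gene_id),
                         setNames(gt$genome_id, gt$gene_id), refs,
                         genome_ids(genomes))
write.table(cbind(reference = rownames(profile), as.data.frame(profile)),
            file.path(outdir, "symbiotic_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

op <- order_profiles(pa)
ape::write.tree(op$tree, file.path(outdir, "profile_upgma.nwk"))
writeLines(op$order, file.path(outdir, "profile_order.txt"))

cat(sprintf("%d gene families (%d BDBH, %d MCL); consensus core: %d families.\n",
            length(mfams), length(bfams), length(mfams),
            length(unique(cc$family_id))))
cat(sprintf("Heaps' fit: pan(n) = %.1f * n^%.3f (gamma > 0 = open pangenome); core decay tau = %.2f.\n",
            pc$fits$K, pc$fits$gamma, pc$fits$tau))
cat(sprintf("Symbiotic references mapped: %d of %d non-redundant.\n",
            sum(rowSums(profile) > 0), nrow(profile)))
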