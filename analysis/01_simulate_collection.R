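#!/usr/bin/env Rscript
# Stage 1: simulate the study collection.
#
# Generates a 16-genome rhizobial-style collection: one 1 Mb chromosome per
# genome, a conserved plasmid and a symbiotic plasmid (nodABC/nifHDK analogs,
# RepC/RepB replication genes), 120 chromosomal core families of which 58 are
# ribosomal-protein analogs, an accessory pool of 200 families under
# gain/loss, and occasional wholesale psym transfer. Writes the collection as
# FASTA + gene table plus the ground truth under results/collection/.

suppressPackageStartupMessages(library(rhizocontinuum))
options(rhizocontinuum.verbose = TRUE)

outdir <- "results/collection"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genomes = 16, birth_rate = 1, subs_rate = 0.02,
                  psym_transfer_rate = 0.15, seed = 20260927L)
sim <- evolve_collection(cfg)

write_genome_collection(sim$genomes, outdir)
ape::write.tree(sim$truth$tree, file.path(outdir, "true_tree.nwk"))
write_matrix(sim$truth$true_pairwise_distance,
             file.path(outdir, "true_distances.tsv"))
write_matrix(sim$truth$psym_divergence,
             file.path(outdir, "true_psym_divergence.tsv"))
write.table(sim$truth$transfer_events,
            file.path(outdir, "transfer_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
pa <- sim$truth$family_table
write.table(cbind(family = rownames(pa), as.data.frame(pa + 0L)),
            file.path(outdir, "true_family_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genomes (%.1f Mb total), %d true families, %d psym transfer events.\n",
            length(sim$genomes),
            sum(vapply(sim$genomes, genome_length, numeric(1))) / 1e6,
            nrow(pa), nrow(sim$truth$transfer_events)))
cat("Outputs under", outdir, "\n")
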