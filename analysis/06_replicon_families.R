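#!/usr/bin/env Rscript
# Stage 6: plasmid/chromid families from Rep proteins.
#
# Extracts RepC and RepB proteins, clusters each set with MCL over the
# alignment-score similarity graph, assigns every plasmid its Rep family,
# builds per-family NJ trees, and quantifies whole-replicon conservation
# within and between families by registered matches > 300 bp.

suppressPackageStartupMessages(library(rhizocontinuum))
options(rhizocontinuum.verbose = TRUE)

col_dir <- "results/collection"
outdir <- "results/replicon_families"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genomes <- read_genome_collection(
  list.files(col_dir, pattern = "\\.fna$", full.names = TRUE),
  file.path(col_dir, "genes.tsv"))
kept <- readLines("results/filter/kept.txt")
genomes <- genomes[genome_ids(genomes) %in% kept]

rp <- extract_rep_proteins(genomes, tags = c("repC", "repB"))
fc <- family_clusters(rp, genomes, inflation = 1.5)

write.table(fc$assignments, file.path(outdir, "assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
wi <- data.frame(family = names(fc$within_identity),
                 mean_within_identity = fc$within_identity)
write.table(wi, file.path(outdir, "within_identity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (fam in names(fc$trees)) {
  if (!is.null(fc$trees[[fam]])) {
    ape::write.tree(fc$trees[[fam]], file.path(outdir, paste0(fam, ".nwk")))
  }
}

# whole-replicon conservation, within vs between RepC families
plasmids <- list()
for (g in genomes) for (r in g$replicons) {
  if (r$kind != "chromosome") plasmids[[r$replicon_id]] <- r
}
a <- fc$assignments[!is.na(fc$assignments$repC_family), ]
fam_of <- setNames(a$repC_family, a$replicon_id)
ids <- names(plasmids)
rows <- list()
set.seed(1)
samp <- ids[seq_len(min(10, length(ids)))]
for (i in seq_along(samp)) for (j in seq_along(samp)) {
  if (i >= j) next
  rows[[length(rows) + 1L]] <- data.frame(
    replicon_a = samp[i], replicon_b = samp[j],
    same_family = fam_of[[samp[i]]] == fam_of[[samp[j]]],
    conservation = replicon_conservation(plasmids[[samp[i]]],
                                         plasmids[[samp[j]]]))
}
cons <- do.call(rbind, rows)
write.table(cons, file.path(outdir, "replicon_conservation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("RepC proteins: %d in %d MCL clusters; RepB: %d in %d clusters.\n",
            sum(rp$tag == "repC"), length(fc$families$repC),
            sum(rp$tag == "repB"), length(fc$families$repB)))
cat(sprintf("Mean replicon conservation within families: %.2f, between: %.2f.\n",
            mean(cons$conservation[cons$same_family]),
            mean(cons$conservation[!cons$same_family])))
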