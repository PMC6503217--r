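# The hierarchical genome model every stage consumes:
# genome -> replicons -> genes. Plain S3 lists with constructors that
# validate the invariants. Coordinates are 0-based, half-open, on the
# forward strand; strand only affects CDS extraction.

REPLICON_KINDS <- c("chromosome", "chromid", "plasmid", "psym")

#' Create a gene record
#'
#' @param gene_id unique gene identifier (within its genome)
#' @param start,end 0-based half-open nucleotide coordinates on the replicon
#' @param strand "+" or "-" (affects CDS extraction only)
#' @param cds coding sequence (coding strand), length divisible by 3, or NULL
#' @param protein amino-acid sequence, or NULL (derived from `cds` if absent)
#' @param role_tags character vector of functional tags, e.g. "ribosomal",
#'   "symbiotic", "nodC", "repC"
#' @param family_truth true family label (simulator provenance), or NULL
#' @return a `gene_record` list
#' @export
gene_record <- function(gene_id, start, end, strand = "+", cds = NULL,
                        protein = NULL, role_tags = character(),
                        family_truth = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) {
    stop(sprintf("gene '%s': end (%d) must exceed start (%d)", gene_id, end, start))
  }
  if (!strand %in% c("+", "-")) stop(sprintf("gene '%s': bad strand", gene_id))
  if (!is.null(cds) && nchar(cds) %% 3L != 0L) {
    stop(sprintf("gene '%s': CDS length not divisible by 3", gene_id))
  }
  if (!is.null(cds) && is.null(protein)) protein <- translate_cds(cds)
  structure(list(gene_id = gene_id, start = start, end = end, strand = strand,
                 cds = cds, protein = protein,
                 role_tags = unique(as.character(role_tags)),
                 family_truth = family_truth),
            class = "gene_record")
}

#' Create a replicon record
#'
#' @param replicon_id unique replicon identifier
#' @param kind one of "chromosome", "chromid", "plasmid", "psym"
#' @param sequence DNA string
#' @param genes list of [gene_record()] objects located on this replicon
#' @return a `replicon_record` list
#' @export
replicon_record <- function(replicon_id, kind, sequence, genes = list()) {
  if (!kind %in% REPLICON_KINDS) {
    stop(sprintf("replicon '%s': unknown kind '%s'", replicon_id, kind))
  }
  len <- nchar(sequence)
  for (g in genes) {
    if (g$end > len) {
      stop(sprintf("gene '%s' extends beyond replicon '%s' (end %d > length %d)",
                   g$gene_id, replicon_id, g$end, len))
    }
  }
  structure(list(replicon_id = replicon_id, kind = kind,
                 sequence = sequence, genes = genes),
            class = "replicon_record")
}

#' Create a genome record
#'
#' @param genome_id unique genome identifier
#' @param status "complete" or "draft"
#' @param replicons list of [replicon_record()] objects; exactly one must be a
#'   chromosome, and any `psym` replicon must carry a gene tagged "nodC"
#' @return a `genome_record` list
#' @export
genome_record <- function(genome_id, status = "complete", replicons = list()) {
  if (!status %in% c("complete", "draft")) stop("status must be complete or draft")
  kinds <- vapply(replicons, function(r) r$kind, character(1))
  if (sum(kinds == "chromosome") != 1L) {
    stop(sprintf("genome '%s': needs exactly one chromosome (found %d)",
                 genome_id, sum(kinds == "chromosome")))
  }
  for (r in replicons) {
    if (r$kind == "psym") {
      tags <- unlist(lapply(r$genes, function(g) g$role_tags))
      if (!"nodC" %in% tags) {
        stop(sprintf("genome '%s': psym replicon '%s' lacks a nodC-tagged gene",
                     genome_id, r$replicon_id))
      }
    }
  }
  structure(list(genome_id = genome_id, status = status, replicons = replicons),
            class = "genome_record")
}

#' Total genome length (sum over replicons)
#' @param genome a `genome_record`
#' @return integer, base pairs
#' @export
genome_length <- function(genome) {
  sum(vapply(genome$replicons, function(r) nchar(r$sequence), numeric(1)))
}

#' Extract the CDS of a gene from its replicon sequence
#' @param replicon a `replicon_record`
#' @param gene a `gene_record` on that replicon
#' @return DNA string (coding strand)
#' @export
gene_cds <- function(replicon, gene) {
  s <- substr(replicon$sequence, gene$start + 1L, gene$end)
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Flat gene table of a genome collection
#'
#' One row per gene with its genome, replicon, replicon kind, coordinates,
#' tags, CDS and protein; the form consumed by the homology, pangenome and Ks
#' stages.
#' @param genomes list of `genome_record`s
#' @return data.frame
#' @export
gene_table <- function(genomes) {
  rows <- list()
  for (g in genomes) {
    for (r in g$replicons) {
      for (gene in r$genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene$gene_id, genome_id = g$genome_id,
          replicon_id = r$replicon_id, kind = r$kind,
          start = gene$start, end = gene$end, strand = gene$strand,
          role_tags = paste(gene$role_tags, collapse = ","),
          family_truth = if (is.null(gene$family_truth)) NA_character_ else gene$family_truth,
          cds = if (is.null(gene$cds)) gene_cds(r, gene) else gene$cds,
          protein = if (is.null(gene$protein)) translate_cds(gene_cds(r, gene)) else gene$protein,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), genome_id = character(),
                      replicon_id = character(), kind = character(),
                      start = integer(), end = integer(), strand = character(),
                      role_tags = character(), family_truth = character(),
                      cds = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genome ids of a collection
#' @param genomes list of `genome_record`s
#' @return character vector
#' @export
genome_ids <- function(genomes) {
  vapply(genomes, function(g) g$genome_id, character(1))
}

# does any gene in the genome carry this tag?
.genome_tags <- function(genome) {
  unique(unlist(lapply(genome$replicons, function(r)
    lapply(r$genes, function(g) g$role_tags))))
}
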