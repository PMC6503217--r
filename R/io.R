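# On-disk formats: nucleotide FASTA (one file per genome, one record per
# replicon, key=value header tokens), a gene table TSV, label-indexed TSV
# matrices, and Newick trees (via ape at the call sites).

#' Write a genome collection to FASTA files plus one gene table
#'
#' Each genome becomes `<genome_id>.fna` with one record per replicon; headers
#' carry `genome=`, `replicon=`, `kind=` and `status=` tokens. All genes go to
#' `genes.tsv` (columns gene_id, genome_id, replicon_id, start, end, strand,
#' role_tags, cds, and family_truth where simulator provenance exists).
#' @param genomes list of `genome_record`s
#' @param dir output directory (created if needed)
#' @return invisibly, a list with `fasta` paths and the `gene_table` path
#' @export
write_genome_collection <- function(genomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta_paths <- character(0)
  for (g in genomes) {
    seqs <- vapply(g$replicons, function(r) r$sequence, character(1))
    names(seqs) <- vapply(g$replicons, function(r)
      sprintf("%s genome=%s replicon=%s kind=%s status=%s",
              r$replicon_id, g$genome_id, r$replicon_id, r$kind, g$status),
      character(1))
    path <- file.path(dir, paste0(g$genome_id, ".fna"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    fasta_paths <- c(fasta_paths, path)
  }
  gt <- gene_table(genomes)
  gt <- gt[, c("gene_id", "genome_id", "replicon_id", "start", "end",
               "strand", "role_tags", "cds", "family_truth")]
  gt_path <- file.path(dir, "genes.tsv")
  write.table(gt, gt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_paths, gene_table = gt_path))
}

.parse_header_token <- function(headers, key) {
  m <- regmatches(headers, regexpr(sprintf("%s=[^ ]+", key), headers))
  has <- grepl(sprintf("%s=", key), headers)
  out <- rep(NA_character_, length(headers))
  out[has] <- sub(sprintf("^%s=", key), "", m)
  out
}

#' Read a genome collection from FASTA files and a gene table
#'
#' @param paths character vector of nucleotide FASTA paths (one per genome;
#'   headers may carry `genome=`, `replicon=`, `kind=`, `status=` tokens —
#'   missing tokens default to the file name, the record name, "chromosome"
#'   for the first record / "plasmid" otherwise, and "complete")
#' @param gene_table path to the gene TSV (columns gene_id, genome_id,
#'   replicon_id, start, end, strand, role_tags, optional cds), or NULL for a
#'   gene-less collection
#' @return list of `genome_record`s ordered by genome_id
#' @export
read_genome_collection <- function(paths, gene_table = NULL) {
  genes <- NULL
  if (!is.null(gene_table)) {
    genes <- read.delim(gene_table, sep = "\t", stringsAsFactors = FALSE,
                        colClasses = "character")
    if (nrow(genes) > 0) {
      genes$start <- as.integer(genes$start)
      genes$end <- as.integer(genes$end)
      bad <- which(genes$end <= genes$start)
      if (length(bad) > 0) {
        stop(sprintf("gene table row %d (gene '%s'): end <= start",
                     bad[1], genes$gene_id[bad[1]]))
      }
    }
  }
  genomes <- list()
  for (path in paths) {
    ss <- Biostrings::readDNAStringSet(path)
    headers <- names(ss)
    rid <- .parse_header_token(headers, "replicon")
    rid[is.na(rid)] <- vapply(strsplit(headers[is.na(rid)], " "), `[`, character(1), 1)
    gid <- .parse_header_token(headers, "genome")
    gid[is.na(gid)] <- sub("\\.(fa|fna|fasta)$", "", basename(path))
    kind <- .parse_header_token(headers, "kind")
    kind[is.na(kind)] <- c("chromosome", rep("plasmid", length(headers) - 1))[is.na(kind)]
    status <- .parse_header_token(headers, "status")
    status[is.na(status)] <- "complete"
    if (length(unique(gid)) != 1L) {
      stop(sprintf("file '%s': records belong to several genomes", path))
    }
    genome_id <- gid[1]
    if (genome_id %in% vapply(genomes, function(g) g$genome_id, character(1))) {
      stop(sprintf("duplicate genome_id '%s'", genome_id))
    }
    replicons <- list()
    for (i in seq_along(ss)) {
      seq_i <- as.character(ss[[i]])
      gl <- list()
      if (!is.null(genes) && nrow(genes) > 0) {
        sel <- genes[genes$genome_id == genome_id & genes$replicon_id == rid[i], ,
                     drop = FALSE]
        for (j in seq_len(nrow(sel))) {
          if (sel$end[j] > nchar(seq_i)) {
            stop(sprintf("gene '%s' outside replicon '%s' (end %d > length %d)",
                         sel$gene_id[j], rid[i], sel$end[j], nchar(seq_i)))
          }
          tags <- if (is.na(sel$role_tags[j]) || sel$role_tags[j] == "") character() else
            strsplit(sel$role_tags[j], ",", fixed = TRUE)[[1]]
          cds <- if ("cds" %in% names(sel) && !is.na(sel$cds[j]) && nzchar(sel$cds[j]))
            sel$cds[j] else NULL
          fam <- if ("family_truth" %in% names(sel) && !is.na(sel$family_truth[j]) &&
                     nzchar(sel$family_truth[j])) sel$family_truth[j] else NULL
          gl[[length(gl) + 1L]] <- gene_record(
            sel$gene_id[j], sel$start[j], sel$end[j], sel$strand[j],
            cds = cds, role_tags = tags, family_truth = fam)
        }
      }
      replicons[[length(replicons) + 1L]] <-
        replicon_record(rid[i], kind[i], seq_i, gl)
    }
    genomes[[length(genomes) + 1L]] <-
      genome_record(genome_id, status[1], replicons)
  }
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  genomes <- genomes[order(ids)]
  rc_log("read %d genomes (%d replicons, %d genes)", length(genomes),
         sum(vapply(genomes, function(g) length(g$replicons), numeric(1))),
         sum(vapply(genomes, function(g)
           sum(vapply(g$replicons, function(r) length(r$genes), numeric(1))), numeric(1))))
  genomes
}

#' Write a symmetric label-indexed matrix as TSV
#'
#' Header row/column of labels, values at fixed precision (6 decimals);
#' re-readable bit-identically with [read_matrix()].
#' @param m symmetric numeric matrix with identical row/column names
#' @param path output TSV path
#' @param saturated_ok allow NA/NaN entries (flagged saturated pairs)
#' @return invisibly, `path`
#' @export
write_matrix <- function(m, path, saturated_ok = FALSE) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE))) {
    stop("matrix is not symmetric")
  }
  if (any(!is.finite(m)) && !saturated_ok) {
    stop("matrix has non-finite entries; use saturated_ok = TRUE to keep them")
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(m)))
  out <- cbind(label = labels,
               matrix(sprintf("%.6f", m), nrow(m), ncol(m)))
  out[out == "NA" | out == "NaN"] <- "NA"
  colnames(out) <- c("label", labels)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path TSV path
#' @return numeric matrix with dimnames
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  labels <- as.character(df$label)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  m
}
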