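# Genome inclusion criteria: symbiotic marker genes must be present and
# draft assemblies must exceed a minimum total length (complete genomes pass
# the length rule by virtue of completeness).

#' Filter a genome collection by symbiotic-gene content and draft length
#'
#' A genome is kept iff it carries every tag in `required_tags` and, when its
#' status is "draft", its total length strictly exceeds `min_draft_length`.
#' @param genomes list of `genome_record`s (role tags populated)
#' @param min_draft_length minimum total length for drafts, bp (default 6 Mb)
#' @param required_tags role tags every genome must carry (default the
#'   nodulation and nitrogenase structural gene set nodABC + nifHDK)
#' @return a `filter_report`: list with `kept` (genome ids), `excluded`
#'   (data.frame genome_id, reason) and the thresholds used
#' @export
filter_collection <- function(genomes, min_draft_length = 6e6,
                              required_tags = c("nodA", "nodB", "nodC",
                                                "nifH", "nifD", "nifK")) {
  if (length(genomes) == 0L) stop("empty collection")
  kept <- character(0)
  excl <- list()
  for (g in genomes) {
    tags <- .genome_tags(g)
    missing <- setdiff(required_tags, tags)
    len <- genome_length(g)
    if (length(missing) > 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        genome_id = g$genome_id,
        reason = paste0("missing:", paste(missing, collapse = ",")),
        stringsAsFactors = FALSE)
    } else if (g$status == "draft" && len <= min_draft_length) {
      excl[[length(excl) + 1L]] <- data.frame(
        genome_id = g$genome_id, reason = "length", stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, g$genome_id)
    }
  }
  excluded <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(genome_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rc_log("filter: %d in, %d kept, %d excluded (min_draft_length=%g)",
         length(genomes), length(kept), nrow(excluded), min_draft_length)
  structure(list(kept = kept, excluded = excluded,
                 min_draft_length = min_draft_length,
                 required_tags = required_tags),
            class = "filter_report")
}
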