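# Whole-genome average nucleotide identity (ANI) and genome coverage, by the
# fragment scheme of JSpecies-style ANIb: the query is cut into fixed windows,
# each window is placed at its best seeded location in the target and aligned
# with a banded local alignment; fragments passing the identity/coverage gate
# contribute to the mean. A match-length-weighted variant ("anim-like") is
# reported alongside for robustness checks.

.encode_replicons <- function(genome) {
  lapply(genome$replicons, function(r) encode_dna(r$sequence))
}

#' Pairwise ANI and genome coverage between two genomes
#'
#' Directed values for (a vs b) and (b vs a) plus their mean, the symmetric
#' value used downstream. Fragments are retained when their alignment reaches
#' `min_frag_identity` percent identity over at least `min_frag_aln_cov`
#' percent of the fragment; `ani_pct` is the plain mean identity of retained
#' fragments and `ani_weighted_pct` the alignment-length-weighted mean.
#' Coverage (`gcov_pct`) is the retained fragment length over the query
#' length. Fragments never cross replicon boundaries.
#'
#' @param a,b `genome_record`s
#' @param frag_len fragment window, bp
#' @param min_frag_identity percent identity gate
#' @param min_frag_aln_cov percent-of-fragment-aligned gate
#' @param k seed k-mer size
#' @param band alignment band half-width, bp
#' @param min_seeds minimum seed k-mers on the best diagonal before a fragment
#'   is aligned at all
#' @return an `ani_result`: list with genome ids, directed and symmetric
#'   ANI/coverage, and fragment counts
#' @export
compute_ani <- function(a, b, frag_len = 1020, min_frag_identity = 30,
                        min_frag_aln_cov = 70, k = 15, band = 32,
                        min_seeds = 2) {
  if (frag_len < 100) stop("frag_len must be >= 100")
  if (genome_length(a) == 0 || genome_length(b) == 0) stop("empty genome")
  if (genome_length(a) < frag_len || genome_length(b) < frag_len) {
    warning("genome shorter than one fragment; single-fragment mode")
  }
  ea <- .encode_replicons(a); eb <- .encode_replicons(b)
  dir_ab <- .ani_directed(ea, eb, frag_len, min_frag_identity,
                          min_frag_aln_cov, k, band, min_seeds)
  dir_ba <- .ani_directed(eb, ea, frag_len, min_frag_identity,
                          min_frag_aln_cov, k, band, min_seeds)
  structure(list(
    genome_a = a$genome_id, genome_b = b$genome_id,
    ani_pct = mean(c(dir_ab$ani, dir_ba$ani)),
    gcov_pct = mean(c(dir_ab$gcov, dir_ba$gcov)),
    ani_weighted_pct = mean(c(dir_ab$ani_w, dir_ba$ani_w)),
    directed = data.frame(
      query = c(a$genome_id, b$genome_id),
      target = c(b$genome_id, a$genome_id),
      ani_pct = c(dir_ab$ani, dir_ba$ani),
      gcov_pct = c(dir_ab$gcov, dir_ba$gcov),
      stringsAsFactors = FALSE),
    n_fragments_total = dir_ab$n_total + dir_ba$n_total,
    n_fragments_retained = dir_ab$n_ret + dir_ba$n_ret),
    class = "ani_result")
}

.ani_directed <- function(eq, et, frag_len, min_id, min_cov, k, band,
                          min_seeds) {
  fr <- .cpp_ani_fragments(eq, et, as.integer(frag_len), as.integer(k),
                           as.integer(band), as.integer(min_seeds), 100L)
  ok <- !is.na(fr$pct_identity) & fr$pct_identity >= min_id &
    fr$frag_cov >= min_cov
  total_len <- sum(vapply(eq, length, numeric(1)))
  list(ani = if (any(ok)) mean(fr$pct_identity[ok]) else NA_real_,
       ani_w = if (any(ok))
         sum(fr$pct_identity[ok] * fr$align_len[ok]) / sum(fr$align_len[ok])
       else NA_real_,
       gcov = 100 * sum(fr$frag_len[ok]) / total_len,
       n_total = nrow(fr), n_ret = sum(ok))
}

#' ANI and coverage matrices over a collection
#'
#' Symmetric pair-mean matrices with a diagonal of 100.
#' @param genomes list of `genome_record`s (>= 2)
#' @param ... passed to [compute_ani()]
#' @return list with `ani`, `gcov` and `ani_weighted` matrices and the long
#'   pair table `pairs`
#' @export
ani_matrix <- function(genomes, ...) {
  n <- length(genomes)
  if (n < 2) stop("need at least 2 genomes")
  ids <- genome_ids(genomes)
  ani <- gcov <- aniw <- matrix(100, n, n, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- tryCatch(compute_ani(genomes[[i]], genomes[[j]], ...),
                    error = function(e)
                      stop(sprintf("pair (%s, %s): %s", ids[i], ids[j],
                                   conditionMessage(e))))
      ani[i, j] <- ani[j, i] <- r$ani_pct
      gcov[i, j] <- gcov[j, i] <- r$gcov_pct
      aniw[i, j] <- aniw[j, i] <- r$ani_weighted_pct
      pairs[[length(pairs) + 1L]] <- data.frame(
        genome_a = ids[i], genome_b = ids[j], ani_pct = r$ani_pct,
        gcov_pct = r$gcov_pct, ani_weighted_pct = r$ani_weighted_pct,
        stringsAsFactors = FALSE)
    }
  }
  rc_log("ani_matrix: %d genomes, %d pairs", n, length(pairs))
  list(ani = ani, gcov = gcov, ani_weighted = aniw,
       pairs = do.call(rbind, pairs))
}

#' Register local matches between two replicons
#'
#' Seeded local alignments on both strands with aligned length strictly
#' greater than `min_match_len`, sorted by start on `a`. Coordinates are
#' 0-based half-open on the forward strand of each replicon.
#' @param replicon_a,replicon_b `replicon_record`s (or DNA strings)
#' @param min_match_len minimum alignment length, bp
#' @param k seed k-mer size
#' @param band alignment band half-width
#' @return data.frame (start_a, end_a, start_b, end_b, pct_identity, length,
#'   strand)
#' @export
register_matches <- function(replicon_a, replicon_b, min_match_len = 300,
                             k = 15, band = 32) {
  sa <- if (is.character(replicon_a)) replicon_a else replicon_a$sequence
  sb <- if (is.character(replicon_b)) replicon_b else replicon_b$sequence
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty sequence")
  m <- .cpp_register_matches(encode_dna(sa), encode_dna(sb), as.integer(k),
                             as.integer(band), as.integer(min_match_len),
                             1000L)
  m[order(m$start_a), , drop = FALSE]
}

#' Histogram of pairwise ANI values in fixed-width bins
#'
#' @param values pairwise ANI percentages
#' @param bin_width bin width in percentage points
#' @param range two-element numeric, binning range (half-open bins
#'   `[lo, lo + bin_width)`; values outside the range are dropped with a
#'   warning)
#' @return data.frame (bin_lo, bin_hi, count)
#' @export
ani_histogram <- function(values, bin_width = 2, range = c(70, 100)) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(values < 0 | values > 100)) stop("ANI values must lie in [0, 100]")
  lo <- seq(range[1], range[2] - bin_width, by = bin_width)
  hi <- lo + bin_width
  outside <- sum(values < range[1] | values >= range[2])
  if (outside > 0) warning(sprintf("%d values outside binning range", outside))
  counts <- vapply(seq_along(lo), function(i)
    sum(values >= lo[i] & values < hi[i]), numeric(1))
  data.frame(bin_lo = lo, bin_hi = hi, count = counts)
}
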