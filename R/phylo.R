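# Marker phylogenetics: universal single-copy marker extraction, alignment
# trimming, corrected pairwise protein distances, neighbor-joining trees,
# Robinson-Foulds distances, and congruence-based marker filtering.

#' Extract universal single-copy markers from a collection
#'
#' Candidate genes are those carrying `role_tag`. When true family labels are
#' available (simulated data) genes are grouped by them; otherwise families
#' are built by BDBH at the marker gates (identity and coverage of the largest
#' protein). Markers missing from any genome, or multi-copy in any genome, are
#' dropped (and logged).
#' @param genomes list of `genome_record`s
#' @param role_tag tag of the marker genes
#' @param min_identity,min_cov_largest marker homology gates (percent; the
#'   coverage is of the larger protein)
#' @return list of `marker_alignment`s: each a list(family_id, seqs = named
#'   character vector genome -> protein, cds = genome -> CDS)
#' @export
extract_markers <- function(genomes, role_tag = "ribosomal",
                            min_identity = 60, min_cov_largest = 60) {
  gt <- gene_table(genomes)
  sel <- gt[vapply(strsplit(gt$role_tags, ","), function(tags)
    role_tag %in% tags, logical(1)), , drop = FALSE]
  if (nrow(sel) == 0) stop("no genes carry the marker tag")
  ids <- genome_ids(genomes)
  if (all(!is.na(sel$family_truth))) {
    groups <- split(seq_len(nrow(sel)), sel$family_truth)
  } else {
    prot <- split(setNames(sel$protein, sel$gene_id), sel$genome_id)
    fams <- bdbh_families(bdbh(prot, min_identity, min_cov_largest,
                               cov_of_largest = TRUE))
    gidx <- setNames(seq_len(nrow(sel)), sel$gene_id)
    groups <- lapply(fams, function(f) unname(gidx[f]))
    names(groups) <- vapply(fams, `[`, character(1), 1)
  }
  markers <- list()
  dropped <- 0L
  for (fam in sort(names(groups))) {
    rows <- sel[groups[[fam]], , drop = FALSE]
    if (anyDuplicated(rows$genome_id) > 0 || !setequal(rows$genome_id, ids)) {
      dropped <- dropped + 1L
      next
    }
    ord <- order(rows$genome_id)
    markers[[length(markers) + 1L]] <- structure(
      list(family_id = fam,
           seqs = setNames(rows$protein[ord], rows$genome_id[ord]),
           cds = setNames(rows$cds[ord], rows$genome_id[ord])),
      class = "marker_alignment")
  }
  rc_log("extract_markers: %d candidate families, %d universal single-copy, %d dropped",
         length(groups), length(markers), dropped)
  if (length(markers) == 0) stop("no universal single-copy markers")
  markers
}

.marker_matrix <- function(marker) {
  lens <- nchar(marker$seqs)
  if (length(unique(lens)) != 1) {
    stop(sprintf("marker '%s': rows differ in length; supply pre-aligned sequences",
                 marker$family_id))
  }
  do.call(rbind, lapply(marker$seqs, function(s) strsplit(s, "")[[1]]))
}

#' Remove alignment columns containing gaps or missing data
#'
#' `complete-deletion` removes every column containing any of `-`, `.`, `X`,
#' `*` or `?`; mode `gap-fraction` keeps columns whose gap fraction is at most
#' `max_gap_frac`.
#' @param aln a `marker_alignment` (equal-length rows)
#' @param mode "complete-deletion" or "gap-fraction"
#' @param max_gap_frac tolerated gap fraction for mode "gap-fraction"
#' @return the trimmed `marker_alignment` with attribute `kept_columns`
#' @export
trim_columns <- function(aln, mode = c("complete-deletion", "gap-fraction"),
                         max_gap_frac = 0.2) {
  mode <- match.arg(mode)
  m <- .marker_matrix(aln)
  bad <- m %in% c("-", ".", "X", "*", "?")
  dim(bad) <- dim(m)
  keep <- if (mode == "complete-deletion") colSums(bad) == 0 else
    colMeans(bad) <= max_gap_frac
  if (!any(keep)) stop(sprintf("marker '%s': all columns removed", aln$family_id))
  m2 <- m[, keep, drop = FALSE]
  aln$seqs <- setNames(apply(m2, 1, paste, collapse = ""), rownames(m))
  attr(aln, "kept_columns") <- which(keep)
  aln
}

#' Concatenate marker alignments into a supermatrix
#' @param markers list of `marker_alignment`s over the same genomes
#' @return a `supermatrix`: list(seqs = named character vector, map =
#'   data.frame(family_id, start, end) 1-based column ranges)
#' @export
concat_markers <- function(markers) {
  if (length(markers) == 0) stop("no markers to concatenate")
  ids <- sort(names(markers[[1]]$seqs))
  pos <- 0L
  map <- list()
  parts <- matrix("", length(ids), length(markers), dimnames = list(ids, NULL))
  for (i in seq_along(markers)) {
    s <- markers[[i]]$seqs[ids]
    if (any(is.na(s))) stop("markers cover different genome sets")
    parts[, i] <- s
    w <- nchar(s[[1]])
    map[[i]] <- data.frame(family_id = markers[[i]]$family_id,
                           start = pos + 1L, end = pos + w,
                           stringsAsFactors = FALSE)
    pos <- pos + w
  }
  structure(list(seqs = setNames(apply(parts, 1, paste, collapse = ""), ids),
                 map = do.call(rbind, map)),
            class = "supermatrix")
}

#' Corrected pairwise distances from a protein supermatrix
#'
#' p is the fraction of differing sites per pair; `poisson` corrects as
#' d = -ln(1 - p), `kimura-protein` as d = -ln(1 - p - p^2/5). Saturated
#' pairs (correction argument <= 0) are set NA and flagged.
#' @param sm a `supermatrix` (or a named character vector of equal-length
#'   sequences)
#' @param model "poisson" or "kimura-protein"
#' @return `DistanceMatrix`: symmetric numeric matrix, attribute `saturated`
#'   (logical matrix)
#' @export
pairwise_distance <- function(sm, model = c("poisson", "kimura-protein")) {
  model <- match.arg(model)
  seqs <- if (inherits(sm, "supermatrix")) sm$seqs else sm
  L <- unique(nchar(seqs))
  if (length(L) != 1 || L == 0) stop("sequences empty or of unequal length")
  ids <- names(seqs)
  chars <- do.call(rbind, lapply(seqs, function(s) utf8ToInt(s)))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- mean(chars[i, ] != chars[j, ])
      arg <- if (model == "poisson") 1 - p else 1 - p - p^2 / 5
      if (arg <= 0) {
        d[i, j] <- d[j, i] <- NA_real_
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -log(arg)
      }
    }
  }
  attr(d, "saturated") <- sat
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard NJ on a symmetric distance matrix. Joins are chosen by the
#' Q-criterion with ties broken by the lexicographically smallest label pair.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sister edge, preserving path lengths.
#' @param d symmetric numeric matrix with dimnames (>= 3 labels, finite)
#' @return unrooted `phylo`
#' @export
nj_tree <- function(d) {
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop("need at least 3 labels")
  D <- d
  frag <- setNames(labels, labels)  # newick fragment per active node
  act <- sort(labels)
  join_k <- 0L
  while (length(act) > 3) {
    m <- length(act)
    Da <- D[act, act]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    pairs <- t(apply(cand, 1, function(ij) sort(c(act[ij[1]], act[ij[2]]))))
    pick <- order(pairs[, 1], pairs[, 2])[1]
    a <- pairs[pick, 1]; b <- pairs[pick, 2]
    la <- 0.5 * Da[a, b] + (r[a] - r[b]) / (2 * (m - 2))
    lb <- Da[a, b] - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    u <- paste0("(", frag[a], ":", sprintf("%.10f", la), ",",
                frag[b], ":", sprintf("%.10f", lb), ")")
    rest <- setdiff(act, c(a, b))
    Du <- (Da[a, rest] + Da[b, rest] - Da[a, b]) / 2
    join_k <- join_k + 1L
    ulab <- paste0("\x01u", join_k)
    D2 <- matrix(0, length(rest) + 1L, length(rest) + 1L,
                 dimnames = list(c(rest, ulab), c(rest, ulab)))
    D2[rest, rest] <- Da[rest, rest]
    D2[ulab, rest] <- Du; D2[rest, ulab] <- Du
    D <- D2
    frag[ulab] <- u
    act <- sort(c(rest, ulab))
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  if (la < 0) { lb <- lb + la; lc <- lc + la; la <- 0 }
  if (lb < 0) { la <- la + lb; lc <- lc + lb; lb <- 0 }
  if (lc < 0) { la <- la + lc; lb <- lb + lc; lc <- 0 }
  nwk <- paste0("(", frag[a], ":", sprintf("%.10f", la), ",",
                frag[b], ":", sprintf("%.10f", lb), ",",
                frag[c3], ":", sprintf("%.10f", lc), ");")
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions of an unrooted tree as canonical strings
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntips <- length(tips)
  desc <- .descendant_leaves(tree)
  ref <- tips[1]
  out <- character(0)
  internal <- tree$edge[, 2] > length(tree$tip.label)
  for (e in which(internal)) {
    side <- sort(desc[[tree$edge[e, 2]]])
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= ntips - 2) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees; multifurcations are allowed.
#' @param t1,t2 `phylo` objects on the same leaf set
#' @return integer RF distance
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees have different leaf sets")
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Congruence-based marker filtering and supermatrix construction
#'
#' Computes an NJ tree per marker and the majority-rule consensus of all
#' marker trees; markers whose RF distance to the consensus exceeds the
#' `max_rf_quantile` quantile of all marker RF values are dropped (a
#' recombination/transfer screen), and the survivors are concatenated.
#' @param markers list of `marker_alignment`s (>= 4 genomes)
#' @param max_rf_quantile drop markers above this RF quantile (strict >)
#' @param min_len minimum marker length in columns
#' @param model distance model for the per-marker trees
#' @return list with `retained` (marker list), `dropped` (family ids), `rf`
#'   (named RF values), `consensus` (phylo) and `supermatrix`
#' @export
filter_markers <- function(markers, max_rf_quantile = 0.75, min_len = 50,
                           model = "poisson") {
  long <- markers[vapply(markers, function(m) nchar(m$seqs[[1]]) >= min_len,
                         logical(1))]
  if (length(long) < 3) stop("fewer than 3 markers pass the length filter")
  trees <- lapply(long, function(m) {
    d <- pairwise_distance(m$seqs, model)
    if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)]) * 1.5
    nj_tree(d)
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  rf <- vapply(trees, function(t) rf_distance(t, cons), numeric(1))
  names(rf) <- vapply(long, function(m) m$family_id, character(1))
  thr <- quantile(rf, max_rf_quantile, names = FALSE, type = 7)
  keep <- rf <= thr
  if (sum(keep) < 3) stop("fewer than 3 markers survive the congruence filter")
  rc_log("filter_markers: %d markers, RF threshold %.2f, %d retained, %d dropped",
         length(long), thr, sum(keep), sum(!keep))
  list(retained = long[keep], dropped = names(rf)[!keep], rf = rf,
       consensus = cons, supermatrix = concat_markers(long[keep]))
}
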