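# Continuum-vs-cluster diagnostics: rank correlations between ANI/coverage
# and genetic distance, threshold-based genomic cluster calling, and smoothed
# ANI-vs-distance profiles with saturation flagging.

#' Spearman rank correlation with tie correction
#'
#' rho is the Pearson correlation of average ranks. The p-value uses the t
#' approximation with n - 2 degrees of freedom, or the exact permutation
#' distribution (all n! orderings, two-sided on |rho|) for n <= 10 when
#' `exact = TRUE`.
#' @param x,y equal-length numeric vectors (n >= 3)
#' @param exact use the exact permutation p-value (n <= 10 only)
#' @return list(rho, p_value, n, method)
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p-value limited to n <= 10")
    p <- .cpp_spearman_perm(rx, ry)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Pair table joining ANI, coverage and genetic distance
#' @param ani,gcov symmetric percentage matrices
#' @param gdist symmetric genetic-distance matrix (substitutions/site)
#' @return data.frame, one row per unordered pair
#' @export
pair_table <- function(ani, gcov, gdist) {
  ids <- rownames(ani)
  stopifnot(identical(ids, rownames(gcov)), identical(ids, rownames(gdist)))
  idx <- which(upper.tri(ani), arr.ind = TRUE)
  data.frame(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
             ani_pct = ani[idx], gcov_pct = gcov[idx],
             genetic_distance = gdist[idx], stringsAsFactors = FALSE)
}

#' Call genomic clusters by ANI and coverage thresholds
#'
#' An edge joins every pair strictly exceeding both thresholds; clusters are
#' the connected components (single linkage). Singletons are reported.
#' @param ani,gcov symmetric percentage matrices on the same labels
#' @param ani_min,gcov_min thresholds in percent (strict >)
#' @param linkage "single" (components) or "complete" (maximal cliques are
#'   not enumerated; complete linkage is approximated by hierarchical
#'   clustering cut at the thresholds) - single linkage is the default and
#'   the convention used throughout
#' @return a `cluster_call`: list(membership = named integer vector,
#'   clusters = list of genome-id vectors, ani_min, gcov_min)
#' @export
call_clusters <- function(ani, gcov, ani_min = 96, gcov_min = 90,
                          linkage = "single") {
  if (ani_min < 0 || ani_min > 100 || gcov_min < 0 || gcov_min > 100) {
    stop("thresholds must lie in [0, 100]")
  }
  ids <- rownames(ani)
  stopifnot(identical(ids, rownames(gcov)))
  adj <- ani > ani_min & gcov > gcov_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1))]
  names(clusters) <- sprintf("GC%03d", seq_along(clusters))
  membership <- setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  rc_log("call_clusters: %d genomes -> %d clusters (%d singletons) at ANI>%g, Gcov>%g",
         length(ids), length(clusters),
         sum(lengths(clusters) == 1), ani_min, gcov_min)
  structure(list(membership = membership, clusters = clusters,
                 ani_min = ani_min, gcov_min = gcov_min),
            class = "cluster_call")
}

#' Smoothed ANI-versus-distance continuum profile
#'
#' Sliding-window mean ANI along genetic distance (window centres every half
#' window). The local slope is estimated by first differences of the smoothed
#' curve; windows where |slope| falls below 10% of the initial slope magnitude
#' are flagged saturated (the asymptote of the continuum).
#' @param pairs data.frame with columns `ani_pct` and `genetic_distance`
#'   (>= 10 pairs)
#' @param window window width in distance units
#' @return data.frame (center, mean_ani, n_pairs, slope, saturated)
#' @export
continuum_profile <- function(pairs, window = 0.005) {
  if (window <= 0) stop("window must be positive")
  if (nrow(pairs) < 10) stop("need at least 10 pairs")
  d <- pairs$genetic_distance
  centers <- seq(min(d), max(d), by = window / 2)
  rows <- lapply(centers, function(cc) {
    sel <- d >= cc - window / 2 & d < cc + window / 2
    data.frame(center = cc,
               mean_ani = if (any(sel)) mean(pairs$ani_pct[sel]) else NA_real_,
               n_pairs = sum(sel))
  })
  prof <- do.call(rbind, rows)
  prof <- prof[!is.na(prof$mean_ani), , drop = FALSE]
  slope <- c(NA, diff(prof$mean_ani) / diff(prof$center))
  slope[!is.finite(slope)] <- NA
  init <- abs(slope[which(!is.na(slope))[1]])
  if (!is.na(init) && init == 0) init <- NA
  prof$slope <- slope
  prof$saturated <- if (is.na(init)) rep(TRUE, nrow(prof)) else
    !is.na(slope) & abs(slope) < 0.1 * init
  if (is.na(init)) prof$saturated[is.na(slope)] <- TRUE
  prof
}
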