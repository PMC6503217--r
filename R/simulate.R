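# Genome-evolution simulator. Generates collections with a known species
# tree, JC69 nucleotide divergence, accessory gene gain/loss from a finite
# pool, and wholesale symbiotic-plasmid (psym) transfer between
# contemporaneous lineages. Ground truth (tree, distances, family table,
# transfer events, per-compartment divergence) is returned alongside the
# genomes so every downstream stage can be validated.

#' Simulator configuration
#'
#' @param n_genomes number of genomes (tree leaves) when `tree` is NULL
#' @param tree optional Newick string or `phylo`; otherwise a Yule tree with
#'   rate `birth_rate` is simulated
#' @param birth_rate Yule birth rate (lineages split at rate k * birth_rate)
#' @param subs_rate expected substitutions/site per unit branch length (JC69)
#' @param n_core_genes chromosomal core families, never lost
#' @param n_marker_genes leading core families tagged `marker_tag` (the
#'   ribosomal-protein analog set)
#' @param marker_tag role tag of the marker families
#' @param n_accessory_pool size of the finite accessory family pool
#' @param gain_rate,loss_rate accessory gain/loss rates per family per unit
#'   branch length (two-state Markov presence process, started at equilibrium)
#' @param mean_gene_len mean gene length in codons (gamma-distributed, min 60)
#' @param chromosome_length chromosome length in bp (genes + neutral spacers)
#' @param plasmid_plan list of plasmid descriptions `list(kind=, n_genes=,
#'   length=)`; exactly one entry must have kind "psym" (it receives
#'   nodABC/nifHDK analogs); every plasmid gets repC/repB genes from an
#'   independent family-specific lineage
#' @param psym_transfer_rate psym transfer events per lineage per unit branch
#'   length (recipient's psym is replaced wholesale by a copy of a random
#'   contemporaneous donor's psym)
#' @param forced_transfers optional data.frame(time, donor, recipient) of
#'   transfer events to plant deterministically; donor/recipient name leaves
#'   and resolve to the lineage ancestral to that leaf at `time`
#' @param accessory_plasmid_bias relative weight of plasmid vs chromosome as
#'   the landing replicon of gained genes
#' @param seed integer RNG seed; identical configs give byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genomes = 16L, tree = NULL, birth_rate = 1,
                       subs_rate = 0.05, n_core_genes = 120L,
                       n_marker_genes = 58L, marker_tag = "ribosomal",
                       n_accessory_pool = 200L, gain_rate = 0.2,
                       loss_rate = 1.0, mean_gene_len = 300L,
                       chromosome_length = 1e6,
                       plasmid_plan = list(
                         list(kind = "plasmid", n_genes = 25L, length = 2e5),
                         list(kind = "psym", n_genes = 25L, length = 2.5e5)),
                       psym_transfer_rate = 0, forced_transfers = NULL,
                       accessory_plasmid_bias = 3, seed = 1L) {
  stopifnot(n_core_genes >= 1L, n_marker_genes <= n_core_genes,
            gain_rate >= 0, loss_rate >= 0, psym_transfer_rate >= 0,
            subs_rate >= 0)
  kinds <- vapply(plasmid_plan, function(p) p$kind, character(1))
  if (sum(kinds == "psym") != 1L) {
    stop("plasmid_plan must contain exactly one entry with kind = 'psym'")
  }
  structure(list(n_genomes = as.integer(n_genomes), tree = tree,
                 birth_rate = birth_rate, subs_rate = subs_rate,
                 n_core_genes = as.integer(n_core_genes),
                 n_marker_genes = as.integer(n_marker_genes),
                 marker_tag = marker_tag,
                 n_accessory_pool = as.integer(n_accessory_pool),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 mean_gene_len = as.integer(mean_gene_len),
                 chromosome_length = chromosome_length,
                 plasmid_plan = plasmid_plan,
                 psym_transfer_rate = psym_transfer_rate,
                 forced_transfers = forced_transfers,
                 accessory_plasmid_bias = accessory_plasmid_bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth process started from two lineages at the root; after the n-th
#' lineage appears, one more exponential waiting time is added so leaves sit
#' strictly below the last split.
#' @param n number of leaves (>= 2)
#' @param birth_rate per-lineage birth rate
#' @param seed RNG seed
#' @return an `ape` phylo object with tips g01..gNN
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  with_seed(seed, {
    parent <- c(NA_integer_, 1L, 1L)
    start <- c(0, 0, 0)
    end <- rep(NA_real_, 3)
    active <- c(2L, 3L)
    t <- 0
    k <- 2L
    while (k < n) {
      t <- t + rexp(1, k * birth_rate)
      pick <- active[sample.int(length(active), 1L)]
      end[pick] <- t
      m <- length(parent)
      parent <- c(parent, pick, pick)
      start <- c(start, t, t)
      end <- c(end, NA_real_, NA_real_)
      active <- c(setdiff(active, pick), m + 1L, m + 2L)
      k <- k + 1L
    }
    t <- t + rexp(1, n * birth_rate)
    end[active] <- t
    # assemble newick; leaves are nodes with no children
    children <- split(seq_along(parent)[-1], parent[-1])
    leaf_ids <- setdiff(seq_along(parent), as.integer(names(children)))
    labels <- setNames(sprintf(paste0("g%0", max(2L, nchar(n)), "d"),
                               seq_along(leaf_ids)), leaf_ids)
    bl <- function(i) sprintf("%.10f", end[i] - start[i])
    nwk <- function(i) {
      ch <- children[[as.character(i)]]
      if (is.null(ch)) return(paste0(labels[[as.character(i)]], ":", bl(i)))
      inner <- paste(vapply(ch, nwk, character(1)), collapse = ",")
      if (i == 1L) paste0("(", inner, ");") else
        paste0("(", inner, "):", bl(i))
    }
    ape::read.tree(text = nwk(1L))
  })
}

# ---- root genome construction ------------------------------------------------

.new_seg <- function(type, family, tags, strand, seq) {
  list(type = type, family = family, tags = tags, strand = strand, seq = seq)
}

.draw_gene_len <- function(n, mean_codons) {
  pmax(60L, as.integer(round(rgamma(n, shape = 4, rate = 4 / mean_codons))))
}

.spacer_segments <- function(total, n_chunks) {
  total <- max(total, 50L * n_chunks)
  sizes <- rep(total %/% n_chunks, n_chunks)
  sizes[seq_len(total %% n_chunks)] <- sizes[seq_len(total %% n_chunks)] + 1L
  lapply(sizes, function(s) .new_seg("spacer", NA_character_, character(), "+",
                                     random_dna_int(s)))
}

.build_gene_segs <- function(families, tags_list, lens) {
  lapply(seq_along(families), function(i) {
    .new_seg("gene", families[i], tags_list[[i]],
             if (runif(1) < 0.5) "+" else "-", random_cds_int(lens[i]))
  })
}

.interleave <- function(genes, spacers) {
  out <- list(spacers[[1]])
  for (i in seq_along(genes)) {
    out[[length(out) + 1L]] <- genes[[i]]
    out[[length(out) + 1L]] <- spacers[[i + 1L]]
  }
  out
}

.build_root <- function(cfg) {
  sym_names <- c("nodA", "nodB", "nodC", "nifH", "nifD", "nifK")
  core_fams <- sprintf("core%03d", seq_len(cfg$n_core_genes))
  core_tags <- lapply(seq_len(cfg$n_core_genes), function(i)
    if (i <= cfg$n_marker_genes) cfg$marker_tag else character())
  core_lens <- .draw_gene_len(cfg$n_core_genes, cfg$mean_gene_len)
  core_genes <- .build_gene_segs(core_fams, core_tags, core_lens)
  sp_total <- as.integer(cfg$chromosome_length - sum(core_lens) * 3L)
  chr <- list(base = "chr", kind = "chromosome",
              segs = .interleave(core_genes,
                                 .spacer_segments(sp_total, cfg$n_core_genes + 1L)))
  reps <- list(chr)
  pl_letters <- LETTERS
  ip <- 0L
  for (plan in cfg$plasmid_plan) {
    is_psym <- plan$kind == "psym"
    base <- if (is_psym) "pSym" else { ip <- ip + 1L; paste0("p", pl_letters[ip]) }
    fams <- c(paste0("repC_", base), paste0("repB_", base))
    tags <- list("repC", "repB")
    if (is_psym) {
      fams <- c(fams, sym_names)
      tags <- c(tags, lapply(sym_names, function(s) c("symbiotic", s)))
      n_extra <- max(0L, plan$n_genes - length(sym_names) - 2L)
      if (n_extra > 0) {
        fams <- c(fams, sprintf("%s_g%03d", base, seq_len(n_extra)))
        tags <- c(tags, rep(list("symbiotic"), n_extra))
      }
    } else {
      n_extra <- max(0L, plan$n_genes - 2L)
      if (n_extra > 0) {
        fams <- c(fams, sprintf("%s_g%03d", base, seq_len(n_extra)))
        tags <- c(tags, rep(list(character()), n_extra))
      }
    }
    lens <- .draw_gene_len(length(fams), cfg$mean_gene_len)
    genes <- .build_gene_segs(fams, tags, lens)
    sp_total <- as.integer(plan$length - sum(lens) * 3L)
    reps[[length(reps) + 1L]] <-
      list(base = base, kind = plan$kind,
           segs = .interleave(genes, .spacer_segments(sp_total, length(fams) + 1L)))
  }
  # accessory pool: root sequences kept aside; gained copies are inserted
  # from this environmental pool
  pool <- NULL
  if (cfg$n_accessory_pool > 0) {
    fams <- sprintf("acc%03d", seq_len(cfg$n_accessory_pool))
    lens <- .draw_gene_len(cfg$n_accessory_pool, cfg$mean_gene_len)
    pool <- list(families = fams, lens = lens,
                 seqs = lapply(lens, random_cds_int))
  }
  list(reps = reps, pool = pool)
}

# ---- lineage evolution -------------------------------------------------------

.evolve_lineage <- function(st, dt, cfg, pool) {
  if (dt <= 0) return(st)
  d <- cfg$subs_rate * dt
  for (ri in seq_along(st$reps)) {
    segs <- st$reps[[ri]]$segs
    for (si in seq_along(segs)) {
      segs[[si]]$seq <- mutate_jc69(segs[[si]]$seq, d,
                                    coding = segs[[si]]$type == "gene")
    }
    st$reps[[ri]]$segs <- segs
  }
  # accessory presence: exact two-state Markov transition over dt
  g <- cfg$gain_rate; l <- cfg$loss_rate
  if (!is.null(pool) && (g + l) > 0) {
    w <- 1 - exp(-(g + l) * dt)
    p_gain <- (g / (g + l)) * w
    p_loss <- (l / (g + l)) * w
    u <- runif(length(st$acc))
    gained <- which(!st$acc & u < p_gain)
    lost <- which(st$acc & u < p_loss)
    if (length(lost) > 0) {
      st <- .remove_accessory(st, pool$families[lost])
      st$acc[lost] <- FALSE
    }
    for (fi in gained) {
      st <- .insert_accessory(st, pool, fi, cfg)
      st$acc[fi] <- TRUE
    }
  }
  st
}

.remove_accessory <- function(st, fams) {
  for (ri in seq_along(st$reps)) {
    segs <- st$reps[[ri]]$segs
    keep <- vapply(segs, function(s)
      !(s$type == "gene" && !is.na(s$family) && s$family %in% fams), logical(1))
    st$reps[[ri]]$segs <- segs[keep]
  }
  st
}

.insert_accessory <- function(st, pool, fi, cfg) {
  kinds <- vapply(st$reps, function(r) r$kind, character(1))
  w <- ifelse(kinds == "chromosome", 1, cfg$accessory_plasmid_bias)
  ri <- sample.int(length(st$reps), 1L, prob = w)
  seg <- .new_seg("gene", pool$families[fi], character(),
                  if (runif(1) < 0.5) "+" else "-", pool$seqs[[fi]])
  segs <- st$reps[[ri]]$segs
  pos <- sample.int(length(segs) + 1L, 1L)
  st$reps[[ri]]$segs <- append(segs, list(seg), after = pos - 1L)
  st
}

.psym_index <- function(st) {
  which(vapply(st$reps, function(r) r$kind == "psym", logical(1)))[1]
}

# ---- main driver -------------------------------------------------------------

#' Evolve a genome collection along a species tree
#'
#' Builds a root genome (chromosomal core genes, plasmids per plan with
#' Rep-protein lineages, a psym carrying nodABC/nifHDK analogs), evolves all
#' sequence neutrally under JC69 along the tree, gains/loses accessory
#' families as a two-state Markov process over a finite pool, and optionally
#' replaces recipients' psyms wholesale by contemporaneous donors' copies
#' (horizontal transfer), either at a Poisson rate or at planted times.
#'
#' @param cfg a [sim_config()]
#' @return `list(genomes = <list of genome_record>, truth = <sim_truth>)`;
#'   the truth carries the tree, true pairwise distances (subs/site), the
#'   family presence table, transfer events, and per-compartment
#'   (chromosome vs psym) expected divergence per genome pair
#' @export
evolve_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- simulate_tree(cfg$n_genomes, cfg$birth_rate, cfg$seed)
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  ntips <- length(tree$tip.label)
  root <- ntips + 1L
  depths <- ape::node.depth.edgelength(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- .descendant_leaves(tree)

  with_seed(cfg$seed + 1L, {
    rootstate <- .build_root(cfg)
    pool <- rootstate$pool
    g <- cfg$gain_rate; l <- cfg$loss_rate
    eq <- if ((g + l) > 0) g / (g + l) else 0
    base_acc <- if (!is.null(pool)) runif(length(pool$families)) < eq else logical(0)
    st0 <- list(reps = rootstate$reps, acc = rep(FALSE, length(base_acc)),
                psym_id = NA_integer_)
    for (fi in which(base_acc)) {
      st0 <- .insert_accessory(st0, pool, fi, cfg)
      st0$acc[fi] <- TRUE
    }

    # psym genealogy: id, parent, birth time
    gen_parent <- c(NA_integer_); gen_time <- c(0)
    next_id <- function() { gen_parent <<- c(gen_parent, NA_integer_)
                            gen_time <<- c(gen_time, 0); length(gen_parent) }
    new_psym_id <- function(parent, t) {
      id <- next_id(); gen_parent[id] <<- parent; gen_time[id] <<- t; id
    }
    st0$psym_id <- 1L

    active <- list()   # keyed by as.character(child node)
    for (ch in children[[as.character(root)]]) {
      st <- st0
      st$psym_id <- new_psym_id(1L, 0)
      active[[as.character(ch)]] <- st
    }

    event_nodes <- setdiff(order(depths), root)
    event_nodes <- event_nodes[depths[event_nodes] > 0 | event_nodes <= ntips]
    # group events by depth
    ev_depth <- depths[event_nodes]
    ord <- order(ev_depth, event_nodes)
    event_nodes <- event_nodes[ord]; ev_depth <- ev_depth[ord]

    leaves_out <- list()
    transfers <- list()
    t0 <- 0
    i <- 1L
    while (i <= length(event_nodes)) {
      t1 <- ev_depth[i]
      # transfer events in (t0, t1]
      evs <- NULL
      if (t1 > t0) {
        keys <- sort(names(active))
        if (cfg$psym_transfer_rate > 0 && length(keys) >= 2) {
          for (kk in keys) {
            nev <- rpois(1, cfg$psym_transfer_rate * (t1 - t0))
            if (nev > 0) {
              evs <- rbind(evs, data.frame(
                time = t0 + runif(nev) * (t1 - t0),
                recipient = kk, donor = NA_character_,
                stringsAsFactors = FALSE))
            }
          }
        }
        if (!is.null(cfg$forced_transfers)) {
          ft <- cfg$forced_transfers
          sel <- ft$time > t0 & ft$time <= t1
          if (any(sel)) {
            for (j in which(sel)) {
              rk <- .lineage_of_leaf(ft$recipient[j], active, desc)
              dk <- .lineage_of_leaf(ft$donor[j], active, desc)
              evs <- rbind(evs, data.frame(time = ft$time[j], recipient = rk,
                                           donor = dk, stringsAsFactors = FALSE))
            }
          }
        }
        if (!is.null(evs)) evs <- evs[order(evs$time), , drop = FALSE]
        # evolve through sub-intervals punctuated by transfers
        tcur <- t0
        nev <- if (is.null(evs)) 0L else nrow(evs)
        for (j in seq_len(nev)) {
          te <- evs$time[j]
          for (kk in sort(names(active))) {
            active[[kk]] <- .evolve_lineage(active[[kk]], te - tcur, cfg, pool)
          }
          tcur <- te
          rk <- evs$recipient[j]
          dk <- evs$donor[j]
          if (is.na(dk)) {
            others <- setdiff(sort(names(active)), rk)
            dk <- others[sample.int(length(others), 1L)]
          }
          if (!identical(dk, rk)) {
            dst <- active[[dk]]; rst <- active[[rk]]
            pi_d <- .psym_index(dst); pi_r <- .psym_index(rst)
            rst$reps[[pi_r]] <- dst$reps[[pi_d]]
            # accessory families living on the transferred psym move too
            rst$acc <- .recount_accessory(rst, pool)
            old <- dst$psym_id
            dst$psym_id <- new_psym_id(old, te)
            rst$psym_id <- new_psym_id(old, te)
            active[[dk]] <- dst; active[[rk]] <- rst
            transfers[[length(transfers) + 1L]] <- data.frame(
              time = te, donor = as.integer(dk), recipient = as.integer(rk),
              donor_leaves = paste(desc[[as.integer(dk)]], collapse = ","),
              recipient_leaves = paste(desc[[as.integer(rk)]], collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
        for (kk in sort(names(active))) {
          active[[kk]] <- .evolve_lineage(active[[kk]], t1 - tcur, cfg, pool)
        }
      }
      # process all events at depth t1
      while (i <= length(event_nodes) && ev_depth[i] <= t1 + 1e-12) {
        nd <- event_nodes[i]
        key <- as.character(nd)
        st <- active[[key]]
        if (nd <= ntips) {
          leaves_out[[tree$tip.label[nd]]] <- st
          active[[key]] <- NULL
        } else {
          active[[key]] <- NULL
          for (ch in children[[key]]) {
            st2 <- st
            st2$psym_id <- new_psym_id(st$psym_id, t1)
            active[[as.character(ch)]] <- st2
          }
        }
        i <- i + 1L
      }
      t0 <- t1
    }

    labels <- sort(tree$tip.label)
    genomes <- lapply(labels, function(lb) .export_genome(lb, leaves_out[[lb]]))
    truth <- .build_truth(tree, cfg, labels, leaves_out, transfers,
                          gen_parent, gen_time, depths, ntips)
    rc_log("simulated %d genomes, %d transfer events", length(genomes),
           length(transfers))
    list(genomes = genomes, truth = truth)
  })
}

.recount_accessory <- function(st, pool) {
  if (is.null(pool)) return(st$acc)
  fams <- unlist(lapply(st$reps, function(r)
    vapply(r$segs, function(s) if (s$type == "gene") s$family else NA_character_,
           character(1))))
  pool$families %in% fams
}

.descendant_leaves <- function(tree) {
  ntips <- length(tree$tip.label)
  nn <- ntips + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntips)) desc[[i]] <- tree$tip.label[i]
  # accumulate leaf sets bottom-up (postorder over edges)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

.lineage_of_leaf <- function(leaf, active, desc) {
  for (kk in sort(names(active))) {
    if (leaf %in% desc[[as.integer(kk)]]) return(kk)
  }
  stop(sprintf("no active lineage is ancestral to leaf '%s'", leaf))
}

.export_genome <- function(genome_id, st) {
  replicons <- list()
  for (r in st$reps) {
    pieces <- character(length(r$segs))
    genes <- list()
    pos <- 0L
    for (si in seq_along(r$segs)) {
      s <- r$segs[[si]]
      n <- length(s$seq)
      if (s$type == "gene") {
        fwd <- if (s$strand == "-") revcomp_int(s$seq) else s$seq
        pieces[si] <- decode_dna(fwd)
        genes[[length(genes) + 1L]] <- gene_record(
          gene_id = paste0(genome_id, "_", s$family),
          start = pos, end = pos + n, strand = s$strand,
          cds = decode_dna(s$seq), role_tags = s$tags, family_truth = s$family)
      } else {
        pieces[si] <- decode_dna(s$seq)
      }
      pos <- pos + n
    }
    replicons[[length(replicons) + 1L]] <- replicon_record(
      paste0(genome_id, "_", r$base), r$kind, paste(pieces, collapse = ""), genes)
  }
  genome_record(genome_id, "complete", replicons)
}

.build_truth <- function(tree, cfg, labels, leaves_out, transfers,
                         gen_parent, gen_time, depths, ntips) {
  coph <- cophenetic(tree)[labels, labels]
  true_d <- cfg$subs_rate * coph
  # family presence table
  fam_sets <- lapply(labels, function(lb) {
    st <- leaves_out[[lb]]
    unique(unlist(lapply(st$reps, function(r)
      vapply(r$segs, function(s) if (s$type == "gene") s$family else NA_character_,
             character(1)))))
  })
  fams <- sort(unique(unlist(fam_sets)))
  fams <- fams[!is.na(fams)]
  pa <- vapply(fam_sets, function(fs) fams %in% fs, logical(length(fams)))
  if (is.null(dim(pa))) pa <- matrix(pa, nrow = length(fams))
  dimnames(pa) <- list(fams, labels)
  # psym divergence via genealogy
  leaf_depth <- setNames(depths[seq_len(ntips)], tree$tip.label)
  psym_ids <- vapply(labels, function(lb) leaves_out[[lb]]$psym_id, integer(1))
  chain <- function(id) {
    out <- integer(0)
    while (!is.na(id)) { out <- c(out, id); id <- gen_parent[id] }
    out
  }
  n <- length(labels)
  psym_div <- matrix(0, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n)) {
    ca <- chain(psym_ids[a])
    for (b in seq_len(n)) {
      if (b <= a) next
      cb <- chain(psym_ids[b])
      common <- intersect(ca, cb)
      # split time = birth of the last ids before the chains merge
      ia <- match(common[1], ca); ib <- match(common[1], cb)
      tsplit <- if (ia == 1L || ib == 1L) {
        # one chain's leaf id is an ancestor of the other: diverged at the
        # younger id's birth
        max(gen_time[ca[max(ia - 1L, 1L)]], gen_time[cb[max(ib - 1L, 1L)]])
      } else {
        gen_time[ca[ia - 1L]]  # equal to gen_time[cb[ib - 1L]] by construction
      }
      d <- cfg$subs_rate *
        ((leaf_depth[labels[a]] - tsplit) + (leaf_depth[labels[b]] - tsplit))
      psym_div[a, b] <- psym_div[b, a] <- d
    }
  }
  tr <- if (length(transfers) > 0) do.call(rbind, transfers) else
    data.frame(time = numeric(), donor = integer(), recipient = integer(),
               donor_leaves = character(), recipient_leaves = character(),
               stringsAsFactors = FALSE)
  structure(list(tree = tree, true_pairwise_distance = true_d,
                 family_table = pa, transfer_events = tr,
                 chromosome_divergence = true_d, psym_divergence = psym_div,
                 config = cfg),
            class = "sim_truth")
}

#' Simulate a genome pair with a planted recent psym transfer
#'
#' Two genomes whose chromosomes diverged by `split_distance` substitutions
#' per site, while the psym of one was replaced by the other's copy at
#' relative time `transfer_fraction` before the present (psym divergence =
#' `transfer_fraction * split_distance`). `transfer_fraction = 1` yields the
#' no-transfer control.
#' @param cfg a [sim_config()] (tree and transfer fields are overridden)
#' @param split_distance chromosome divergence, substitutions/site
#' @param transfer_fraction relative age of the transfer (0 = now, 1 = at the
#'   split, i.e. no transfer)
#' @param seed RNG seed
#' @return as [evolve_collection()]
#' @export
simulate_transfer_pair <- function(cfg, split_distance, transfer_fraction,
                                   seed = 1L) {
  h <- split_distance / (2 * cfg$subs_rate)
  nwk <- sprintf("(gA:%.10f,gB:%.10f);", h, h)
  cfg$tree <- nwk
  cfg$seed <- as.integer(seed)
  cfg$psym_transfer_rate <- 0
  cfg$forced_transfers <- if (transfer_fraction < 1) {
    data.frame(time = h * (1 - transfer_fraction),
               donor = "gA", recipient = "gB", stringsAsFactors = FALSE)
  } else NULL
  evolve_collection(cfg)
}

#' Simulate codon-aligned CDS pairs with purely synonymous divergence
#'
#' Genes are built from fourfold-degenerate codon families only (Ala, Gly,
#' Pro, Thr, Val), so every codon carries exactly one synonymous site (the
#' third position) and no synonymous changes are possible elsewhere. Third
#' positions then evolve under JC69 at distance `ks`, making `ks` the exact
#' generating value of synonymous substitutions per synonymous site.
#' @param n_pairs number of gene pairs
#' @param n_codons codons per gene
#' @param ks generating synonymous divergence (subs per synonymous site)
#' @param seed RNG seed
#' @return list of `list(cds_a=, cds_b=)` DNA strings
#' @export
simulate_syn_cds_pairs <- function(n_pairs, n_codons, ks, seed = 1L) {
  fourfold_first2 <- matrix(c(2L, 1L,   # GC Ala
                              2L, 2L,   # GG Gly
                              1L, 1L,   # CC Pro
                              0L, 1L,   # AC Thr
                              2L, 3L),  # GT Val
                            ncol = 2, byrow = TRUE)
  with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      fam <- sample.int(5L, n_codons, replace = TRUE)
      third <- sample(0:3, n_codons, replace = TRUE)
      a <- as.integer(rbind(fourfold_first2[fam, 1], fourfold_first2[fam, 2], third))
      b <- a
      idx3 <- seq(3L, length(a), by = 3L)
      third_b <- mutate_jc69(a[idx3], ks)
      b[idx3] <- third_b
      list(cds_a = decode_dna(a), cds_b = decode_dna(b))
    })
  })
}

#' Plant a single-gene horizontal transfer into a simulated collection
#'
#' Replaces the recipient genome's copy of `family` (sequence and strand) by
#' the donor's copy, leaving coordinates intact where lengths agree. Used to
#' create one incongruent marker among otherwise clean markers.
#' @param genomes list of `genome_record`s
#' @param family family_truth label of the gene to transfer
#' @param donor,recipient genome ids
#' @return modified genome list
#' @export
plant_marker_hgt <- function(genomes, family, donor, recipient) {
  ids <- genome_ids(genomes)
  gd <- genomes[[match(donor, ids)]]
  donor_gene <- NULL
  for (r in gd$replicons) for (g in r$genes) {
    if (identical(g$family_truth, family)) donor_gene <- g
  }
  if (is.null(donor_gene)) stop(sprintf("family '%s' not found in donor", family))
  ir <- match(recipient, ids)
  gr <- genomes[[ir]]
  for (ri in seq_along(gr$replicons)) {
    r <- gr$replicons[[ri]]
    for (gi in seq_along(r$genes)) {
      g <- r$genes[[gi]]
      if (identical(g$family_truth, family)) {
        if (nchar(donor_gene$cds) != g$end - g$start) {
          stop("donor and recipient copies differ in length")
        }
        fwd <- if (g$strand == "-") revcomp(donor_gene$cds) else donor_gene$cds
        substr(r$sequence, g$start + 1L, g$end) <- fwd
        g$cds <- donor_gene$cds
        g$protein <- donor_gene$protein
        r$genes[[gi]] <- g
      }
    }
    gr$replicons[[ri]] <- r
  }
  genomes[[ir]] <- gr
  genomes
}
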