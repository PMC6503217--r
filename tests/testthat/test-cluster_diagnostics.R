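# Rank correlations, cluster calling, and the smoothed continuum profile.

test_that("Spearman correlation matches direct rank computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  s <- spearman_cor(x, y)
  # ranks of y are (2,1,4,3,5): sum d^2 = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(s$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(s$rho, unname(cor(x, y, method = "spearman")))
  # perfectly decreasing
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("exact permutation p-values match full enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  s <- spearman_cor(x, y, exact = TRUE)
  # brute-force enumeration in R
  perms <- rbind(y)
  all_p <- combinat_perms <- NULL
  enum <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enum(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rho_obs <- abs(cor(rank(x), rank(y)))
  rhos <- vapply(enum(y), function(p) abs(cor(rank(x), rank(p))), numeric(1))
  expect_equal(s$p_value, mean(rhos >= rho_obs - 1e-12))
  # ties: average ranks, checked against enumeration as well
  xt <- c(1, 1, 2, 3)
  yt <- c(1, 2, 3, 3)
  st <- spearman_cor(xt, yt, exact = TRUE)
  expect_equal(st$rho, unname(cor(xt, yt, method = "spearman")))
  rho_obs_t <- abs(cor(rank(xt), rank(yt)))
  rhos_t <- vapply(enum(rank(yt)), function(p) abs(cor(rank(xt), p)), numeric(1))
  expect_equal(st$p_value, mean(rhos_t >= rho_obs_t - 1e-12))
  expect_error(spearman_cor(1:12, 12:1, exact = TRUE), "n <= 10")
})

test_that("cluster calls use strict thresholds and single linkage", {
  ids <- c("A", "B", "C", "D")
  ani <- matrix(90, 4, 4, dimnames = list(ids, ids)); diag(ani) <- 100
  gcov <- matrix(95, 4, 4, dimnames = list(ids, ids)); diag(gcov) <- 100
  # all below ANI threshold: all singletons
  cl <- call_clusters(ani, gcov)
  expect_length(cl$clusters, 4)
  # chain A-B and B-C above, A-C below -> one component {A,B,C}
  ani2 <- ani
  ani2["A", "B"] <- ani2["B", "A"] <- 97
  ani2["B", "C"] <- ani2["C", "B"] <- 97
  cl2 <- call_clusters(ani2, gcov)
  expect_true(any(vapply(cl2$clusters, function(x)
    setequal(x, c("A", "B", "C")), logical(1))))
  expect_length(cl2$clusters, 2)
  # exactly at the threshold is NOT above it (strict >)
  ani3 <- ani
  ani3["A", "B"] <- ani3["B", "A"] <- 96
  expect_length(call_clusters(ani3, gcov)$clusters, 4)
  expect_error(call_clusters(ani, gcov, ani_min = 101), "0, 100")
})

test_that("raising thresholds never merges clusters, lowering never splits", {
  set.seed(12)
  ids <- paste0("g", 1:10)
  base <- matrix(runif(100, 85, 99), 10, 10, dimnames = list(ids, ids))
  ani <- (base + t(base)) / 2; diag(ani) <- 100
  gcov <- matrix(95, 10, 10, dimnames = list(ids, ids)); diag(gcov) <- 100
  prev <- NULL
  for (th in c(88, 90, 92, 94, 96)) {
    memb <- call_clusters(ani, gcov, ani_min = th)$membership
    if (!is.null(prev)) {
      # refinement: genomes together at the higher threshold were together
      # at the lower one
      for (i in 1:9) for (j in (i + 1):10) {
        if (memb[[i]] == memb[[j]]) expect_true(prev[[i]] == prev[[j]])
      }
    }
    prev <- memb
  }
})

test_that("the continuum profile tracks the JC curve and flags the asymptote", {
  set.seed(8)
  d <- runif(300, 0.005, 0.08)
  ani <- jc_identity_pct(d) + rnorm(300, 0, 0.05)
  pairs <- data.frame(ani_pct = ani, genetic_distance = d)
  prof <- continuum_profile(pairs, window = 0.005)
  expect_lt(max(abs(prof$mean_ani - jc_identity_pct(prof$center))), 0.35)
  # constant input: zero slope, saturated from the start
  flat <- data.frame(ani_pct = rep(95, 40),
                     genetic_distance = seq(0.01, 0.05, length.out = 40))
  pf <- continuum_profile(flat)
  expect_true(all(pf$saturated))
  # monotone ladder in, monotone non-increasing smoothed curve out
  lad <- data.frame(genetic_distance = seq(0.005, 0.08, length.out = 60))
  lad$ani_pct <- jc_identity_pct(lad$genetic_distance)
  pl <- continuum_profile(lad)
  expect_true(all(diff(pl$mean_ani) <= 1e-9))
  expect_error(continuum_profile(pairs, window = 0), "window")
  expect_error(continuum_profile(pairs[1:5, ]), "10 pairs")
})
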