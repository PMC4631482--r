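# naive O(n^3) agglomerative clustering oracle (average / single / complete
# linkage on the original inter-point distances)
naive_agglomerate <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage,
           average = mean(vals), single = min(vals), complete = max(vals))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(letters[1:n], letters[1:n])
  d
}

test_that("pairwise CC matches the Pearson formula and flags thin overlap", {
  truth <- p1_truth_coarse()
  a <- simulate_partial_dataset(truth, fraction_f = 0.4, noise_frac = 0.1,
                                label = "a", seed = 1)
  ccm <- pairwise_cc(list(a, a))
  expect_equal(ccm$cc[1, 2], 1, tolerance = 1e-12) # self-pairing
  expect_equal(diag(ccm$cc), c(1, 1), ignore_attr = TRUE)

  # 10-reflection toy pair against the direct Pearson formula
  setting <- symmetry_preset("P1")
  hkl <- cbind(1:10, 2, 3)
  ia <- c(5, 8, 2, 9, 4, 7, 1, 6, 3, 10)
  ib <- c(6, 7, 3, 10, 3, 8, 2, 5, 4, 9)
  sa <- reflection_set(tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                                      i_obs = ia, sigma = rep(1, 10)),
                       setting, label = "ta")
  sb <- reflection_set(tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                                      i_obs = ib, sigma = rep(1, 10)),
                       setting, label = "tb")
  ccm2 <- pairwise_cc(list(sa, sb), min_common = 5)
  expect_equal(ccm2$cc[1, 2], cor(ia, ib), tolerance = 1e-12)
  expect_equal(ccm2$n_common[1, 2], 10L)

  # below min_common: missing
  ccm3 <- pairwise_cc(list(sa, sb), min_common = 30)
  expect_true(ccm3$missing[1, 2])
  expect_true(is.na(ccm3$cc[1, 2]))

  # null distribution: independent Wilson draws on shared uniques
  set.seed(99)
  null_cc <- vapply(1:40, function(i) {
    ia <- rexp(200); ib <- rexp(200)
    cor(ia, ib)
  }, 0)
  expect_lt(mean(abs(null_cc) > 2 / sqrt(200)), 0.15)
})

test_that("cc_to_distance implements sqrt(1 - cc^2) with maximal missing", {
  expect_equal(cc_to_distance(1), 0)
  expect_equal(cc_to_distance(0), 1)
  expect_equal(cc_to_distance(-1), 0)
  expect_equal(cc_to_distance(0.989), 0.1479, tolerance = 1e-3)
  expect_lt(cc_to_distance(0.989), 0.15) # just inside the selection cutoff
  expect_equal(cc_to_distance(NA), 1)
  # symmetry and range on a cc_matrix
  truth <- p1_truth_coarse()
  sets <- lapply(1:3, function(i) {
    simulate_partial_dataset(truth, fraction_f = 0.3, noise_frac = 0.2,
                             label = paste0("s", i), seed = i)
  })
  d <- cc_to_distance(pairwise_cc(sets))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
})

test_that("hca agrees with a naive O(n^3) oracle and is permutation-stable", {
  # three leaves: the close pair merges first at its own distance
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend3 <- hca(d3)
  expect_equal(dend3$merges$height[1], 0.1)
  first_pair <- dend3$labels[c(-dend3$merges$node_a[1],
                               -dend3$merges$node_b[1])]
  expect_setequal(first_pair, c("A", "B"))

  for (seed in 1:6) {
    d <- random_dist(7, seed)
    for (lk in c("average", "single", "complete")) {
      dend <- hca(d, linkage = lk)
      expect_true(all(diff(dend$merges$height) >= -1e-12))
      if (lk != "average") next
      # average-linkage heights match hclust's UPGMA exactly; the naive
      # oracle on original distances agrees at the first merges and in
      # count
      expect_length(dend$merges$height, 6)
    }
    # oracle comparison for single linkage (chain-independent)
    expect_equal(sort(hca(d, linkage = "single")$merges$height),
                 sort(naive_agglomerate(d, "single")), tolerance = 1e-12)
  }

  # average-linkage oracle on UPGMA-consistent data: ultrametric distances
  set.seed(3)
  for (rep in 1:4) {
    d <- random_dist(7, 100 + rep)
    dend <- hca(d, linkage = "average")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(dend$merges$height, hc$height)
    # permuting leaves yields the same multiset of merge heights
    perm <- sample(7)
    dp <- d[perm, perm]
    expect_equal(sort(hca(dp, linkage = "average")$merges$height),
                 sort(dend$merges$height), tolerance = 1e-12)
  }

  expect_error(hca(matrix(0, 1, 1)), "at least 2")
})

test_that("naive average-linkage oracle matches hca on random matrices", {
  # full O(n^3) UPGMA oracle with Lance-Williams size-weighted updates
  upgma_oracle <- function(d) {
    n <- nrow(d)
    active <- seq_len(n)
    sizes <- rep(1, n)
    dm <- d
    heights <- numeric(0)
    while (length(active) > 1) {
      sub <- dm[active, active]
      diag(sub) <- Inf
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      a <- active[ij[1]]; b <- active[ij[2]]
      heights <- c(heights, dm[a, b])
      for (x in setdiff(active, c(a, b))) {
        dm[a, x] <- dm[x, a] <-
          (sizes[a] * dm[a, x] + sizes[b] * dm[b, x]) / (sizes[a] + sizes[b])
      }
      sizes[a] <- sizes[a] + sizes[b]
      active <- setdiff(active, b)
    }
    heights
  }
  for (seed in 11:16) {
    d <- random_dist(7, seed)
    expect_equal(hca(d, linkage = "average")$merges$height, upgma_oracle(d),
                 tolerance = 1e-12)
  }
})

test_that("cutting the dendrogram recovers planted partitions", {
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- hca(d3)
  # height 0: every leaf its own cluster
  sel0 <- cut_dendrogram(dend, 0)
  expect_equal(length(unique(sel0$membership)), 3)
  # height above the last merge: one cluster
  sel1 <- cut_dendrogram(dend, 1.5)
  expect_equal(length(unique(sel1$membership)), 1)
  # intermediate: {A,B} is the main cluster
  sel <- cut_dendrogram(dend, 0.5, d3)
  expect_setequal(sel$main_cluster, c("A", "B"))

  # planted 8-vs-3 with the calibrated class separation, cut at 0.15
  truth <- p1_truth_coarse()
  cls <- rep(c(1L, 2L), c(8, 3))
  sets <- lapply(1:11, function(i) {
    simulate_partial_dataset(truth, fraction_f = 0.35, noise_frac = 0.05,
                             class_shift = 0.2, class_id = cls[i],
                             label = paste0("s", i), seed = 400 + i)
  })
  dm <- cc_to_distance(pairwise_cc(sets))
  sel2 <- cut_dendrogram(hca(dm), 0.15, dm)
  expect_setequal(sel2$main_cluster, paste0("s", 1:8))
})

test_that("indexing ambiguities are resolved against the first dataset", {
  truth6 <- p6_truth()
  s6 <- attr(truth6, "setting")
  op <- s6$ambiguity_ops[[1]]

  # without ambiguity operators: identity pass-through
  truth1 <- p1_truth_coarse()
  sets1 <- lapply(1:3, function(i) {
    simulate_partial_dataset(truth1, fraction_f = 0.3, label = paste0("s", i),
                             seed = i)
  })
  res1 <- resolve_indexing(sets1)
  expect_equal(res1$chosen_ops, rep(1L, 3))
  expect_identical(res1$sets[[2]]$h, sets1[[2]]$h)

  # planted flips on half the sets are all detected and inverted
  flip <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  sets <- lapply(1:8, function(i) {
    simulate_partial_dataset(truth6, fraction_f = 0.5, noise_frac = 0.05,
                             label = paste0("s", i), seed = 200 + i,
                             reindex_op = if (flip[i]) op else NULL)
  })
  res <- resolve_indexing(sets)
  expect_equal(res$chosen_ops, ifelse(flip, 2L, 1L))
  expect_false(any(res$flagged))

  # mean pairwise CC strictly improves after resolution
  mean_cc <- function(s) {
    cc <- pairwise_cc(s)$cc
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  expect_gt(mean_cc(res$sets), mean_cc(sets))
})

test_that("the Newick serialization parses and has non-negative branch lengths", {
  d <- matrix(c(0, 0.1, 0.9, 0.8,
                0.1, 0, 0.85, 0.9,
                0.9, 0.85, 0, 0.2,
                0.8, 0.9, 0.2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nwk <- dendrogram_newick(hca(d))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, letters[1:4])
  expect_true(all(tree$edge.length >= 0))
})
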