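test_that("relative scales are recovered exactly in the noiseless limit", {
  truth <- p1_truth_coarse()
  ref <- simulate_partial_dataset(truth, fraction_f = 0.6, noise_frac = 0,
                                  label = "ref", seed = 1)

  # set identical to the reference: k = 1, b = 0
  sc0 <- fit_scales(list(ref, ref))
  expect_equal(sc0$scale_k, c(1, 1), tolerance = 1e-9)
  expect_equal(sc0$b_rel, c(0, 0), tolerance = 1e-9)

  # planted k = 2, b = 5, noiseless: recovered to 1e-6
  scaled <- simulate_partial_dataset(truth, fraction_f = 0.6, noise_frac = 0,
                                     scale_k = 2, b_rel = 5, label = "s",
                                     seed = 2)
  sc <- fit_scales(list(ref, scaled))
  expect_equal(sc$scale_k[2], 2, tolerance = 1e-6)
  expect_equal(sc$b_rel[2], 5, tolerance = 1e-6)

  # under noise: median recovered k within 5% over 20 seeds
  ks <- vapply(1:20, function(sd) {
    s <- simulate_partial_dataset(truth, fraction_f = 0.6, noise_frac = 0.1,
                                  scale_k = 2, b_rel = 5, label = "s",
                                  seed = 100 + sd)
    fit_scales(list(ref, s))$scale_k[2]
  }, 0)
  expect_lt(abs(median(ks) - 2) / 2, 0.05)

  # insufficient overlap: dropped with a warning (the simulator itself
  # warns about the very thin wedge)
  expect_warning(
    tiny <- simulate_partial_dataset(truth, fraction_f = 0.002,
                                     noise_frac = 0, label = "tiny",
                                     seed = 3),
    "fewer than 10")
  expect_warning(sc2 <- fit_scales(list(ref, tiny), min_common = 1e4),
                 "dropped")
  expect_true(sc2$dropped[2])
})

test_that("merging is an inverse-variance weighted mean with propagated sigma", {
  setting <- symmetry_preset("P1")

  # closed form: {10 +/- 1, 12 +/- 1} -> 11 +/- 1/sqrt(2)
  s <- reflection_set(tibble::tibble(h = c(2, 2), k = c(3, 3), l = c(4, 4),
                                     i_obs = c(10, 12), sigma = c(1, 1)),
                      setting)
  m <- merge_datasets(list(s))
  expect_equal(m$i_merged, 11)
  expect_equal(m$sigma_merged, sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(m$n_obs, 2L)

  # one noiseless set merges back to the truth subset
  truth <- p1_truth_coarse()
  one <- simulate_partial_dataset(truth, fraction_f = 0.4, noise_frac = 0,
                                  seed = 5)
  m1 <- merge_datasets(list(one))
  key <- paste(m1$h, m1$k, m1$l)
  tkey <- paste(truth$h, truth$k, truth$l)
  expect_equal(m1$i_merged, truth$i_true[match(key, tkey)])

  # duplicating a set leaves merged intensities unchanged, doubles
  # multiplicity
  m2 <- merge_datasets(list(one, one))
  expect_equal(m2$i_merged, m1$i_merged[match(paste(m2$h, m2$k, m2$l), key)])
  expect_equal(sum(m2$n_obs), 2 * sum(m1$n_obs))

  # scale/merge consistency: arbitrary planted (k, b) undone by fit_scales
  a <- simulate_partial_dataset(truth, fraction_f = 0.5, noise_frac = 0,
                                scale_k = 1, label = "a", seed = 6)
  b <- simulate_partial_dataset(truth, fraction_f = 0.5, noise_frac = 0,
                                scale_k = 3, b_rel = 8, label = "b", seed = 7)
  mm <- merge_datasets(list(a, b), fit_scales(list(a, b)))
  key3 <- paste(mm$h, mm$k, mm$l)
  rel_err <- abs(mm$i_merged - truth$i_true[match(key3, tkey)]) /
    truth$i_true[match(key3, tkey)]
  expect_lt(sqrt(mean(rel_err^2)), 1e-6)
})

test_that("merge statistics match hand calculations", {
  setting <- symmetry_preset("P1")
  s <- reflection_set(tibble::tibble(h = c(1, 1, 1), k = c(2, 2, 2),
                                     l = c(3, 3, 3), i_obs = c(10, 12, 14),
                                     sigma = c(1, 1, 1)),
                      setting)
  m <- merge_datasets(list(s))
  st <- compute_stats(m, n_possible = 1)
  # R_pim = sqrt(1/2) * (2 + 0 + 2) / 36
  expect_equal(st$r_pim, sqrt(0.5) * 4 / 36, tolerance = 1e-12)
  expect_equal(st$r_merge, 4 / 36, tolerance = 1e-12)
  expect_equal(st$completeness, 100)
  expect_equal(st$multiplicity, 3)

  # completeness against a larger universe
  truth <- p1_truth_coarse()
  sub <- simulate_partial_dataset(truth, fraction_f = 0.85, noise_frac = 0,
                                  seed = 2)
  st2 <- compute_stats(merge_datasets(list(sub)), nrow(truth))
  expect_equal(st2$completeness, 100 * nrow(sub) / nrow(truth),
               tolerance = 1e-9)

  # two identical half-datasets: CC_1/2 = 1
  dup <- merge_datasets(list(sub, sub))
  st3 <- compute_stats(dup, nrow(truth))
  expect_equal(st3$cc_half, 1, tolerance = 1e-12)

  # all-singleton merge: R factors and CC_1/2 absent
  st4 <- compute_stats(merge_datasets(list(sub)), nrow(truth))
  expect_true(is.na(st4$r_pim))
  expect_true(is.na(st4$cc_half))
})

test_that("H-test estimates the twin fraction", {
  truth4 <- memo("p4_truth",
                 generate_ground_truth(symmetry_preset("P4"), 2.5,
                                       b_true = 10, seed = 21))
  setting <- attr(truth4, "setting")
  op <- setting$ambiguity_ops[[1]]

  twin_mix <- function(alpha, seed) {
    # mix each unique with its twin mate: I' = (1-a) I + a I_mate
    set.seed(seed)
    m <- merge_datasets(list(simulate_partial_dataset(
      truth4, fraction_f = 1, noise_frac = 0, seed = seed)))
    mate <- reduce_to_asu(as.matrix(m[, c("h", "k", "l")]) %*% op, setting)
    idx <- match(paste(mate[, 1], mate[, 2], mate[, 3]),
                 paste(m$h, m$k, m$l))
    mixed <- m
    ok <- !is.na(idx)
    mixed$i_merged[ok] <- (1 - alpha) * m$i_merged[ok] +
      alpha * m$i_merged[idx[ok]]
    mixed
  }

  # perfect twin: mean H = 0, alpha = 0.5
  perfect <- twin_mix(0.5, 1)
  ht <- h_test(perfect, op)
  expect_equal(ht$mean_h, 0, tolerance = 1e-9)
  expect_equal(ht$alpha, 0.5, tolerance = 1e-9)

  # untwinned iid exponential pairs: E[H] = 1/2, alpha ~ 0
  ht0 <- h_test(twin_mix(0, 2), op)
  expect_equal(ht0$mean_h, 0.5, tolerance = 0.02)
  expect_lt(ht0$alpha, 0.03)

  # planted alpha = 0.2 recovered within 0.05
  ht2 <- h_test(twin_mix(0.2, 3), op)
  expect_gt(ht2$n_pairs, 1000)
  expect_lt(abs(ht2$alpha - 0.2), 0.05)

  # too few pairs: estimate absent
  small <- twin_mix(0, 4)[1:20, ]
  attr(small, "setting") <- setting
  ht3 <- h_test(small, op)
  expect_false(ht3$ok)
})

test_that("anomalous ratio and crystal volume follow their closed forms", {
  expect_equal(anomalous_ratio(300, data.frame(count = numeric(),
                                               f_pp = numeric())), 0)

  # 316-residue chain with 1 Zn (f'' 3.9) + 3 Ca (f'' 1.4) at the Zn K edge
  thermolysin <- anomalous_ratio(316, data.frame(count = c(1, 3),
                                                 f_pp = c(3.9, 1.4)))
  expect_equal(round(thermolysin), 2)
  expect_equal(thermolysin,
               100 * sqrt(2) * sqrt(1 * 3.9^2 + 3 * 1.4^2) /
                 (6.7 * sqrt(316 * 7.7)),
               tolerance = 1e-12)

  # doubling every atom count scales the ratio by sqrt(2)
  doubled <- anomalous_ratio(316, data.frame(count = c(2, 6),
                                             f_pp = c(3.9, 1.4)))
  expect_equal(doubled, sqrt(2) * thermolysin, tolerance = 1e-12)

  expect_equal(crystal_volume(c(5, 5, 2)), 50)
  expect_error(crystal_volume(c(5, 5)))
})
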