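make_frame <- function(mat, geom) {
  structure(mat, class = c("diffraction_frame", "matrix", "array"),
            geometry = geom)
}

test_that("background estimation converges and rejects outliers", {
  geom <- test_geom()
  shells <- test_shells(geom)

  # constant frame: every shell mean is the constant, no rejections
  const <- make_frame(matrix(7, 160, 160), geom)
  cv <- estimate_background(const, shells)
  expect_equal(cv$b_of_h[cv$usable], rep(7, sum(cv$usable)))

  # constant frame plus 10 isolated hot pixels: hot pixels are clipped out,
  # so the shell means match the median-based oracle
  hot <- matrix(5, 160, 160)
  set.seed(1)
  pos <- sample.int(160 * 160, 10)
  hot[pos] <- 500
  cvh <- estimate_background(make_frame(hot, geom), shells)
  expect_equal(cvh$b_of_h[cvh$usable], rep(5, sum(cvh$usable)))

  # Poisson background: each usable shell within 3 standard errors
  f <- render_frame(frame_recipe(background_level = 20, background_falloff = 0,
                                 n_spots = 0, seed = 17), geom)
  cvp <- estimate_background(f, shells)
  ok <- cvp$usable
  se <- sqrt(20 / cvp$n_pixels[ok])
  # sigma-clipping trims the top Poisson tail a touch, hence the extra slack
  expect_true(all(abs(cvp$b_of_h[ok] - 20) < 3 * se + 0.15))

  # shells with too few pixels are unusable
  tiny_shells <- make_shells(geom, 40, 1 / (0.98 * mxmesh:::max_h(geom)))
  cvt <- estimate_background(const, tiny_shells, min_pixels = 1e5)
  expect_true(all(!cvt$usable))
})

test_that("sharp rings are flagged and flagging is idempotent", {
  geom <- test_geom()
  # smooth monotone background: no flags
  f <- render_frame(frame_recipe(background_level = 30, n_spots = 0, seed = 4),
                    geom)
  cv <- flag_sharp_rings(estimate_background(f, test_shells(geom)))
  expect_equal(sum(cv$flagged), 0)

  # synthetic ice ring at d = 3.44 A: the shell containing h = 1/3.44 flagged
  fi <- render_frame(frame_recipe(background_level = 30, n_spots = 0,
                                  ice_rings = 3.44, seed = 4), geom)
  cvi <- flag_sharp_rings(estimate_background(fi, test_shells(geom)))
  ring_shell <- mxmesh:::shell_index(test_shells(geom), 1 / 3.44)
  expect_true(cvi$flagged[ring_shell])

  # idempotent
  cvi2 <- flag_sharp_rings(cvi)
  expect_identical(cvi$flagged, cvi2$flagged)
})

test_that("spot detection finds planted spots and applies geometric checks", {
  geom <- test_geom()
  shells <- test_shells(geom)

  # single ample Gaussian spot: exactly one detection within 1 px
  base <- matrix(10, 160, 160)
  fp <- mxmesh:::spot_footprint(60.3, 90.7, 5e4, 1.2, 160, 160)
  base[cbind(rep(fp$rows, times = length(fp$cols)),
             rep(fp$cols, each = length(fp$rows)))] <-
    base[cbind(rep(fp$rows, times = length(fp$cols)),
               rep(fp$cols, each = length(fp$rows)))] + as.numeric(fp$values)
  fr <- make_frame(base, geom)
  cv <- estimate_background(fr, shells)
  sp <- find_spots(fr, cv)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 60.3), 1)
  expect_lt(abs(sp$y - 90.7), 1)

  # an elongated streak is rejected by the eccentricity check
  streak <- matrix(10, 160, 160)
  streak[70:71, 40:59] <- 500 # 2 x 20 px
  frs <- make_frame(streak, geom)
  sps <- find_spots(frs, estimate_background(frs, shells))
  expect_equal(nrow(sps), 0)

  # oversized blobs are rejected too
  blob <- matrix(10, 160, 160)
  blob[40:59, 40:59] <- 500 # 400 px
  frb <- make_frame(blob, geom)
  spb <- find_spots(frb, estimate_background(frb, shells))
  expect_equal(nrow(spb), 0)
})

test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE # diagonal neighbour: same component
  m[5, 5] <- TRUE # far away: its own component
  lab <- mxmesh:::label_components_8(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
  expect_equal(length(unique(lab[lab > 0])), 2)
})

test_that("mean spot intensity matches a brute-force oracle", {
  geom <- test_geom()
  shells <- test_shells(geom)
  fr <- render_frame(protein_recipe(seed = 12), geom)
  cv <- flag_sharp_rings(estimate_background(fr, shells))
  sp <- find_spots(fr, cv)
  ib <- mean_spot_intensity(fr, sp, shells)

  # oracle: recompute the azimuthal excess sum over all shell pixels from
  # the label and background matrices
  lab <- attr(sp, "label_matrix")
  bg <- attr(sp, "background_matrix")
  idx <- attr(cv, "shell_raster")
  for (s in which(is.finite(ib$i_bar))) {
    sel <- !is.na(idx) & idx == s
    expect_equal(ib$i_bar[s], sum((unclass(fr) - bg)[sel]) / sum(sel),
                 tolerance = 1e-12)
    expect_gt(sum(lab[sel] > 0), 0) # only spot-bearing shells are reported
  }
  # shells without spot pixels are absent
  for (s in which(!is.finite(ib$i_bar))) {
    sel <- !is.na(idx) & idx == s
    expect_equal(sum(lab[sel] > 0), 0)
  }

  # no spots at all: every shell absent
  f0 <- render_frame(frame_recipe(n_spots = 0, seed = 1), geom)
  cv0 <- estimate_background(f0, shells)
  sp0 <- find_spots(f0, cv0)
  ib0 <- mean_spot_intensity(f0, sp0, shells)
  expect_true(all(!is.finite(ib0$i_bar)))
})

test_that("Wilson fit recovers exact synthetic data and is log-shift invariant", {
  shells <- test_shells()
  h <- mxmesh:::shell_mid_h(shells)
  s2 <- (h / 2)^2
  ib <- tibble::tibble(shell = seq_along(h), h_mid = h,
                       i_bar = 5 * standard_wilson_curve(h) * exp(-2 * 30 * s2),
                       n_spot_pixels = 10L)
  fit <- fit_wilson(ib)
  expect_equal(fit$scale_k, 5, tolerance = 1e-6)
  expect_equal(fit$b_iso, 30, tolerance = 1e-6)
  expect_equal(fit$cc_powder, 1, tolerance = 1e-9)

  # scaling intensities by 10 changes only the scale
  ib10 <- ib
  ib10$i_bar <- ib$i_bar * 10
  fit10 <- fit_wilson(ib10)
  expect_equal(fit10$b_iso, fit$b_iso, tolerance = 1e-9)
  expect_equal(fit10$cc_powder, fit$cc_powder, tolerance = 1e-9)
  expect_equal(fit10$scale_k, 10 * fit$scale_k, tolerance = 1e-6)

  # pure noise: weak correlation in the median seed
  ccs <- vapply(1:20, function(s) {
    set.seed(s)
    ibn <- ib
    ibn$i_bar <- runif(length(h), 0.5, 1.5)
    fit_wilson(ibn)$cc_powder
  }, 0)
  expect_lt(median(abs(ccs)), 0.5)

  # too few shells: absent fit, cc 0
  fit3 <- fit_wilson(ib[1:3, ])
  expect_false(fit3$ok)
  expect_equal(fit3$cc_powder, 0)
})

test_that("the diffraction score obeys the zero rule and linearity", {
  geom <- test_geom()
  shells <- test_shells(geom)

  # no spots -> score exactly zero
  f0 <- render_frame(frame_recipe(n_spots = 0, seed = 3), geom)
  expect_equal(dozor(f0)$score, 0)

  # doubling all mean spot intensities doubles the score at fixed cc
  h <- mxmesh:::shell_mid_h(shells)
  ib <- tibble::tibble(shell = seq_along(h), h_mid = h,
                       i_bar = 3 * standard_wilson_curve(h) *
                         exp(-2 * 25 * (h / 2)^2),
                       n_spot_pixels = 10L)
  fit <- fit_wilson(ib)
  fake_spots <- structure(tibble::tibble(x = 1, y = 1, pixel_count = 5L,
                                         integrated_intensity = 10,
                                         shell = 1L, eccentricity = 0),
                          class = c("spot_table", class(tibble::tibble())))
  s1 <- dozor_score(fake_spots, ib, fit, shells)
  ib2 <- ib
  ib2$i_bar <- 2 * ib$i_bar
  s2 <- dozor_score(fake_spots, ib2, fit_wilson(ib2), shells)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)

  # negative cc is clamped: anti-Wilson profile scores zero
  ib_neg <- ib
  ib_neg$i_bar <- rev(ib$i_bar)
  expect_equal(dozor_score(fake_spots, ib_neg, fit_wilson(ib_neg), shells), 0)
})
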