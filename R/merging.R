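#' Fit relative scales of partial datasets against a reference
#'
#' Each set is modelled against the reference by a linear scale and an
#' isotropic relative Debye-Waller factor:
#' `log I_set = log k - 2 b_rel s^2 + log I_ref`, `s = h/2 = 1/(2d)`.
#' The fit is weighted least squares over the pair's common uniques with
#' weights proportional to the set's `(I/sigma)^2`; records with
#' non-positive intensity on either side are excluded from the log fit.
#' The reference set gets `k = 1, b = 0` by construction.
#'
#' @param sets List of [reflection_set()]s.
#' @param reference Index of the reference set (default 1).
#' @param min_common Minimum usable commons per set (default 10); sets below
#'   it are dropped with a warning.
#' @return Object of class `scale_model`: tibble `set, label, scale_k,
#'   b_rel, n_common, dropped`.
#' @export
fit_scales <- function(sets, reference = 1L, min_common = 10) {
  setting <- attr(sets[[reference]], "setting")
  cell <- setting$cell
  ref_merged <- merge_set_duplicates(sets[[reference]])
  rows <- purrr::map(seq_along(sets), function(i) {
    lab <- as.character(attr(sets[[i]], "label"))
    if (i == reference) {
      return(tibble::tibble(set = i, label = lab, scale_k = 1, b_rel = 0,
                            n_common = nrow(ref_merged), dropped = FALSE))
    }
    m <- merge_set_duplicates(sets[[i]])
    ij <- dplyr::inner_join(ref_merged, m, by = c("h", "k", "l"),
                            suffix = c("_r", "_s"))
    ij <- ij[ij$i_obs_r > 0 & ij$i_obs_s > 0, ]
    if (nrow(ij) < min_common) {
      warning(sprintf("set '%s' shares too few commons with the reference; dropped", lab))
      return(tibble::tibble(set = i, label = lab, scale_k = NA_real_,
                            b_rel = NA_real_, n_common = nrow(ij), dropped = TRUE))
    }
    s2 <- inv_d2(as.matrix(ij[, c("h", "k", "l")]), cell) / 4
    y <- log(ij$i_obs_s) - log(ij$i_obs_r)
    w <- (ij$i_obs_s / ij$sigma_s)^2
    fit <- stats::lm(y ~ s2, weights = w)
    tibble::tibble(
      set = i, label = lab,
      scale_k = exp(unname(stats::coef(fit)[1])),
      b_rel = -unname(stats::coef(fit)[2]) / 2,
      n_common = nrow(ij), dropped = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("scale_model", class(out)), reference = reference)
}

#' Merge scaled partial datasets
#'
#' Every observation is brought to the reference scale by dividing by its
#' set's `k * exp(-2 b_rel s^2)`, indices are reduced to the asymmetric
#' unit, and each unique is merged by the inverse-variance weighted mean
#' with propagated sigma `1 / sqrt(sum w)`.
#'
#' @param sets List of [reflection_set()]s.
#' @param scales A [fit_scales()] model (or NULL to merge unscaled).
#' @return Object of class `merged_dataset`: tibble `h, k, l, d, i_merged,
#'   sigma_merged, n_obs`, with the per-observation scaled table kept in the
#'   `observations` attribute for the statistics stage.
#' @export
merge_datasets <- function(sets, scales = NULL) {
  setting <- attr(sets[[1]], "setting")
  cell <- setting$cell
  obs <- purrr::map(seq_along(sets), function(i) {
    s <- sets[[i]]
    k <- 1; b <- 0
    if (!is.null(scales)) {
      row <- scales[scales$set == i, ]
      if (nrow(row) == 0 || row$dropped) return(NULL)
      k <- row$scale_k; b <- row$b_rel
    }
    asu <- reduce_to_asu(s[, c("h", "k", "l")], setting)
    s2 <- inv_d2(asu, cell) / 4
    corr <- k * exp(-2 * b * s2)
    tibble::tibble(
      h = asu[, 1], k = asu[, 2], l = asu[, 3],
      i_scaled = s$i_obs / corr,
      sigma_scaled = s$sigma / corr,
      set = i
    )
  })
  obs <- dplyr::bind_rows(obs)
  merged <- obs |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(
      i_merged = sum(.data$i_scaled / .data$sigma_scaled^2) /
        sum(1 / .data$sigma_scaled^2),
      sigma_merged = sqrt(1 / sum(1 / .data$sigma_scaled^2)),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  merged$d <- d_spacing(as.matrix(merged[, c("h", "k", "l")]), cell)
  merged <- merged[, c("h", "k", "l", "d", "i_merged", "sigma_merged", "n_obs")]
  structure(merged, class = c("merged_dataset", class(merged)),
            setting = setting, observations = obs)
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("<merged_dataset> %d uniques, multiplicity %.2f\n",
              nrow(x), sum(x$n_obs) / nrow(x)))
  NextMethod()
}

#' Merging quality statistics
#'
#' Standard multi-crystal merging statistics computed from a merged dataset
#' and its contributing observations:
#' completeness (percent of the possible uniques to the truth universe's
#' resolution), multiplicity, `R_merge`, the precision-indicating
#' `R_pim = sum_h sqrt(1/(n_h - 1)) sum_i |I_i - Ibar_h| / sum_h sum_i I_i`
#' (multiplicity-2+ uniques only), half-set correlation `CC_1/2` (mean
#' Pearson correlation of two random half-averages over 10 seeded splits),
#' and mean merged `I/sigma`.
#'
#' @param merged A [merge_datasets()] result.
#' @param n_possible Number of ASU uniques possible to the resolution limit
#'   (e.g. `nrow(truth)`).
#' @param n_half_splits Number of random half-splits averaged for CC_1/2.
#' @param seed Seed for the half-splits.
#' @return Object of class `merge_stats` (a one-row tibble): `completeness`,
#'   `multiplicity`, `r_merge`, `r_pim`, `cc_half`, `mean_i_over_sigma`,
#'   `n_unique`, `n_obs`.
#' @export
compute_stats <- function(merged, n_possible, n_half_splits = 10, seed = 1L) {
  obs <- attr(merged, "observations")
  stopifnot(!is.null(obs), n_possible >= nrow(merged))
  grp <- obs |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::mutate(i_bar = mean(.data$i_scaled), n_h = dplyr::n()) |>
    dplyr::ungroup()

  # merging R factors follow the usual convention: only uniques measured at
  # least twice enter, in the numerator and the denominator alike
  multi <- grp[grp$n_h >= 2, ]
  sum_i <- sum(multi$i_scaled)
  r_merge <- if (nrow(multi) == 0) NA_real_ else {
    sum(abs(multi$i_scaled - multi$i_bar)) / sum_i
  }
  r_pim <- if (nrow(multi) == 0) NA_real_ else {
    num <- multi |>
      dplyr::group_by(.data$h, .data$k, .data$l) |>
      dplyr::summarise(
        dev = sqrt(1 / (dplyr::n() - 1)) * sum(abs(.data$i_scaled - mean(.data$i_scaled))),
        .groups = "drop"
      )
    sum(num$dev) / sum_i
  }

  cc_half <- if (nrow(multi) == 0) NA_real_ else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    grp <- as.integer(factor(paste(multi$h, multi$k, multi$l)))
    vals <- vapply(seq_len(n_half_splits), function(rep) half_split_cc(multi, grp), 0)
    mean(vals, na.rm = TRUE)
  }

  out <- tibble::tibble(
    completeness = 100 * nrow(merged) / n_possible,
    multiplicity = nrow(obs) / nrow(merged),
    r_merge = r_merge,
    r_pim = r_pim,
    cc_half = cc_half,
    mean_i_over_sigma = mean(merged$i_merged / merged$sigma_merged),
    n_unique = nrow(merged),
    n_obs = nrow(obs)
  )
  structure(out, class = c("merge_stats", class(out)))
}

# one random half-split CC: observations of each multi-observed unique are
# split in two halves at random (odd counts put the extra observation in
# the second half); CC of the two half-averages over uniques. Vectorized:
# rows are shuffled, stably re-sorted by unique, and the within-unique
# sequence index decides the half.
half_split_cc <- function(multi, grp) {
  n <- nrow(multi)
  ord <- order(grp, sample.int(n))
  g <- grp[ord]
  i <- multi$i_scaled[ord]
  sizes <- tabulate(g)
  sizes <- sizes[sizes > 0]
  seq_id <- sequence(sizes)
  half <- rep(sizes, sizes) / 2
  pick <- seq_id <= floor(half + 1e-9)
  pick[half < 1] <- FALSE # singletons (should not occur) go to half b
  sum_a <- rowsum(i * pick, g)
  cnt_a <- rowsum(pick * 1, g)
  sum_b <- rowsum(i * !pick, g)
  cnt_b <- rowsum((!pick) * 1, g)
  ok <- cnt_a > 0 & cnt_b > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(sum_a[ok] / cnt_a[ok], sum_b[ok] / cnt_b[ok])
}

#' @method glance merge_stats
#' @export
glance.merge_stats <- function(x, ...) tibble::as_tibble(x)

# divide a set's intensities and sigmas by k * exp(-2 b s^2)
apply_scale <- function(set, k, b) {
  setting <- attr(set, "setting")
  s2 <- inv_d2(as.matrix(set[, c("h", "k", "l")]), setting$cell) / 4
  corr <- k * exp(-2 * b * s2)
  out <- set
  out$i_obs <- set$i_obs / corr
  out$sigma <- set$sigma / corr
  out
}

#' Yeates H-test for merohedral twinning
#'
#' Over twin-related pairs of merged uniques with both intensities positive,
#' `H = |I1 - I2| / (I1 + I2)`. For untwinned acentric data `mean(H) = 1/2`;
#' a twin fraction `alpha` shifts it to `(1 - 2 alpha)/2`, so
#' `alpha = clamp(1/2 - mean(H), 0, 1/2)`.
#'
#' @param merged A [merge_datasets()] result.
#' @param twin_op 3x3 matrix mapping each unique onto its twin mate (for the
#'   shipped presets, the ambiguity operator).
#' @param min_pairs Minimum twin-related pairs required (default 50).
#' @return Object of class `twin_estimate`: list `mean_h`, `alpha`,
#'   `n_pairs`, `ok`.
#' @export
h_test <- function(merged, twin_op, min_pairs = 50) {
  setting <- attr(merged, "setting")
  hkl <- as.matrix(merged[, c("h", "k", "l")])
  mate <- reduce_to_asu(hkl %*% twin_op, setting)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  self_key <- key(reduce_to_asu(hkl, setting))
  mate_key <- key(mate)
  idx <- match(mate_key, self_key)
  ok <- !is.na(idx) & idx != seq_along(idx)
  # each unordered pair once
  first <- ok & seq_along(idx) < idx
  i1 <- merged$i_merged[first]
  i2 <- merged$i_merged[idx[first]]
  pos <- i1 > 0 & i2 > 0
  i1 <- i1[pos]; i2 <- i2[pos]
  if (length(i1) < min_pairs) {
    return(structure(list(mean_h = NA_real_, alpha = NA_real_,
                          n_pairs = length(i1), ok = FALSE),
                     class = "twin_estimate"))
  }
  hvals <- abs(i1 - i2) / (i1 + i2)
  mean_h <- mean(hvals)
  structure(
    list(mean_h = mean_h,
         alpha = min(max(0.5 - mean_h, 0), 0.5),
         n_pairs = length(i1), ok = TRUE),
    class = "twin_estimate"
  )
}

#' @export
print.twin_estimate <- function(x, ...) {
  if (!x$ok) {
    cat(sprintf("<twin_estimate> absent (%d pairs)\n", x$n_pairs))
  } else {
    cat(sprintf("<twin_estimate> mean H = %.3f, alpha = %.3f (%d pairs)\n",
                x$mean_h, x$alpha, x$n_pairs))
  }
  invisible(x)
}

#' Theoretical anomalous diffraction ratio
#'
#' Crick-Magdoff-style estimate of the expected relative Bijvoet difference
#' `<dF/F>` for a protein of `n_residues` residues containing the given
#' anomalous scatterers, in percent:
#' `100 * sqrt(2) * sqrt(sum count * f''^2) / (Z_eff * sqrt(n_residues * atoms_per_residue))`
#' with the light-atom constants `Z_eff = 6.7` effective electrons and 7.7
#' non-hydrogen atoms per residue.
#'
#' @param n_residues Number of residues in the chain.
#' @param anom_atoms Data frame (or tibble) with columns `count` and `f_pp`
#'   (f'' in electrons at the measurement energy); empty gives 0.
#' @param z_eff,atoms_per_residue The light-atom constants.
#' @return Ratio in percent.
#' @examples
#' # one catalytic Zn (f'' = 3.9 e at its K edge) and three Ca (f'' = 1.4 e)
#' # in a 316-residue chain:
#' anomalous_ratio(316, data.frame(count = c(1, 3), f_pp = c(3.9, 1.4)))
#' @export
anomalous_ratio <- function(n_residues, anom_atoms,
                            z_eff = 6.7, atoms_per_residue = 7.7) {
  stopifnot(n_residues > 0)
  if (is.null(anom_atoms) || nrow(anom_atoms) == 0) return(0)
  stopifnot(all(c("count", "f_pp") %in% names(anom_atoms)))
  100 * sqrt(2) * sqrt(sum(anom_atoms$count * anom_atoms$f_pp^2)) /
    (z_eff * sqrt(n_residues * atoms_per_residue))
}

#' Rectangular-prism crystal volume
#'
#' Average crystal volume from average linear dimensions, e.g. plate-like
#' microcrystals of ~5 x 5 x 2 micrometres have a volume of ~50 um^3.
#'
#' @param dims_um Numeric vector of edge lengths in micrometres.
#' @return Volume in cubic micrometres.
#' @export
crystal_volume <- function(dims_um) {
  stopifnot(length(dims_um) == 3, all(dims_um > 0))
  prod(dims_um)
}
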