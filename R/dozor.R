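#' Iterative azimuthal background estimation
#'
#' Estimates the one-dimensional background function `B(h)`: pixels are binned
#' into resolution shells and each shell's mean is computed by iterative
#' sigma-clipping — pixels more than `k_rej` standard deviations above the
#' running mean are rejected and the mean/sd recomputed until the rejection
#' set is stable (or `max_iter` passes). Shells with fewer than `min_pixels`
#' pixels are marked unusable.
#'
#' @param frame A `diffraction_frame` (or plain matrix with a `geometry`
#'   attribute).
#' @param shells A [make_shells()] binning sharing the frame's geometry.
#' @param k_rej Rejection threshold in standard deviations (default 3).
#' @param max_iter Maximum clipping iterations (default 10).
#' @param min_pixels Minimum usable pixels per shell (default 50).
#' @param exclude Optional logical matrix of pixels to leave out entirely
#'   (e.g. a dilated mask of already-detected spots, for a refinement pass).
#' @param truncation_z When `exclude` was built by thresholding at
#'   `z` background sigmas, the surviving sample is upper-truncated and its
#'   mean biased low by `sigma * dnorm(z) / pnorm(z)`; passing `z` applies
#'   the analytic correction.
#' @return Object of class `background_curve`: a tibble with one row per
#'   shell (`shell`, `h_mid`, `b_of_h`, `n_pixels`, `usable`, `flagged`,
#'   `flag_reason`) carrying the shells and the per-pixel shell raster as
#'   attributes.
#' @export
estimate_background <- function(frame, shells, k_rej = 3, max_iter = 10,
                                min_pixels = 50, exclude = NULL,
                                truncation_z = NULL) {
  geom <- attr(frame, "geometry")
  stopifnot(!is.null(geom), inherits(shells, "shell_binning"))
  hmap <- resolution_raster(geom)
  idx <- shell_index(shells, hmap)
  n_shell <- length(shells$volumes)
  vals <- as.numeric(frame)
  use_px <- if (is.null(exclude)) rep(TRUE, length(vals)) else !as.logical(exclude)
  b <- rep(NA_real_, n_shell)
  npix <- integer(n_shell)
  usable <- logical(n_shell)
  for (s in seq_len(n_shell)) {
    in_s <- !is.na(idx) & idx == s
    npix[s] <- sum(in_s) # total shell pixels (normalization constant N(h))
    x <- vals[in_s & use_px]
    if (length(x) < min_pixels) next
    keep <- rep(TRUE, length(x))
    for (it in seq_len(max_iter)) {
      m <- mean(x[keep])
      sd_ <- stats::sd(x[keep])
      if (!is.finite(sd_) || sd_ == 0) break
      new_keep <- x <= m + k_rej * sd_
      if (identical(new_keep, keep)) break
      keep <- new_keep
      if (!any(keep)) { keep <- rep(TRUE, length(x)); break }
    }
    b[s] <- mean(x[keep])
    usable[s] <- TRUE
  }
  if (!is.null(truncation_z)) {
    corr <- stats::dnorm(truncation_z) / stats::pnorm(truncation_z)
    b <- b + corr * sqrt(pmax(b, 0))
  }
  # raw azimuthal mean over all shell pixels; its excess over the clipped
  # mean carries spot + ring + salt flux and feeds the sharp-ring detector
  raw <- rep(NA_real_, n_shell)
  all_in <- !is.na(idx)
  sums <- tapply(vals[all_in], idx[all_in], mean)
  raw[as.integer(names(sums))] <- as.numeric(sums)
  ring_h <- fine_ring_profile(vals, hmap, max(shells$edges))
  out <- tibble::tibble(
    shell = seq_len(n_shell),
    h_mid = shell_mid_h(shells),
    b_of_h = b,
    excess_mean = raw - b,
    n_pixels = npix,
    usable = usable,
    flagged = FALSE,
    flag_reason = NA_character_
  )
  structure(out, class = c("background_curve", class(out)),
            shells = shells, shell_raster = idx, geometry = geom,
            ring_intervals = ring_h)
}

# fine-grained powder-ring scan: equal-h bins (much narrower than the
# scoring shells), per-bin pixel MEDIAN (robust to Bragg spots, sensitive
# to an annulus that elevates a whole bin), compared with a moving-median
# smoothed reference; returns the h intervals of ring-like bins
fine_ring_profile <- function(vals, hmap, h_max, n_bins = 150,
                              factor = 1.4, min_px = 40) {
  edges <- seq(0, h_max, length.out = n_bins + 1)
  bin <- findInterval(as.numeric(hmap), edges, left.open = TRUE)
  ok <- bin >= 1 & bin <= n_bins
  med <- rep(NA_real_, n_bins)
  cnt <- tabulate(bin[ok], n_bins)
  meds <- tapply(vals[ok], bin[ok], stats::median)
  med[as.integer(names(meds))] <- as.numeric(meds)
  med[cnt < min_px] <- NA
  smooth <- moving_median(med, 9)
  hot <- which(is.finite(med) & is.finite(smooth) &
                 med > pmax(factor * smooth, smooth + 2))
  if (length(hot) == 0) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("h_lo", "h_hi"))))
  }
  cbind(h_lo = edges[hot], h_hi = edges[hot + 1])
}

#' Flag sharp rings in a background curve
#'
#' The azimuthally averaged intensity of a macromolecular frame varies
#' smoothly with resolution; a sharp per-shell excess indicates an ice ring
#' or salt diffraction, and such shells are excluded from the Wilson fit and
#' the score. Two complementary tests are applied, both against a
#' moving-median smoothed reference over neighbouring shells:
#' a spike in the clipped background `b_of_h` (a broad ring that dominates
#' its shell), and a spike in the excess mean (raw minus clipped azimuthal
#' mean: a narrow ring or strong salt spots survive sigma-clipping and show
#' up here). The excess test is restricted to shells at `h >= 0.2` (d below
#' 5 Angstrom) — ice and salt powder rings live there, while at lower
#' resolution the protein signal itself falls too steeply to be called
#' smooth. Idempotent: a second pass adds no flags.
#'
#' @param curve A `background_curve`.
#' @param ring_factor Multiplicative threshold on the clipped background
#'   (default 1.5).
#' @param excess_factor Multiplicative threshold on the excess mean
#'   (default 2.5): the excess curve is dominated by Wilson-statistic
#'   fluctuations of a handful of spots per shell, so its spike criterion
#'   is stricter.
#' @param window Moving-median window in shells (odd, default 5).
#' @return The curve with `flagged`/`flag_reason` updated.
#' @export
flag_sharp_rings <- function(curve, ring_factor = 1.5, excess_factor = 2.5,
                             window = 5) {
  stopifnot(inherits(curve, "background_curve"))
  ok <- curve$usable & !curve$flagged
  if (sum(ok) < 5) return(curve)
  b <- curve$b_of_h
  b_ref <- b
  b_ref[!ok] <- NA
  smoothed <- moving_median(b_ref, window)
  flag_b <- ok & is.finite(smoothed) & smoothed > 0 & b > ring_factor * smoothed
  ex <- curve$excess_mean
  ex_ref <- ex
  ex_ref[!ok] <- NA
  ex_smooth <- moving_median(ex_ref, window)
  flag_ex <- ok & curve$h_mid >= 0.2 & is.finite(ex) & is.finite(ex_smooth) &
    ex > pmax(excess_factor * ex_smooth, 1, 0.2 * b)
  # shells overlapping a ring interval from the fine powder-ring scan
  flag_ring <- rep(FALSE, nrow(curve))
  rings <- attr(curve, "ring_intervals")
  if (!is.null(rings) && nrow(rings) > 0) {
    shells <- attr(curve, "shells")
    lo <- shells$edges[-length(shells$edges)]
    hi <- shells$edges[-1]
    for (r in seq_len(nrow(rings))) {
      flag_ring <- flag_ring | (lo < rings[r, "h_hi"] & hi > rings[r, "h_lo"])
    }
    flag_ring <- flag_ring & ok
  }
  new_flag <- flag_b | flag_ex | flag_ring
  curve$flagged <- curve$flagged | new_flag
  curve$flag_reason[new_flag & flag_ring] <- "ring"
  curve$flag_reason[new_flag & flag_b & !flag_ring] <- "background_spike"
  curve$flag_reason[new_flag & !flag_b & !flag_ring] <- "excess_spike"
  curve
}

# running median ignoring NAs, window w (odd), edges use truncated windows
moving_median <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    xi <- x[setdiff(lo:hi, i)]
    xi <- xi[is.finite(xi)]
    if (length(xi) > 0) out[i] <- stats::median(xi)
  }
  out
}

#' Detect Bragg spots
#'
#' Thresholds pixels at `B(h) + k_spot * sqrt(B(h))` (Poisson noise model on
#' the shell background), labels 8-connected components, and keeps components
#' passing simple geometric checks: `min_pixels <= size <= max_pixels`,
#' eccentricity at most `ecc_max`, and centroid not on a flagged shell.
#' Integrated intensity is the sum of pixel counts above the local shell
#' background.
#'
#' @param frame The frame the curve was computed on.
#' @param curve Its `background_curve` (ring-flagged or not).
#' @param k_spot Threshold in Poisson sigmas (default 4).
#' @param min_pixels,max_pixels Component size limits (defaults 2 and 100).
#' @param ecc_max Maximum eccentricity (default 0.95); elongated streaks are
#'   rejected.
#' @return Object of class `spot_table`: a tibble with one spot per row
#'   (`x`, `y` centroid in 0-based pixels, `pixel_count`,
#'   `integrated_intensity`, `shell`, `eccentricity`), carrying the per-pixel
#'   label matrix and the background used as attributes.
#' @export
find_spots <- function(frame, curve, k_spot = 4, min_pixels = 2,
                       max_pixels = 100, ecc_max = 0.95) {
  stopifnot(inherits(curve, "background_curve"))
  idx <- attr(curve, "shell_raster")
  shells <- attr(curve, "shells")
  b_shell <- curve$b_of_h
  bg <- matrix(NA_real_, nrow = nrow(frame), ncol = ncol(frame))
  in_shell <- !is.na(idx)
  bg[in_shell] <- b_shell[idx[in_shell]]
  thresh <- bg + k_spot * sqrt(pmax(bg, 0))
  mask <- !is.na(thresh) & unclass(frame) > thresh
  if (!any(mask)) return(empty_spot_table(frame, curve, bg))

  lab <- label_components_8(mask)
  labs <- as.integer(lab)
  keep <- labs > 0L
  df <- data.frame(
    label = labs[keep],
    row = ((seq_along(labs) - 1L) %% nrow(frame))[keep] + 1L,
    col = ((seq_along(labs) - 1L) %/% nrow(frame))[keep] + 1L,
    val = as.numeric(frame)[keep],
    bg = as.numeric(bg)[keep]
  )
  sp <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      pixel_count = dplyr::n(),
      x = mean(.data$col - 1), # fast axis, 0-based
      y = mean(.data$row - 1),
      integrated_intensity = sum(.data$val - .data$bg),
      ecc = component_eccentricity(.data$col, .data$row),
      .groups = "drop"
    )
  cen_h <- pixel_resolution(attr(curve, "geometry"), sp$x, sp$y)
  sp$shell <- shell_index(shells, cen_h)
  flagged_shells <- which(curve$flagged | !curve$usable)
  ok <- sp$pixel_count >= min_pixels & sp$pixel_count <= max_pixels &
    sp$ecc <= ecc_max & !is.na(sp$shell) & !(sp$shell %in% flagged_shells) &
    sp$integrated_intensity > 0
  sp <- sp[ok, , drop = FALSE]
  kept_labels <- sp$label
  lab[!(lab %in% kept_labels)] <- 0L

  out <- tibble::tibble(
    x = sp$x, y = sp$y,
    pixel_count = as.integer(sp$pixel_count),
    integrated_intensity = sp$integrated_intensity,
    shell = as.integer(sp$shell),
    eccentricity = sp$ecc
  )
  structure(out, class = c("spot_table", class(out)),
            label_matrix = lab, background_matrix = bg,
            curve = curve)
}

# binary dilation of a logical matrix with a (2r+1)-square structuring
# element, by accumulating shifted copies
dilate_mask <- function(mask, radius = 3L) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      sr <- max(1, 1 + dr):min(nr, nr + dr)
      tr <- max(1, 1 - dr):min(nr, nr - dr)
      sc <- max(1, 1 + dc):min(nc, nc + dc)
      tc <- max(1, 1 - dc):min(nc, nc - dc)
      out[tr, tc] <- out[tr, tc] | mask[sr, sc]
    }
  }
  out
}

# 8-connected component labelling of a logical mask; returns an integer
# matrix with 0 for background and 1..k component ids. Built on graph
# components over neighbour pairs of mask pixels (masks here are sparse).
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  on_idx <- which(mask)
  if (length(on_idx) == 0) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[on_idx] <- seq_along(on_idx)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- ((on_idx - 1L) %% nr) + 1L
  cols <- ((on_idx - 1L) %/% nr) + 1L
  edges <- list()
  k <- 0L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    sel <- nb > 0L
    if (!any(sel)) next
    k <- k + 1L
    edges[[k]] <- cbind(id[on_idx][ok][sel], nb[sel])
  }
  if (k == 0L) {
    lab[on_idx] <- seq_along(on_idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(on_idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(on_idx)]
  lab[on_idx] <- as.integer(comp)
  lab
}

empty_spot_table <- function(frame, curve, bg) {
  out <- tibble::tibble(
    x = numeric(), y = numeric(), pixel_count = integer(),
    integrated_intensity = numeric(), shell = integer(),
    eccentricity = numeric()
  )
  structure(out, class = c("spot_table", class(out)),
            label_matrix = matrix(0L, nrow(frame), ncol(frame)),
            background_matrix = bg, curve = curve)
}

# eccentricity from the second central moments of a pixel set:
# sqrt(1 - lambda_min/lambda_max) of the 2x2 covariance; 0 for single pixels
component_eccentricity <- function(cols, rows) {
  if (length(cols) < 2) return(0)
  cv <- stats::cov(cbind(cols, rows))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1] <= 0) return(0)
  sqrt(1 - ev[2] / ev[1])
}

#' Mean Bragg-spot intensity per resolution shell
#'
#' For each usable, unflagged shell that contains at least one detected
#' spot pixel: the azimuthal mean of background-subtracted counts over all
#' `N(h)` detector pixels of the shell,
#' `Ibar(h) = sum over shell pixels of (I_ij - B(h)) / N(h)`.
#' Summing over the whole shell (rather than over detected spot pixels
#' alone) makes the estimate an unbiased measure of the total Bragg flux
#' per unit detector area: faint spots below the detection threshold still
#' contribute their counts, so high-resolution shells are not biased toward
#' the brightest survivors. Shells without detected spot pixels are treated
#' as signal-free and get `NA`.
#'
#' @param frame The frame.
#' @param spots A `spot_table` from [find_spots()].
#' @param shells The shell binning.
#' @return Tibble: `shell`, `h_mid`, `i_bar` (counts/pixel), `n_spot_pixels`.
#' @export
mean_spot_intensity <- function(frame, spots, shells) {
  stopifnot(inherits(spots, "spot_table"))
  curve <- attr(spots, "curve")
  lab <- attr(spots, "label_matrix")
  bg <- attr(spots, "background_matrix")
  idx <- attr(curve, "shell_raster")
  n_shell <- length(shells$volumes)
  i_bar <- rep(NA_real_, n_shell)
  n_px <- integer(n_shell)
  sel <- lab > 0L & !is.na(idx)
  if (any(sel)) {
    # spot-pixel bookkeeping decides which shells carry signal at all
    sh_spot <- idx[sel]
    cnts <- tapply(sh_spot, sh_spot, length)
    s_idx <- as.integer(names(cnts))
    n_px[s_idx] <- as.integer(cnts)
    # azimuthal excess over the whole shell, normalized by its pixel count
    all_in <- !is.na(idx)
    excess_all <- (unclass(frame) - bg)[all_in]
    sums_all <- tapply(excess_all, idx[all_in], sum)
    shell_of_sum <- as.integer(names(sums_all))
    keep <- shell_of_sum %in% s_idx
    i_bar[shell_of_sum[keep]] <-
      as.numeric(sums_all)[keep] / curve$n_pixels[shell_of_sum[keep]]
  }
  bad <- curve$flagged | !curve$usable
  i_bar[bad] <- NA_real_
  n_px[bad] <- 0L
  tibble::tibble(
    shell = seq_len(n_shell),
    h_mid = shell_mid_h(shells),
    i_bar = i_bar,
    n_spot_pixels = n_px
  )
}

#' Fit the Wilson model to per-shell mean spot intensities
#'
#' Least-squares fit, linear in the log, of
#' `log Ibar(h) = log k - 2 B s^2 + log Sigma_p(h)` with `s = h/2` and
#' `Sigma_p` the [standard_wilson_curve()]. The fit quality `cc_powder` is
#' the Pearson correlation between observed and fitted `log Ibar(h)` over
#' the shells used. Fewer than `min_shells` usable shells yields an absent
#' fit with `cc_powder = 0`.
#'
#' @param ibar Tibble from [mean_spot_intensity()] (or any tibble with
#'   `h_mid` and `i_bar`).
#' @param min_shells Minimum shells with positive `i_bar` (default 4).
#' @return Object of class `wilson_fit`: list with `scale_k`, `b_iso`
#'   (Angstrom^2), `cc_powder`, `n_shells_used`, `data` (per-shell observed
#'   and fitted log intensities), `ok`.
#' @export
fit_wilson <- function(ibar, min_shells = 4) {
  use <- is.finite(ibar$i_bar) & ibar$i_bar > 0
  if (sum(use) < min_shells) {
    return(structure(
      list(scale_k = NA_real_, b_iso = NA_real_, cc_powder = 0,
           n_shells_used = sum(use), data = ibar[0, ], ok = FALSE),
      class = "wilson_fit"
    ))
  }
  h <- ibar$h_mid[use]
  s2 <- (h / 2)^2
  y <- log(ibar$i_bar[use]) - log(standard_wilson_curve(h))
  fit <- stats::lm(y ~ s2)
  k <- exp(unname(stats::coef(fit)[1]))
  b <- -unname(stats::coef(fit)[2]) / 2
  if (b < 0) {
    # a crystal cannot be sharper than the standard curve: clamp B at 0 and
    # refit the scale alone, so resolution-flat signal (salt) cannot
    # masquerade as a well-fitting negative-B Wilson model
    b <- 0
    k <- exp(mean(y))
    fit <- NULL
  }
  fitted_log <- log(k) - 2 * b * s2 + log(standard_wilson_curve(h))
  obs_log <- log(ibar$i_bar[use])
  cc <- if (stats::sd(obs_log) > 0 && stats::sd(fitted_log) > 0) {
    stats::cor(obs_log, fitted_log)
  } else 0
  structure(
    list(
      scale_k = k, b_iso = b, cc_powder = cc,
      n_shells_used = sum(use),
      data = tibble::tibble(
        shell = ibar$shell[use], h_mid = h,
        log_ibar = obs_log, log_fit = fitted_log
      ),
      ok = TRUE
    ),
    class = "wilson_fit"
  )
}

#' @export
print.wilson_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<wilson_fit> absent (too few shells)\n")
  } else {
    cat(sprintf("<wilson_fit> k = %.4g, B = %.4g A^2, CC_powder = %.3f (%d shells)\n",
                x$scale_k, x$b_iso, x$cc_powder, x$n_shells_used))
  }
  invisible(x)
}

#' @method tidy wilson_fit
#' @export
tidy.wilson_fit <- function(x, ...) {
  tibble::tibble(
    term = c("scale_k", "b_iso", "cc_powder"),
    estimate = c(x$scale_k, x$b_iso, x$cc_powder)
  )
}

#' Score one diffraction frame
#'
#' The full per-frame scoring chain: background estimation, sharp-ring
#' flagging, spot detection, per-shell mean spot intensity, Wilson-model fit,
#' and the diffraction-strength score
#' `score = max(CC_powder, 0) * sum over unflagged spot-bearing shells of
#' Ibar(h) * V(h)`, with `V(h)` the reciprocal volume of the shell. A frame
#' in which no Bragg spots are found scores exactly zero.
#'
#' @param frame A `diffraction_frame`.
#' @param shells A [make_shells()] binning (default: 24 equal-volume shells
#'   to the detector-corner resolution, slightly inset).
#' @param k_rej,k_spot,min_spot_pixels,max_spot_pixels,ecc_max,ring_factor
#'   Tuning knobs passed to the component stages.
#' @return Object of class `dozor_result`: list with `score`, `background`,
#'   `spots`, `ibar`, `fit`, `n_spots`.
#' @examples
#' geom <- detector_geometry(180, 0.2, c(80, 80), 1.0, 160, 160)
#' fr <- render_frame(frame_recipe(n_spots = 120, spot_scale = 4000, seed = 7), geom)
#' res <- dozor(fr)
#' res$score
#' @export
dozor <- function(frame, shells = NULL, k_rej = 3, k_spot = 4,
                  min_spot_pixels = 2, max_spot_pixels = 100,
                  ecc_max = 0.95, ring_factor = 1.5) {
  geom <- attr(frame, "geometry")
  if (is.null(shells)) {
    shells <- make_shells(geom, 24, 1 / (0.98 * max_h(geom)))
  }
  # pass 1: background and provisional spots
  curve <- estimate_background(frame, shells, k_rej = k_rej)
  curve <- flag_sharp_rings(curve, ring_factor = ring_factor)
  spots <- find_spots(frame, curve, k_spot = k_spot,
                      min_pixels = min_spot_pixels,
                      max_pixels = max_spot_pixels, ecc_max = ecc_max)
  # pass 2: re-estimate the background with signal-bearing pixels excluded,
  # so spot flux (including spots too faint for full detection) cannot leak
  # into the background and flatten the excess at high resolution; the
  # exclusion threshold sits below the detection threshold on purpose
  if (nrow(spots) > 0) {
    bg_mat <- attr(spots, "background_matrix")
    excl <- !is.na(bg_mat) &
      unclass(frame) > bg_mat + 2.5 * sqrt(pmax(bg_mat, 0))
    excl <- dilate_mask(excl, radius = 2L)
    curve <- estimate_background(frame, shells, k_rej = k_rej, exclude = excl,
                                 truncation_z = 2.5)
    curve <- flag_sharp_rings(curve, ring_factor = ring_factor)
    spots <- find_spots(frame, curve, k_spot = k_spot,
                        min_pixels = min_spot_pixels,
                        max_pixels = max_spot_pixels, ecc_max = ecc_max)
  }
  ibar <- mean_spot_intensity(frame, spots, shells)
  fit <- fit_wilson(ibar)
  score <- dozor_score(spots, ibar, fit, shells, curve)
  structure(
    list(score = score, background = curve, spots = spots,
         ibar = ibar, fit = fit, n_spots = nrow(spots)),
    class = "dozor_result"
  )
}

#' Diffraction-strength score from scored components
#'
#' `score = max(CC_powder, 0) * sum of Ibar(h) V(h)` over spot-bearing
#' shells. Shells dropped for contamination (flagged rings/salt, or left
#' without a usable background) that lie inside the spot-bearing resolution
#' range are imputed from the fitted Wilson model when a fit is available:
#' the protein signal under an ice ring is real, and imputing it keeps the
#' score stable under ring contamination instead of docking the frame for
#' its flagged shells.
#'
#' @param spots `spot_table`; an empty table forces score 0.
#' @param ibar Per-shell mean spot intensities.
#' @param fit `wilson_fit`.
#' @param shells Shell binning supplying `V(h)`.
#' @param curve Optional `background_curve` used to identify contaminated
#'   shells for imputation.
#' @return Non-negative scalar score.
#' @export
dozor_score <- function(spots, ibar, fit, shells, curve = NULL) {
  if (nrow(spots) == 0) return(0)
  cc <- max(fit$cc_powder, 0)
  vals <- ibar$i_bar
  use <- is.finite(vals)
  if (!is.null(curve) && fit$ok && any(use)) {
    rng <- range(ibar$shell[use])
    impute <- (curve$flagged | !curve$usable) & !use &
      ibar$shell >= rng[1] & ibar$shell <= rng[2]
    if (any(impute)) {
      h <- ibar$h_mid[impute]
      vals[impute] <- fit$scale_k * standard_wilson_curve(h) *
        exp(-2 * fit$b_iso * (h / 2)^2)
      use <- use | impute
    }
  }
  total <- sum(vals[use] * shells$volumes[use])
  max(cc * total, 0)
}

#' @export
print.dozor_result <- function(x, ...) {
  cat(sprintf("<dozor_result> score = %.4g, %d spots, CC_powder = %.3f, B = %.3g A^2\n",
              x$score, x$n_spots, x$fit$cc_powder,
              if (is.null(x$fit$b_iso)) NA else x$fit$b_iso))
  invisible(x)
}

#' @method glance dozor_result
#' @export
glance.dozor_result <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_spots = x$n_spots,
    cc_powder = x$fit$cc_powder,
    b_iso = x$fit$b_iso,
    scale_k = x$fit$scale_k
  )
}

#' Score every frame of a mesh stack
#'
#' @param stack A `mesh_stack`.
#' @param shells Optional shared [make_shells()] binning (by default 24
#'   equal-volume shells to just inside the detector corner).
#' @param ... Passed to [dozor()].
#' @return Tibble with one row per frame in raster order: `frame`, `row`,
#'   `col`, `score`, `n_spots`, `cc_powder`, `b_iso`.
#' @export
score_stack <- function(stack, shells = NULL, ...) {
  if (is.null(shells)) {
    shells <- make_shells(stack$geometry, 24, 1 / (0.98 * max_h(stack$geometry)))
  }
  res <- purrr::map(stack$frames, dozor, shells = shells, ...)
  tibble::tibble(
    frame = seq_along(res) - 1L,
    row = rep(seq_len(stack$n_y), each = stack$n_x),
    col = rep(seq_len(stack$n_x), times = stack$n_y),
    score = purrr::map_dbl(res, "score"),
    n_spots = purrr::map_int(res, "n_spots"),
    cc_powder = purrr::map_dbl(res, ~ .x$fit$cc_powder),
    b_iso = purrr::map_dbl(res, ~ ifelse(is.null(.x$fit$b_iso), NA_real_, .x$fit$b_iso))
  )
}
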