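# ---- symmetry settings -----------------------------------------------------

# generate the closure of a set of integer 3x3 generators acting on row
# vectors (h,k,l) -> hkl %*% M; small point groups only
group_closure <- function(generators) {
  eye <- diag(3)
  ops <- list(eye)
  keys <- paste(eye, collapse = ",")
  queue <- generators
  while (length(queue) > 0) {
    m <- queue[[1]]
    queue <- queue[-1]
    key <- paste(m, collapse = ",")
    if (key %in% keys) next
    ops <- c(ops, list(m))
    keys <- c(keys, key)
    for (o in ops) {
      for (p in list(m %*% o, o %*% m)) {
        if (!(paste(p, collapse = ",") %in% keys)) queue <- c(queue, list(p))
      }
    }
  }
  ops
}

#' Symmetry setting
#'
#' A unit cell plus an explicit list of reciprocal-space point-group
#' operators (integer 3x3 matrices acting on row vectors `(h,k,l)`), a
#' Friedel flag, and the operators relating alternative indexing choices
#' (merohedral ambiguity operators). Use [symmetry_preset()] for the shipped
#' settings.
#'
#' @param cell Numeric length-6: `a, b, c` (Angstrom), `alpha, beta, gamma`
#'   (degrees).
#' @param operators List of integer 3x3 matrices; the identity is added if
#'   missing.
#' @param friedel Treat `(h,k,l)` and `(-h,-k,-l)` as equivalent (default
#'   TRUE).
#' @param ambiguity_ops List of 3x3 matrices relating alternative indexings
#'   (may be empty).
#' @param name Optional label.
#' @return Object of class `symmetry_setting`.
#' @export
symmetry_setting <- function(cell, operators, friedel = TRUE,
                             ambiguity_ops = list(), name = "custom") {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0), all(cell[4:6] > 0))
  keys <- vapply(operators, function(m) paste(m, collapse = ","), "")
  if (!(paste(diag(3), collapse = ",") %in% keys)) {
    operators <- c(list(diag(3)), operators)
  }
  structure(
    list(cell = as.numeric(cell), operators = operators,
         friedel = isTRUE(friedel), ambiguity_ops = ambiguity_ops,
         name = name),
    class = "symmetry_setting"
  )
}

#' Shipped symmetry presets
#'
#' Explicit operator lists for the point-group families relevant to
#' multi-crystal merging experiments:
#' \describe{
#'   \item{`"P1"`}{triclinic, identity only.}
#'   \item{`"P2"`}{monoclinic point group 2 (b unique).}
#'   \item{`"P4"`}{tetragonal point group 4, with merohedral ambiguity
#'     operator `(k, h, -l)`.}
#'   \item{`"P6"`}{hexagonal point group 6, with ambiguity operator
#'     `(k, h, -l)`.}
#'   \item{`"H3"`}{rhombohedral (hexagonal setting) point group 3, with its
#'     twofold ambiguity operator `(k, h, -l)`.}
#' }
#'
#' @param name Preset name.
#' @param cell Optional unit cell override (defaults are plausible cells of
#'   the family).
#' @return A [symmetry_setting()].
#' @export
symmetry_preset <- function(name = c("P1", "P2", "P4", "P6", "H3"),
                            cell = NULL) {
  name <- match.arg(name)
  op <- function(...) matrix(as.integer(c(...)), 3, 3, byrow = TRUE)
  swap_ab <- op(0, 1, 0, 1, 0, 0, 0, 0, -1) # (h,k,l) -> (k,h,-l)
  spec <- switch(name,
    P1 = list(cell = c(30, 40, 50, 80, 95, 100), gens = list(), amb = list()),
    P2 = list(cell = c(40, 50, 60, 90, 105, 90),
              gens = list(op(-1, 0, 0, 0, 1, 0, 0, 0, -1)), amb = list()),
    P4 = list(cell = c(60, 60, 90, 90, 90, 90),
              gens = list(op(0, 1, 0, -1, 0, 0, 0, 0, 1)),
              amb = list(swap_ab)),
    P6 = list(cell = c(60, 60, 90, 90, 90, 120),
              gens = list(op(0, 1, 0, -1, 1, 0, 0, 0, 1)),
              amb = list(swap_ab)),
    H3 = list(cell = c(60, 60, 150, 90, 90, 120),
              gens = list(op(-1, 1, 0, -1, 0, 0, 0, 0, 1)),
              amb = list(swap_ab))
  )
  if (is.null(cell)) cell <- spec$cell
  symmetry_setting(cell, group_closure(spec$gens), friedel = TRUE,
                   ambiguity_ops = spec$amb, name = name)
}

#' @export
print.symmetry_setting <- function(x, ...) {
  cat(sprintf("<symmetry_setting> %s: %d operators%s, %d ambiguity op(s)\n",
              x$name, length(x$operators),
              if (x$friedel) " (+Friedel)" else "", length(x$ambiguity_ops)))
  invisible(x)
}

# 1/d^2 for hkl rows under a general triclinic cell (metric-tensor form)
inv_d2 <- function(hkl, cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  G <- matrix(c(
    a * a, a * b * cos(ga), a * c_ * cos(be),
    a * b * cos(ga), b * b, b * c_ * cos(al),
    a * c_ * cos(be), b * c_ * cos(al), c_ * c_
  ), 3, 3)
  Gstar <- solve(G)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  rowSums((hkl %*% Gstar) * hkl)
}

#' d-spacings of Miller indices
#'
#' @param hkl Integer matrix (or data frame) with columns h, k, l.
#' @param cell Unit cell, length 6.
#' @return d in Angstrom.
#' @export
d_spacing <- function(hkl, cell) {
  1 / sqrt(inv_d2(as.matrix(hkl[, 1:3]), cell))
}

#' Reduce Miller indices to asymmetric-unit representatives
#'
#' Applies every point-group operator (and the Friedel mate when the setting
#' is centric-equivalent) to each index and returns the lexicographically
#' greatest image (compare h, then k, then l). Idempotent and constant on
#' symmetry orbits.
#'
#' @param hkl Integer matrix / data frame with columns h, k, l (rows are
#'   reflections).
#' @param setting A [symmetry_setting()].
#' @return Integer matrix of the same shape with canonical indices.
#' @export
reduce_to_asu <- function(hkl, setting) {
  stopifnot(inherits(setting, "symmetry_setting"))
  m <- as.matrix(hkl[, 1:3, drop = FALSE])
  storage.mode(m) <- "double"
  ops <- setting$operators
  if (setting$friedel) {
    ops <- c(ops, lapply(setting$operators, function(o) -o))
  }
  best <- m %*% ops[[1]]
  for (o in ops[-1]) {
    cand <- m %*% o
    repl <- cand[, 1] > best[, 1] |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
    best[repl, ] <- cand[repl, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

# ---- reflection sets -------------------------------------------------------

#' Construct a reflection set
#'
#' A reflection set is a tibble of `(h, k, l, i_obs, sigma)` records carrying
#' its [symmetry_setting()], a source label and (for simulated sets) the
#' planted isomorphism class as attributes.
#'
#' @param records Data frame with columns `h, k, l, i_obs, sigma`.
#' @param setting A [symmetry_setting()].
#' @param label Source identifier (e.g. grid position).
#' @param true_class Optional planted class label.
#' @param wavelength X-ray wavelength recorded in file headers (Angstrom).
#' @return Object of class `reflection_set` (a tibble).
#' @export
reflection_set <- function(records, setting, label = "set",
                           true_class = NA, wavelength = 1.0) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("h", "k", "l", "i_obs", "sigma") %in% names(records)))
  if (any(records$sigma <= 0)) stop("all sigma values must be positive")
  structure(
    records,
    class = c("reflection_set", class(tibble::tibble())),
    setting = setting, label = label, true_class = true_class,
    wavelength = wavelength
  )
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> '%s': %d records, %s\n",
              attr(x, "label"), nrow(x), attr(x, "setting")$name))
  NextMethod()
}

# per-set merge of symmetry-equivalent duplicates by inverse-variance mean;
# returns tibble h,k,l,i_obs,sigma with ASU-canonical unique indices
merge_set_duplicates <- function(set) {
  setting <- attr(set, "setting")
  asu <- reduce_to_asu(set[, c("h", "k", "l")], setting)
  df <- tibble::tibble(
    h = asu[, 1], k = asu[, 2], l = asu[, 3],
    i_obs = set$i_obs, w = 1 / set$sigma^2
  )
  df |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(
      i_m = sum(.data$i_obs * .data$w) / sum(.data$w),
      sigma = sqrt(1 / sum(.data$w)),
      .groups = "drop"
    ) |>
    dplyr::rename(i_obs = "i_m")
}

#' Generate ground-truth unique intensities
#'
#' Enumerates every Miller index with `d >= d_min` under the setting's cell
#' (general triclinic d-spacing), reduces to the asymmetric unit, and draws
#' each unique true intensity from an exponential distribution with mean
#' `standard_wilson_curve(h) * exp(-2 B_true s^2)` (acentric Wilson
#' statistics), `s = h/2`. Deterministic for a fixed seed.
#'
#' @param setting A [symmetry_setting()].
#' @param d_min Resolution limit (Angstrom).
#' @param b_true Debye-Waller B of the simulated crystal (Angstrom^2).
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: tibble `h, k, l, d, i_true` with
#'   the setting and parameters as attributes.
#' @export
generate_ground_truth <- function(setting, d_min, b_true = 15, seed = 1L) {
  stopifnot(d_min > 0)
  cell <- setting$cell
  lim <- function(axis_len) as.integer(floor(axis_len / d_min)) + 1L
  grid <- expand.grid(
    h = -lim(cell[1]):lim(cell[1]),
    k = -lim(cell[2]):lim(cell[2]),
    l = -lim(cell[3]):lim(cell[3])
  )
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- d_spacing(as.matrix(grid), cell)
  grid <- grid[d >= d_min, ]
  asu <- unique(reduce_to_asu(grid, setting))
  d_asu <- d_spacing(asu, cell)
  ord <- order(-d_asu, asu[, 1], asu[, 2], asu[, 3])
  asu <- asu[ord, , drop = FALSE]
  d_asu <- d_asu[ord]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h_len <- 1 / d_asu
  s2 <- (h_len / 2)^2
  mean_i <- standard_wilson_curve(h_len) * exp(-2 * b_true * s2)
  out <- tibble::tibble(
    h = asu[, 1], k = asu[, 2], l = asu[, 3],
    d = d_asu,
    i_true = stats::rexp(nrow(asu), rate = 1 / mean_i)
  )
  structure(out, class = c("ground_truth", class(out)),
            setting = setting, d_min = d_min, b_true = b_true, seed = seed)
}

#' Simulate a partial-wedge reflection dataset
#'
#' Emulates one small-rotation-wedge dataset measured from one crystal:
#' a random fraction of the unique reflections is observed (index-random
#' sampling; the clustering and merging statistics depend only on overlap
#' structure, not on which reflections a physical wedge sweeps), each
#' observation is scaled by a per-crystal linear scale and relative
#' Debye-Waller factor, optionally perturbed by a per-class non-isomorphism
#' field, and measured with Gaussian noise. Negative observed intensities
#' are kept, as in real integration. If `reindex_op` is set the output
#' indices are mapped through it, emulating an alternative indexing choice.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param fraction_f Fraction of uniques observed (0, 1].
#' @param scale_k Linear scale of this crystal.
#' @param b_rel Relative B (Angstrom^2) of this crystal vs the truth.
#' @param noise_frac Measurement noise as a fraction of `i_true`.
#' @param class_shift Magnitude of the non-isomorphism perturbation; the
#'   perturbation field is a fixed unit-variance Gaussian field seeded by
#'   `class_id`, so sets sharing a class share the field.
#' @param class_id Integer isomorphism-class label (default 1).
#' @param reindex_op Optional 3x3 matrix applied to output indices.
#' @param label Set label.
#' @param seed Integer seed for sampling and noise.
#' @return A [reflection_set()].
#' @export
simulate_partial_dataset <- function(truth, fraction_f = 0.3, scale_k = 1,
                                     b_rel = 0, noise_frac = 0.1,
                                     class_shift = 0, class_id = 1L,
                                     reindex_op = NULL, label = "sim",
                                     seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), fraction_f > 0, fraction_f <= 1)
  setting <- attr(truth, "setting")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # per-class perturbation field: fixed for the class, shared across sets
  delta <- 0
  if (class_shift != 0) {
    set.seed(1000L + as.integer(class_id))
    delta <- stats::rnorm(nrow(truth))
  }

  set.seed(seed)
  n_take <- max(1L, round(fraction_f * nrow(truth)))
  take <- sort(sample.int(nrow(truth), n_take))
  if (n_take < 10) warning("fewer than 10 records in simulated wedge")

  d <- truth$d[take]
  s2 <- (1 / (2 * d))^2
  i_t <- truth$i_true[take] * (1 + class_shift * (if (length(delta) > 1) delta[take] else 0))
  atten <- scale_k * exp(-2 * b_rel * s2)
  sigma_floor <- 0.01 * stats::median(truth$i_true)
  sigma <- pmax(noise_frac * truth$i_true[take], sigma_floor)
  eps <- if (noise_frac > 0) stats::rnorm(n_take, 0, noise_frac * truth$i_true[take]) else 0
  i_obs <- atten * i_t + eps

  hkl <- as.matrix(truth[take, c("h", "k", "l")])
  if (!is.null(reindex_op)) {
    hkl <- hkl %*% reindex_op
    storage.mode(hkl) <- "integer"
  }
  reflection_set(
    tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   i_obs = i_obs, sigma = sigma),
    setting = setting, label = label, true_class = class_id
  )
}

# ---- file I/O --------------------------------------------------------------

# minimal space-group number bookkeeping for headers (presets only)
preset_sg_number <- function(name) {
  switch(name, P1 = 1L, P2 = 3L, P4 = 75L, P6 = 168L, H3 = 146L, 0L)
}
sg_number_preset <- function(num) {
  switch(as.character(num), "1" = "P1", "3" = "P2", "75" = "P4",
         "168" = "P6", "146" = "H3", NULL)
}

#' Write / read reflection files
#'
#' A plain-text column dialect in the style of XDS-ASCII files: comment
#' header lines starting with `!` carry the space-group number, unit-cell
#' constants and wavelength, followed by whitespace-separated rows
#' `H K L IOBS SIGMA(IOBS)`. Round-trip write-then-read preserves values to
#' 6 significant digits.
#'
#' @param set A [reflection_set()].
#' @param path File path.
#' @return `write_reflections()` returns `path` invisibly;
#'   `read_reflections()` returns a [reflection_set()].
#' @export
write_reflections <- function(set, path) {
  setting <- attr(set, "setting")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "!FORMAT=MXMESH_ASCII",
    sprintf("!SPACE_GROUP_NUMBER= %d", preset_sg_number(setting$name)),
    sprintf("!UNIT_CELL_CONSTANTS= %s",
            paste(formatC(setting$cell, format = "g", digits = 7), collapse = " ")),
    sprintf("!WAVELENGTH= %s", formatC(attr(set, "wavelength") %||% 1.0,
                                       format = "g", digits = 7)),
    sprintf("!LABEL= %s", attr(set, "label")),
    "!ITEM_H=1 !ITEM_K=2 !ITEM_L=3 !ITEM_IOBS=4 !ITEM_SIGMA(IOBS)=5",
    "!END_OF_HEADER"
  ), con)
  writeLines(sprintf("%5d %5d %5d %14.6g %14.6g",
                     set$h, set$k, set$l, set$i_obs, set$sigma), con)
  writeLines("!END_OF_DATA", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "!")
  hdr <- lines[is_header]
  get_field <- function(key) {
    ln <- grep(paste0("^!", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub(paste0("^!", key, "="), "", ln[1]))
  }
  sg <- get_field("SPACE_GROUP_NUMBER")
  cell_str <- get_field("UNIT_CELL_CONSTANTS")
  if (is.null(sg) || is.null(cell_str)) {
    stop(sprintf("%s: missing SPACE_GROUP_NUMBER or UNIT_CELL_CONSTANTS header", path))
  }
  cell <- as.numeric(strsplit(cell_str, "\\s+")[[1]])
  preset <- sg_number_preset(as.integer(sg))
  setting <- if (is.null(preset)) {
    symmetry_setting(cell, list(diag(3)), name = paste0("SG", sg))
  } else {
    symmetry_preset(preset, cell = cell)
  }
  label <- get_field("LABEL") %||% basename(path)
  wl <- as.numeric(get_field("WAVELENGTH") %||% "1.0")

  data_lines <- which(!is_header & nzchar(trimws(lines)))
  rows <- lapply(data_lines, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5 || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop(sprintf("%s: malformed data row at line %d", path, i))
    }
    as.numeric(parts)
  })
  m <- do.call(rbind, rows)
  bad_sigma <- which(m[, 5] <= 0)
  if (length(bad_sigma) > 0) {
    stop(sprintf("%s: non-positive sigma at line %d", path,
                 data_lines[bad_sigma[1]]))
  }
  reflection_set(
    tibble::tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                   l = as.integer(m[, 3]), i_obs = m[, 4], sigma = m[, 5]),
    setting = setting, label = label, wavelength = wl
  )
}
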