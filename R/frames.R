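#' Recipe for one synthetic diffraction frame
#'
#' Parameters of the frame simulator. A frame is a Poisson background with a
#' smooth radial profile `background_level * exp(-falloff * h^2)`, plus Bragg
#' spots rendered as 2-D Gaussians at uniformly random pixels whose integrated
#' intensities follow the standard protein Wilson curve attenuated by the
#' crystal's Debye-Waller factor `exp(-2 B s^2)` (with `s = h/2`) and scaled
#' by a unit-mean exponential deviate (acentric Wilson statistics). Optional
#' ice rings add narrow annuli of excess background at the listed d-spacings;
#' salt spots are few, intense and resolution-flat.
#'
#' @param background_level Poisson mean (counts/pixel) at `h = 0`.
#' @param background_falloff Radial decay constant of the background in
#'   `Angstrom^2` (multiplies `h^2`).
#' @param n_spots Number of Bragg spots to place.
#' @param spot_scale Integrated-intensity scale of spots (counts).
#' @param wilson_B Debye-Waller B of the simulated crystal (Angstrom^2).
#' @param spot_sigma_px Gaussian sigma of a rendered spot, pixels.
#' @param ice_rings d-spacings (Angstrom) of ice rings; empty for none.
#'   Hexagonal-ice defaults are `c(3.90, 3.67, 3.44, 2.67, 2.25)`.
#' @param ice_strength Excess counts/pixel at each ring crest.
#' @param salt_spots Number of intense resolution-flat salt spots.
#' @param salt_scale Integrated-intensity scale of salt spots.
#' @param seed Integer seed; frames are bit-identical for a fixed recipe.
#' @return Object of class `frame_recipe`.
#' @export
frame_recipe <- function(background_level = 20,
                         background_falloff = 4,
                         n_spots = 0,
                         spot_scale = 2000,
                         wilson_B = 20,
                         spot_sigma_px = 1.2,
                         ice_rings = numeric(),
                         ice_strength = 60,
                         salt_spots = 0,
                         salt_scale = 5e4,
                         seed = 1L) {
  stopifnot(background_level >= 0, n_spots >= 0, wilson_B >= 0,
            spot_sigma_px > 0, salt_spots >= 0)
  structure(
    list(
      background_level = background_level,
      background_falloff = background_falloff,
      n_spots = as.integer(n_spots),
      spot_scale = spot_scale,
      wilson_B = wilson_B,
      spot_sigma_px = spot_sigma_px,
      ice_rings = as.numeric(ice_rings),
      ice_strength = ice_strength,
      salt_spots = as.integer(salt_spots),
      salt_scale = salt_scale,
      seed = as.integer(seed)
    ),
    class = "frame_recipe"
  )
}

#' Default hexagonal-ice ring d-spacings
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
ice_ring_d_spacings <- function() c(3.90, 3.67, 3.44, 2.67, 2.25)

# additive Gaussian footprint of a spot of total flux `flux` centred at
# (cx, cy) px, truncated at 4 sigma; returns list(rows, cols, values) in the
# n_slow x n_fast matrix layout, or NULL when fully off-detector
spot_footprint <- function(cx, cy, flux, sigma, n_fast, n_slow) {
  half <- ceiling(4 * sigma)
  xs <- seq(floor(cx) - half, floor(cx) + half)
  ys <- seq(floor(cy) - half, floor(cy) + half)
  xs <- xs[xs >= 0 & xs < n_fast]
  ys <- ys[ys >= 0 & ys < n_slow]
  if (length(xs) == 0 || length(ys) == 0) return(NULL)
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
  vals <- outer(gy, gx) # rows = slow (y), cols = fast (x)
  vals <- vals / (2 * pi * sigma^2) * flux
  list(rows = ys + 1L, cols = xs + 1L, values = vals)
}

#' Render one synthetic diffraction frame
#'
#' Deterministic for a fixed recipe (the recipe's `seed` drives all draws).
#' The returned frame is a numeric `n_slow x n_fast` matrix of counts (class
#' `diffraction_frame`) carrying the geometry, the recipe and the planted
#' ground truth (spot positions and fluxes) as attributes. Spot profiles are
#' added deterministically on top of the Poisson background, so with
#' `background_level = 0` the total spot flux scales exactly linearly in
#' `spot_scale`. Spots whose footprint falls entirely off the detector are
#' skipped and counted in the `n_spots_skipped` attribute.
#'
#' @param recipe A [frame_recipe()].
#' @param geom A [detector_geometry()].
#' @return A `diffraction_frame` matrix.
#' @export
render_frame <- function(recipe, geom) {
  stopifnot(inherits(recipe, "frame_recipe"), inherits(geom, "detector_geometry"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  # background and spots use independent derived sub-seeds, so toggling one
  # component (say, an ice ring) leaves the spot realization untouched
  sub_seed <- function(offset) as.integer((recipe$seed + offset) %% 2147483647)
  set.seed(sub_seed(0))

  hmap <- resolution_raster(geom)
  mu <- recipe$background_level * exp(-recipe$background_falloff * hmap^2)
  # ice rings enter the Poisson mean as narrow Gaussian annuli in h
  if (length(recipe$ice_rings) > 0) {
    ring_w <- 0.004 # sigma in h units (~ sharp on typical geometries)
    for (d in recipe$ice_rings) {
      mu <- mu + recipe$ice_strength * exp(-((hmap - 1 / d)^2) / (2 * ring_w^2))
    }
  }
  # Poisson background by inversion: exactly one uniform per pixel, so the
  # realization at a pixel depends only on its own mean — toggling an ice
  # ring perturbs the ring region alone, not the whole stream
  frame <- matrix(stats::qpois(stats::runif(length(mu)), mu), nrow = nrow(mu))
  frame <- frame * 1.0

  truth <- list(spots = NULL, salt = NULL)
  n_skipped <- 0L
  add_spots <- function(n, flux_fun) {
    if (n == 0) return(NULL)
    cx <- stats::runif(n, 0, geom$n_fast - 1)
    cy <- stats::runif(n, 0, geom$n_slow - 1)
    h <- pixel_resolution(geom, cx, cy)
    flux <- flux_fun(h)
    for (i in seq_len(n)) {
      fp <- spot_footprint(cx[i], cy[i], flux[i], recipe$spot_sigma_px,
                           geom$n_fast, geom$n_slow)
      if (is.null(fp)) {
        n_skipped <<- n_skipped + 1L
        next
      }
      frame[fp$rows, fp$cols] <<- frame[fp$rows, fp$cols] + fp$values
    }
    tibble::tibble(x = cx, y = cy, h = h, flux = flux)
  }

  set.seed(sub_seed(1000003))
  truth$spots <- add_spots(recipe$n_spots, function(h) {
    s2 <- (h / 2)^2
    recipe$spot_scale * standard_wilson_curve(h) * exp(-2 * recipe$wilson_B * s2) *
      stats::rexp(length(h))
  })
  set.seed(sub_seed(2000003))
  truth$salt <- add_spots(recipe$salt_spots, function(h) {
    recipe$salt_scale * stats::rexp(length(h))
  })

  structure(
    frame,
    class = c("diffraction_frame", "matrix", "array"),
    geometry = geom,
    recipe = recipe,
    truth = truth,
    n_spots_skipped = n_skipped
  )
}

# save/restore the global RNG state so seeded rendering is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.diffraction_frame <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf(
    "<diffraction_frame> %d x %d px, counts in [%.4g, %.4g], %d planted spots\n",
    g$n_fast, g$n_slow, min(x), max(x),
    if (is.null(attr(x, "truth")$spots)) 0L else nrow(attr(x, "truth")$spots)
  ))
  invisible(x)
}

#' Recipe for a whole mesh scan
#'
#' A rectangular grid of positions, a logical mask marking which positions
#' hold a crystal, optional per-crystal recipe overrides, and per-crystal
#' isomorphism-class labels used downstream by the partial-dataset simulator.
#'
#' @param n_x,n_y Grid dimensions (x = horizontal translation = columns).
#' @param crystal_mask `n_y x n_x` logical matrix; `TRUE` marks a crystal.
#' @param base_recipe [frame_recipe()] used at every position (empty positions
#'   get its background with `n_spots = 0`).
#' @param overrides Optional named list of per-position recipe overrides:
#'   names are `"row,col"` (1-based), values are lists of recipe fields.
#' @param cluster_labels Optional `n_y x n_x` integer matrix of isomorphism
#'   class labels for crystal positions (default all 1).
#' @param seed Master seed; each position gets a derived sub-seed.
#' @return Object of class `mesh_recipe`.
#' @export
mesh_recipe <- function(n_x, n_y, crystal_mask,
                        base_recipe = frame_recipe(n_spots = 150),
                        overrides = list(),
                        cluster_labels = NULL,
                        seed = 1L) {
  crystal_mask <- matrix(as.logical(crystal_mask), nrow = n_y, ncol = n_x)
  if (is.null(cluster_labels)) {
    cluster_labels <- matrix(1L, nrow = n_y, ncol = n_x)
  }
  stopifnot(all(dim(crystal_mask) == c(n_y, n_x)),
            all(dim(cluster_labels) == c(n_y, n_x)))
  structure(
    list(
      n_x = as.integer(n_x), n_y = as.integer(n_y),
      crystal_mask = crystal_mask,
      base_recipe = base_recipe,
      overrides = overrides,
      cluster_labels = cluster_labels,
      seed = as.integer(seed)
    ),
    class = "mesh_recipe"
  )
}

# recipe for position (row, col) of a mesh, with the derived sub-seed
position_recipe <- function(sample, row, col) {
  r <- sample$base_recipe
  if (!sample$crystal_mask[row, col]) {
    r$n_spots <- 0L
    r$salt_spots <- 0L
  }
  key <- paste0(row, ",", col)
  if (!is.null(sample$overrides[[key]])) {
    for (nm in names(sample$overrides[[key]])) r[[nm]] <- sample$overrides[[key]][[nm]]
  }
  # derived per-position seed, kept within 32-bit integer range
  r$seed <- as.integer((sample$seed * 1000003 + (row - 1) * sample$n_x + col) %% 2147483647)
  r
}

#' Render a mesh scan
#'
#' Renders one frame per grid point in row-major raster order (x varies
#' fastest within a row), matching heat-map axes: x is the horizontal
#' translation, y the vertical.
#'
#' @param sample A [mesh_recipe()].
#' @param geom A [detector_geometry()].
#' @return A list of class `mesh_stack`: `frames` (list, row-major),
#'   `mask` (ground-truth crystal mask), `cluster_labels`, `n_x`, `n_y`.
#' @export
render_mesh <- function(sample, geom) {
  stopifnot(inherits(sample, "mesh_recipe"))
  frames <- vector("list", sample$n_x * sample$n_y)
  k <- 0L
  for (row in seq_len(sample$n_y)) {
    for (col in seq_len(sample$n_x)) {
      k <- k + 1L
      frames[[k]] <- render_frame(position_recipe(sample, row, col), geom)
    }
  }
  structure(
    list(
      frames = frames,
      mask = sample$crystal_mask,
      cluster_labels = sample$cluster_labels,
      n_x = sample$n_x, n_y = sample$n_y,
      geometry = geom, sample = sample
    ),
    class = "mesh_stack"
  )
}

#' @export
print.mesh_stack <- function(x, ...) {
  cat(sprintf("<mesh_stack> %d x %d grid, %d frames, %d crystal positions\n",
              x$n_x, x$n_y, length(x$frames), sum(x$mask)))
  invisible(x)
}

#' Write / read frames as 16-bit grayscale TIFF
#'
#' Counts are clipped to the 16-bit range `[0, 65535]` and rounded on output
#' (overflowing pixels are counted and reported via a warning); the geometry
#' travels in a JSON sidecar next to the image.
#'
#' @param frame A `diffraction_frame`.
#' @param path Output TIFF path; the sidecar is `<path>.geom.json`.
#' @return `write_frame_tiff()` returns `path` invisibly; `read_frame_tiff()`
#'   returns a `diffraction_frame` (counts only; no planted truth).
#' @export
write_frame_tiff <- function(frame, path) {
  x <- unclass(frame)
  n_over <- sum(x > 65535)
  if (n_over > 0) {
    warning(sprintf("%d pixels exceeded the 16-bit range and were clipped", n_over))
  }
  x <- pmin(pmax(round(x), 0), 65535)
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  write_geometry(attr(frame, "geometry"), paste0(path, ".geom.json"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  counts <- round(x * 65535)
  geom <- read_geometry(paste0(path, ".geom.json"))
  structure(
    counts,
    class = c("diffraction_frame", "matrix", "array"),
    geometry = geom
  )
}

#' Write a mesh stack to numbered TIFFs plus a manifest
#'
#' Frames land as `frame_0000.tif`, `frame_0001.tif`, ... in raster order,
#' with `manifest.json` recording the grid shape, seed and ground-truth mask
#' and one shared geometry sidecar `geometry.json`.
#'
#' @param stack A `mesh_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesh_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    p <- file.path(dir, sprintf("frame_%04d.tif", i - 1L))
    x <- pmin(pmax(round(unclass(stack$frames[[i]])), 0), 65535)
    tiff::writeTIFF(x / 65535, p, bits.per.sample = 16L)
  }
  write_geometry(stack$geometry, file.path(dir, "geometry.json"))
  jsonlite::write_json(
    list(
      n_x = stack$n_x, n_y = stack$n_y,
      seed = stack$sample$seed,
      crystal_mask = stack$mask
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_mesh_stack
#' @export
read_mesh_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  geom <- read_geometry(file.path(dir, "geometry.json"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$", full.names = TRUE))
  frames <- lapply(files, function(p) {
    structure(round(tiff::readTIFF(p) * 65535),
              class = c("diffraction_frame", "matrix", "array"),
              geometry = geom)
  })
  structure(
    list(
      frames = frames,
      mask = matrix(as.logical(man$crystal_mask), nrow = man$n_y),
      cluster_labels = NULL,
      n_x = man$n_x, n_y = man$n_y,
      geometry = geom, sample = list(seed = man$seed)
    ),
    class = "mesh_stack"
  )
}
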