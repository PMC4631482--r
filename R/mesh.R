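#' Mesh grid dimensions from area and beam size
#'
#' The number of mesh points along each axis is the ceiling of the scan
#' area divided by the beam size: every part of the area is illuminated at
#' least once.
#'
#' @param area_w,area_h Scan area width and height in micrometres.
#' @param beam Beam size in micrometres.
#' @return Integer vector `c(n_x, n_y)`.
#' @examples
#' grid_dimensions(100, 80, 10) # 10 x 8
#' @export
grid_dimensions <- function(area_w, area_h, beam) {
  stopifnot(area_w > 0, area_h > 0, beam > 0)
  c(n_x = as.integer(ceiling(area_w / beam)),
    n_y = as.integer(ceiling(area_h / beam)))
}

#' Assemble a heat map from per-frame scores
#'
#' Scores are laid out in row-major raster order: x (columns) is the
#' horizontal translation, y (rows) the vertical.
#'
#' @param scores Numeric vector of per-frame scores in raster order, or the
#'   tibble from [score_stack()].
#' @param n_x,n_y Grid dimensions (taken from the score tibble if omitted).
#' @param beam_um Beam size recorded as grid metadata (micrometres).
#' @return Object of class `heat_map`: an `n_y x n_x` matrix with `beam_um`
#'   attribute.
#' @export
build_heat_map <- function(scores, n_x = NULL, n_y = NULL, beam_um = NA) {
  if (is.data.frame(scores)) {
    if (is.null(n_x)) n_x <- max(scores$col)
    if (is.null(n_y)) n_y <- max(scores$row)
    scores <- scores$score
  }
  stopifnot(!is.null(n_x), !is.null(n_y))
  if (length(scores) != n_x * n_y) {
    stop(sprintf("expected %d scores for a %d x %d grid, got %d",
                 n_x * n_y, n_x, n_y, length(scores)))
  }
  if (any(scores < 0)) stop("scores must be non-negative")
  structure(matrix(scores, nrow = n_y, ncol = n_x, byrow = TRUE),
            class = c("heat_map", "matrix", "array"), beam_um = beam_um)
}

#' Write / read a heat map as CSV
#'
#' One CSV row per grid row (comma-separated scores, no header).
#'
#' @param map A `heat_map`.
#' @param path File path.
#' @return `write_heat_map()` returns `path` invisibly; `read_heat_map()`
#'   returns a `heat_map`.
#' @export
write_heat_map <- function(map, path) {
  utils::write.table(unclass(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_heat_map
#' @export
read_heat_map <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  structure(m, class = c("heat_map", "matrix", "array"), beam_um = NA)
}

#' Select and rank collection positions
#'
#' Positions with score strictly above the threshold, ranked by score
#' descending (ties broken by raster order), each carrying the wedge
#' specification for the subsequent partial data collection: by default a
#' total rotation range of 10 degrees (+/- 5 degrees about the mesh
#' orientation) covered by 100 images of 0.1 degrees each.
#'
#' @param map A `heat_map`.
#' @param threshold Score threshold (>= 0); only strictly greater scores are
#'   kept.
#' @param top_n Optional cap on the number of positions after ranking.
#' @param total_range_deg,n_images Wedge specification.
#' @return Object of class `collection_plan`: tibble `rank, row, col, score`
#'   with the wedge spec (`total_range_deg`, `n_images`,
#'   `oscillation_deg`) as attributes.
#' @export
select_positions <- function(map, threshold = 0, top_n = Inf,
                             total_range_deg = 10, n_images = 100) {
  stopifnot(threshold >= 0)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(map)), times = ncol(map)),
    col = rep(seq_len(ncol(map)), each = nrow(map)),
    score = as.numeric(unclass(map))
  )
  df$raster <- (df$row - 1L) * ncol(map) + df$col
  df <- df[df$score > threshold, ]
  df <- df[order(-df$score, df$raster), ]
  if (is.finite(top_n)) df <- utils::head(df, top_n)
  out <- tibble::tibble(rank = seq_len(nrow(df)), row = df$row,
                        col = df$col, score = df$score)
  structure(out, class = c("collection_plan", class(out)),
            total_range_deg = total_range_deg, n_images = n_images,
            oscillation_deg = total_range_deg / n_images)
}

#' @export
print.collection_plan <- function(x, ...) {
  cat(sprintf(
    "<collection_plan> %d positions; wedges of %g deg in %d images (%g deg/image)\n",
    nrow(x), attr(x, "total_range_deg"), attr(x, "n_images"),
    attr(x, "oscillation_deg")
  ))
  NextMethod()
}

#' Default end-to-end pipeline configuration
#'
#' @param n_x,n_y Mesh grid size.
#' @param n_crystals Number of planted crystals.
#' @param n_classes Number of isomorphism classes among the crystals.
#' @param class_pattern Optional explicit vector of class labels recycled
#'   over the planted crystals (e.g. `rep(c(1, 2), c(8, 3))` for a large
#'   class and a small outlier class); default alternates `1:n_classes`.
#' @param class_shift Non-isomorphism magnitude between classes.
#' @param threshold Heat-map selection threshold.
#' @param top_n Cap on selected positions.
#' @param cutoff Dendrogram cut height (default 0.15).
#' @param preset Symmetry preset name for the simulated reflections.
#' @param d_min Resolution limit of the simulated reflections.
#' @param fraction Wedge completeness fraction per position.
#' @param noise_frac Measurement noise fraction.
#' @param detector Detector geometry (small by default for speed).
#' @return A list, suitable for [run_pipeline()].
#' @export
pipeline_config <- function(n_x = 6, n_y = 5, n_crystals = 10, n_classes = 1,
                            class_pattern = NULL,
                            class_shift = 0, threshold = 0, top_n = Inf,
                            cutoff = 0.15, preset = "P1", d_min = 2.5,
                            fraction = 0.35, noise_frac = 0.05,
                            detector = detector_geometry(40, 0.2, c(64, 64),
                                                         1.0, 128, 128)) {
  list(n_x = n_x, n_y = n_y, n_crystals = n_crystals, n_classes = n_classes,
       class_pattern = class_pattern,
       class_shift = class_shift, threshold = threshold, top_n = top_n,
       cutoff = cutoff, preset = preset, d_min = d_min, fraction = fraction,
       noise_frac = noise_frac, detector = detector)
}

#' Run the whole multi-crystal workflow on a simulated sample
#'
#' Simulates a mesh scan, scores every frame, assembles the heat map,
#' selects and ranks collection positions, simulates one partial reflection
#' wedge per selected position (inheriting the position's planted
#' isomorphism class), resolves indexing ambiguities against the first
#' wedge, clusters the pairwise dataset correlations, cuts the dendrogram,
#' merges the main cluster and reports the merging statistics. Fully
#' deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @return Object of class `pipeline_report`: nested list with elements
#'   `seed`, `grid`, `heat_map`, `plan`, `clustering`, `merge`; serialize
#'   with [report_json()].
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L) {
  seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # ---- mesh simulation -----------------------------------------------------
  set.seed(seed)
  n_pos <- config$n_x * config$n_y
  n_cry <- min(config$n_crystals, n_pos)
  mask <- matrix(FALSE, config$n_y, config$n_x)
  mask[sample.int(n_pos, n_cry)] <- TRUE
  labels <- matrix(0L, config$n_y, config$n_x)
  pattern <- config$class_pattern %||% seq_len(config$n_classes)
  labels[mask] <- rep_len(as.integer(pattern), n_cry)
  sample_recipe <- mesh_recipe(
    config$n_x, config$n_y, mask,
    base_recipe = frame_recipe(n_spots = 120, spot_scale = 4000,
                               background_level = 15, wilson_B = 18),
    cluster_labels = labels,
    seed = seed
  )
  stack <- render_mesh(sample_recipe, config$detector)

  # ---- scoring + selection -------------------------------------------------
  scores <- score_stack(stack)
  map <- build_heat_map(scores, config$n_x, config$n_y)
  plan <- select_positions(map, threshold = config$threshold,
                           top_n = config$top_n)

  report <- list(
    seed = seed,
    grid = list(n_x = config$n_x, n_y = config$n_y, n_crystals = n_cry,
                crystal_mask = unclass(mask),
                cluster_labels = unclass(labels)),
    heat_map = unclass(map),
    plan = as.data.frame(plan),
    clustering = NULL,
    merge = NULL
  )
  if (nrow(plan) == 0) {
    return(structure(report, class = "pipeline_report"))
  }

  # ---- partial wedges at selected positions --------------------------------
  setting <- symmetry_preset(config$preset)
  truth <- generate_ground_truth(setting, config$d_min, b_true = 15,
                                 seed = seed + 1L)
  sets <- purrr::map(seq_len(nrow(plan)), function(i) {
    row <- plan$row[i]; col <- plan$col[i]
    cls <- max(1L, labels[row, col])
    simulate_partial_dataset(
      truth,
      fraction_f = config$fraction,
      scale_k = exp(stats::runif(1, -0.3, 0.3)),
      b_rel = stats::runif(1, 0, 4),
      noise_frac = config$noise_frac,
      class_shift = if (cls > 1) config$class_shift else 0,
      class_id = cls,
      label = sprintf("pos_%d_%d", row, col),
      seed = (seed * 131 + i) %% 2147483647
    )
  })

  # ---- clustering + merge --------------------------------------------------
  res <- resolve_indexing(sets)
  sets <- res$sets
  # bring all wedges to a common scale before correlating, as the real
  # workflow does (pairwise CC is computed on scaled intensities)
  pre_scales <- suppressWarnings(fit_scales(sets))
  sets <- purrr::map(seq_along(sets), function(i) {
    row <- pre_scales[pre_scales$set == i, ]
    if (nrow(row) == 0 || row$dropped) return(sets[[i]])
    apply_scale(sets[[i]], row$scale_k, row$b_rel)
  })
  ccm <- pairwise_cc(sets)
  dmat <- cc_to_distance(ccm)
  if (length(sets) >= 2) {
    dend <- hca(dmat)
    sel <- cut_dendrogram(dend, config$cutoff, dmat)
    members <- match(sel$main_cluster, ccm$labels)
  } else {
    dend <- NULL
    sel <- NULL
    members <- 1L
  }
  merged_sets <- sets[members]
  scales <- fit_scales(merged_sets)
  merged <- merge_datasets(merged_sets, scales)
  stats <- compute_stats(merged, nrow(truth), seed = seed)

  report$clustering <- list(
    labels = ccm$labels,
    cc = ccm$cc,
    chosen_ops = res$chosen_ops,
    cutoff = config$cutoff,
    main_cluster = if (is.null(sel)) ccm$labels else sel$main_cluster,
    merges = if (is.null(dend)) NULL else as.data.frame(dend$merges)
  )
  report$merge <- list(
    n_sets_merged = length(members),
    scales = as.data.frame(scales),
    stats = as.data.frame(stats)
  )
  structure(report, class = "pipeline_report")
}

#' Serialize a pipeline report to JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Optional path; if given, written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d x %d grid, %d positions planned\n",
              x$grid$n_x, x$grid$n_y, nrow(x$plan)))
  if (!is.null(x$merge)) {
    s <- x$merge$stats
    cat(sprintf("  merged %d sets: completeness %.1f%%, multiplicity %.2f, R_pim %.4f, CC1/2 %.3f\n",
                x$merge$n_sets_merged, s$completeness, s$multiplicity,
                s$r_pim, s$cc_half))
  }
  invisible(x)
}
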