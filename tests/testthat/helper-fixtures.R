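# Shared fixtures. Heavier objects (reflection ground truths) are built once
# per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small but realistic detector: 160 x 160 px, corner resolution ~1.6 A
test_geom <- function() {
  detector_geometry(30, 0.2, c(80, 80), 1.0, 160, 160)
}

test_shells <- function(geom = test_geom(), n = 24) {
  make_shells(geom, n, 1 / (0.98 * mxmesh:::max_h(geom)))
}

# the standard protein-like frame used across scoring tests
protein_recipe <- function(seed = 1, ...) {
  frame_recipe(n_spots = 150, spot_scale = 2e4, wilson_B = 20,
               background_level = 20, seed = seed, ...)
}

p1_truth <- function() {
  memo("p1_truth", generate_ground_truth(symmetry_preset("P1"), 2.5,
                                         b_true = 15, seed = 99))
}

# coarser P1 truth for merging tests that only need overlap structure
p1_truth_coarse <- function() {
  memo("p1_truth_coarse", generate_ground_truth(symmetry_preset("P1"), 3.0,
                                                b_true = 15, seed = 99))
}

p6_truth <- function() {
  memo("p6_truth", generate_ground_truth(symmetry_preset("P6"), 3.0,
                                         b_true = 15, seed = 7))
}

# adjusted Rand index between two labellings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
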