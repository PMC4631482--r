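#' Pairwise correlation of partial datasets
#'
#' For every pair of reflection sets: each set's symmetry-equivalent
#' duplicates are first merged to asymmetric-unit uniques (inverse-variance
#' mean), then the Pearson correlation of intensities is computed over the
#' uniques the pair has in common. Pairs with fewer than `min_common` common
#' uniques are marked missing.
#'
#' @param sets List of [reflection_set()]s sharing one symmetry setting.
#' @param min_common Minimum number of common uniques (default 30).
#' @return Object of class `cc_matrix`: list with `cc` (n x n, diagonal 1),
#'   `n_common` (pair overlap counts), `missing` (logical), `labels`.
#' @export
pairwise_cc <- function(sets, min_common = 30) {
  n <- length(sets)
  stopifnot(n >= 1)
  merged <- lapply(sets, merge_set_duplicates)
  labels <- vapply(sets, function(s) as.character(attr(s, "label")), "")
  cc <- diag(1, n)
  n_common <- matrix(0L, n, n)
  missing <- matrix(FALSE, n, n)
  diag(n_common) <- vapply(merged, nrow, 1L)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ij <- dplyr::inner_join(merged[[i]], merged[[j]],
                                by = c("h", "k", "l"), suffix = c("_i", "_j"))
        n_common[i, j] <- n_common[j, i] <- nrow(ij)
        if (nrow(ij) < min_common ||
            stats::sd(ij$i_obs_i) == 0 || stats::sd(ij$i_obs_j) == 0) {
          cc[i, j] <- cc[j, i] <- NA_real_
          missing[i, j] <- missing[j, i] <- TRUE
        } else {
          r <- stats::cor(ij$i_obs_i, ij$i_obs_j)
          cc[i, j] <- cc[j, i] <- r
        }
      }
    }
  }
  dimnames(cc) <- dimnames(n_common) <- dimnames(missing) <- list(labels, labels)
  structure(list(cc = cc, n_common = n_common, missing = missing,
                 labels = labels),
            class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  off <- x$cc[upper.tri(x$cc)]
  cat(sprintf("<cc_matrix> %d datasets; CC range [%.3f, %.3f], %d missing pairs\n",
              length(x$labels), min(off, na.rm = TRUE), max(off, na.rm = TRUE),
              sum(x$missing[upper.tri(x$missing)])))
  invisible(x)
}

#' Correlation-to-distance transform
#'
#' `dist(i, j) = sqrt(1 - CC(i, j)^2)`; missing correlations map to the
#' maximal distance 1. A CC of 0.989 maps to ~0.148, just inside the
#' conventional 0.15 selection cutoff.
#'
#' @param cc A `cc_matrix` or a plain numeric matrix/vector of correlations.
#' @return Same shape: distances in `[0, 1]`.
#' @export
cc_to_distance <- function(cc) {
  if (inherits(cc, "cc_matrix")) {
    d <- sqrt(pmax(0, 1 - cc$cc^2))
    dim(d) <- dim(cc$cc)
    dimnames(d) <- dimnames(cc$cc)
    d[cc$missing] <- 1
    diag(d) <- 0
    return(d)
  }
  d <- sqrt(pmax(0, 1 - cc^2))
  attributes(d) <- attributes(cc)
  d[is.na(d)] <- 1
  d
}

#' Agglomerative clustering of the dataset distance matrix
#'
#' Average linkage by default (complete, single and Ward available).
#' Returns the merge history in a normalized form: a tibble of `n - 1`
#' merges with non-decreasing heights plus the leaf labels.
#'
#' @param dist_mat Symmetric distance matrix (zero diagonal).
#' @param linkage One of "average", "complete", "single", "ward".
#' @return Object of class `mx_dendrogram`: list with `merges` (tibble
#'   `node_a, node_b, height, size`; negative ids are leaves, positive ids
#'   refer to earlier merge rows), `labels`, and the underlying `hclust`.
#' @export
hca <- function(dist_mat, linkage = c("average", "complete", "single", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(dist_mat)
  if (is.null(n) || n < 2) stop("need at least 2 datasets to cluster")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(dist_mat), method = method)
  merges <- tibble::tibble(
    node_a = hc$merge[, 1],
    node_b = hc$merge[, 2],
    height = hc$height,
    size = merge_sizes(hc$merge)
  )
  labels <- rownames(dist_mat) %||% as.character(seq_len(n))
  structure(list(merges = merges, labels = labels, hclust = hc),
            class = "mx_dendrogram")
}

merge_sizes <- function(merge) {
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sz <- function(id) if (id < 0) 1L else sizes[id]
    sizes[i] <- sz(merge[i, 1]) + sz(merge[i, 2])
  }
  sizes
}

#' @export
print.mx_dendrogram <- function(x, ...) {
  cat(sprintf("<mx_dendrogram> %d leaves, merge heights [%.3f, %.3f]\n",
              length(x$labels), min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' @method tidy mx_dendrogram
#' @export
tidy.mx_dendrogram <- function(x, ...) x$merges

#' Newick serialization of a dendrogram
#'
#' @param dend An `mx_dendrogram`.
#' @return Single Newick string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(dend) {
  hc <- dend$hclust
  # branch length = parent merge height - own height (leaves sit at 0)
  node_str <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%.6g", dend$labels[-id], parent_h)
    } else {
      h <- hc$height[id]
      sprintf("(%s,%s):%.6g",
              node_str(hc$merge[id, 1], h),
              node_str(hc$merge[id, 2], h),
              max(parent_h - h, 0))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", node_str(hc$merge[root, 1], h), ",",
         node_str(hc$merge[root, 2], h), ");")
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected components formed by merges strictly below the
#' cut height. The main cluster is the largest; ties are broken in favour of
#' the lower mean intra-cluster distance.
#'
#' @param dend An `mx_dendrogram`.
#' @param height Cut height (>= 0); the conventional dataset-selection value
#'   is 0.15.
#' @param dist_mat Optional distance matrix for tie-breaking.
#' @return Object of class `cluster_selection`: list with `height`,
#'   `membership` (named integer vector), `main_cluster` (labels),
#'   `cluster_sizes`.
#' @export
cut_dendrogram <- function(dend, height, dist_mat = NULL) {
  stopifnot(height >= 0)
  hc <- dend$hclust
  # components of merges strictly below `height`: cutree with h just under it
  memb <- stats::cutree(hc, h = height - 1e-9)
  names(memb) <- dend$labels
  sizes <- table(memb)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1 && !is.null(dist_mat)) {
    mean_d <- vapply(best, function(cl) {
      ii <- which(memb == cl)
      if (length(ii) < 2) return(0)
      mean(dist_mat[ii, ii][upper.tri(dist_mat[ii, ii])])
    }, 0)
    best <- best[which.min(mean_d)]
  } else {
    best <- best[1]
  }
  structure(
    list(height = height, membership = memb,
         main_cluster = dend$labels[memb == best],
         cluster_sizes = as.integer(sizes)),
    class = "cluster_selection"
  )
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> cut %.3f: %d clusters, main has %d of %d datasets\n",
              x$height, length(x$cluster_sizes), length(x$main_cluster),
              length(x$membership)))
  invisible(x)
}

#' Resolve merohedral indexing ambiguities against a reference
#'
#' With a merohedrally ambiguous point group, independently indexed wedges
#' can come back in either of two (or more) equivalent-looking settings;
#' merging them unresolved manufactures apparent twinning. Following the
#' reference-dataset convention, the first set is taken as the reference and
#' every other set is mapped through the ambiguity operator (identity
#' included) that maximizes its correlation with the reference over common
#' uniques. Sets with insufficient overlap under every operator are left
#' unchanged and flagged.
#'
#' @param sets List of [reflection_set()]s.
#' @param reference Index of the reference set (default 1).
#' @param min_common Minimum overlap to trust a correlation (default 30).
#' @return List with `sets` (reindexed), `chosen_ops` (integer index into
#'   `c(identity, ambiguity_ops)` per set), `flagged` (logical).
#' @export
resolve_indexing <- function(sets, reference = 1L, min_common = 30) {
  setting <- attr(sets[[reference]], "setting")
  ops <- c(list(diag(3)), setting$ambiguity_ops)
  n <- length(sets)
  chosen <- rep(1L, n)
  flagged <- rep(FALSE, n)
  if (length(setting$ambiguity_ops) == 0) {
    return(list(sets = sets, chosen_ops = chosen, flagged = flagged))
  }
  ref_merged <- merge_set_duplicates(sets[[reference]])
  out <- sets
  for (i in seq_len(n)) {
    if (i == reference) next
    ccs <- vapply(ops, function(o) {
      cand <- apply_op(sets[[i]], o)
      m <- merge_set_duplicates(cand)
      ij <- dplyr::inner_join(ref_merged, m, by = c("h", "k", "l"),
                              suffix = c("_r", "_s"))
      if (nrow(ij) < min_common) return(NA_real_)
      stats::cor(ij$i_obs_r, ij$i_obs_s)
    }, 0)
    if (all(is.na(ccs))) {
      flagged[i] <- TRUE
      next
    }
    best <- which.max(ccs)
    chosen[i] <- best
    if (best != 1L) out[[i]] <- apply_op(sets[[i]], ops[[best]])
  }
  list(sets = out, chosen_ops = chosen, flagged = flagged)
}

# apply a reindexing operator to a set's indices
apply_op <- function(set, op) {
  hkl <- as.matrix(set[, c("h", "k", "l")]) %*% op
  out <- set
  out$h <- as.integer(hkl[, 1])
  out$k <- as.integer(hkl[, 2])
  out$l <- as.integer(hkl[, 3])
  out
}
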