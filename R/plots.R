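#' Plot a mesh-scan heat map
#'
#' Tile plot of per-position diffraction scores, x = horizontal grid
#' translation, y = vertical, colour = score.
#'
#' @param object A `heat_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heat_map
#' @export
autoplot.heat_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$score <- as.numeric(unclass(object)[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid x (horizontal translation)",
                  y = "grid y (vertical)", fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot a per-frame scoring result
#'
#' Background curve and, when a Wilson fit is present, observed versus
#' fitted mean spot intensity per resolution shell.
#'
#' @param object A `dozor_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dozor_result
#' @export
autoplot.dozor_result <- function(object, ...) {
  bg <- tibble::tibble(h = object$background$h_mid,
                       value = object$background$b_of_h,
                       series = "background (counts/px)")
  layers <- ggplot2::ggplot(bg, ggplot2::aes(x = .data$h, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$series))
  if (object$fit$ok) {
    wf <- object$fit$data
    df <- tibble::tibble(
      h = rep(wf$h_mid, 2),
      value = exp(c(wf$log_ibar, wf$log_fit)),
      series = rep(c("mean spot intensity", "Wilson model"), each = nrow(wf))
    )
    layers <- layers +
      ggplot2::geom_point(data = df[df$series == "mean spot intensity", ]) +
      ggplot2::geom_line(data = df[df$series == "Wilson model", ],
                         ggplot2::aes(linetype = .data$series))
  }
  layers +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "h = 1/d (1/Angstrom)", y = "counts",
                  title = sprintf("score %.3g, %d spots, CC_powder %.3f",
                                  object$score, object$n_spots,
                                  object$fit$cc_powder)) +
    ggplot2::theme_minimal()
}

#' Plot a dataset dendrogram with a cut line
#'
#' @param dend An `mx_dendrogram`.
#' @param cutoff Optional horizontal cut line (e.g. 0.15).
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(dend, cutoff = NULL) {
  hc <- dend$hclust
  n <- length(dend$labels)
  x_leaf <- order(hc$order)          # leaf -> x position
  xs <- numeric(nrow(hc$merge))      # x of each internal node
  segs <- list()
  node_x <- function(id) if (id < 0) x_leaf[-id] else xs[id]
  node_h <- function(id) if (id < 0) 0 else hc$height[id]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    xs[i] <- (xa + xb) / 2
    segs[[length(segs) + 1]] <- data.frame(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_h(a), hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], node_h(b))
    )
  }
  segs <- do.call(rbind, segs)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = dend$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "dist(i, j)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
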