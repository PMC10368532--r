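#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' per-position editing z profiles, 96-class mutation spectra, per-arm
#' copy-number calls and sample progression dendrograms.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name mosaicevo-autoplot
NULL

#' @rdname mosaicevo-autoplot
#' @method autoplot editing_score
#' @export
autoplot.editing_score <- function(object, ...) {
  ggplot2::ggplot(
    object$positions,
    ggplot2::aes(
      x = .data$position_offset, y = .data$z,
      group = .data$sample, colour = .data$sample
    )
  ) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(
      x = "offset from expected cut site (bp)",
      y = "z of ln odds ratio (tumor vs normal alteration)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname mosaicevo-autoplot
#' @method autoplot trinuc_spectrum
#' @export
autoplot.trinuc_spectrum <- function(object, ...) {
  d <- as_tibble(object)
  d$substitution <- sub(".*\\[(.*)\\].*", "\\1", d$class)
  d$class <- factor(d$class, levels = trinuc_classes())
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$class, y = .data$frequency, fill = .data$substitution)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$cohort),
      cols = ggplot2::vars(.data$substitution),
      scales = "free_x"
    ) +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, size = 4, vjust = 0.5),
      legend.position = "none"
    )
}

#' @rdname mosaicevo-autoplot
#' @method autoplot karyotype_profile
#' @export
autoplot.karyotype_profile <- function(object, ...) {
  d <- object$arms
  d$arm <- factor(d$arm, levels = d$arm)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$arm, y = .data$mean_log2, fill = .data$call)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-0.2, 0.2), linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(
      gain = "#b2182b", loss = "#2166ac", neutral = "grey70", `no-call` = "grey90"
    )) +
    ggplot2::labs(x = NULL, y = "weighted mean log2 read-depth ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

tree_layout <- function(tree) {
  leaf_x <- new.env()
  counter <- 0
  segs <- list()
  place <- function(node, parent_height) {
    if (length(node$children) == 0) {
      counter <<- counter + 1
      x <- counter
    } else {
      xs <- vapply(node$children, place, numeric(1),
        parent_height = node$height
      )
      x <- mean(xs)
      # horizontal bar joining the children at this node's height
      segs[[length(segs) + 1]] <<- tibble(
        x = min(xs), xend = max(xs), y = node$height, yend = node$height
      )
    }
    # vertical drop from this node up to its parent's height
    segs[[length(segs) + 1]] <<- tibble(
      x = x, xend = x, y = node$height, yend = parent_height
    )
    if (length(node$children) == 0) {
      assign(node$members, x, envir = leaf_x)
    }
    x
  }
  place(tree$root, tree$root$height)
  leaves <- tibble(
    label = ls(leaf_x),
    x = vapply(ls(leaf_x), get, numeric(1), envir = leaf_x)
  )
  list(segments = dplyr::bind_rows(segs), leaves = leaves)
}

#' @rdname mosaicevo-autoplot
#' @method autoplot sample_tree
#' @export
autoplot.sample_tree <- function(object, ...) {
  lay <- tree_layout(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = lay$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = lay$leaves,
      ggplot2::aes(x = .data$x, y = -0.02, label = .data$label),
      angle = 90, hjust = 1, size = 3
    ) +
    ggplot2::scale_y_continuous(
      "shared-mutation distance",
      limits = c(-0.35, max(0.05, object$root$height * 1.05))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.title.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}
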