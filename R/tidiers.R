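#' Tidiers for fitted result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (positions, arms, internal nodes), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name mosaicevo-tidiers
NULL

#' @rdname mosaicevo-tidiers
#' @method tidy editing_score
#' @export
tidy.editing_score <- function(x, ...) {
  x$positions
}

#' @rdname mosaicevo-tidiers
#' @method glance editing_score
#' @export
glance.editing_score <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_gene_windows = nrow(x$genes),
    mean_score = mean(x$samples$score),
    central_halfwidth = x$central_halfwidth
  )
}

#' @rdname mosaicevo-tidiers
#' @method tidy karyotype_profile
#' @export
tidy.karyotype_profile <- function(x, ...) {
  x$arms
}

#' @rdname mosaicevo-tidiers
#' @method glance karyotype_profile
#' @export
glance.karyotype_profile <- function(x, ...) {
  x$summary
}

#' @rdname mosaicevo-tidiers
#' @method tidy sample_tree
#' @export
tidy.sample_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  tibble(
    node = seq_along(nodes),
    height = vapply(nodes, `[[`, numeric(1), "height"),
    n_members = vapply(nodes, function(n) length(n$members), integer(1)),
    members = vapply(
      nodes, function(n) paste(n$members, collapse = ","), character(1)
    )
  )
}

#' @rdname mosaicevo-tidiers
#' @method glance sample_tree
#' @export
glance.sample_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  tibble(
    n_samples = length(x$labels),
    n_internal_nodes = length(nodes),
    root_height = x$root$height
  )
}
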