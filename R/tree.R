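#' Per-sample nondriver mutation sets
#'
#' Collapses a (union re-genotyped) variant table to one mutation-key set
#' per sample. A mutation counts as present in a sample when at least
#' `min_alt` reads support it there, so truncal mutations that a caller
#' missed in one sample are not spuriously privatized. Driver mutations in
#' sgRNA-targeted regions should be excluded upstream
#' ([exclude_sgrna_regions()]).
#'
#' @param variants Data frame with `sample`, `chrom`, `pos`, `ref`, `alt`
#'   and (optionally) `tumor_alt` columns.
#' @param min_alt Alt-read support required for presence (default 2);
#'   ignored when the table has no `tumor_alt` column.
#' @return Named list of character vectors of `chrom:pos:ref:alt` keys.
#' @export
mutation_sets <- function(variants, min_alt = 2) {
  v <- as_tibble(variants)
  req <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(v))
  if (length(miss) > 0) {
    abort(paste0("`variants` is missing columns: ", paste(miss, collapse = ", ")))
  }
  if ("tumor_alt" %in% names(v)) {
    v <- v[v$tumor_alt >= min_alt, ]
  }
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  split(key, v$sample) |> lapply(unique)
}

#' Shared-mutation distance between two samples
#'
#' The distance used for progression trees: the number of nondriver
#' somatic mutations shared by two samples as a fraction of all mutations
#' carried by either, subtracted from 1 (the Jaccard distance on mutation
#' sets). Two samples with identical sets are at distance 0, disjoint
#' non-empty sets at 1. Two empty sets return 0 by convention, flagged via
#' the `"both_empty"` attribute.
#'
#' @param set_a,set_b Character vectors of mutation keys.
#' @return Distance in \[0, 1\].
#' @examples
#' pair_distance(c("m1", "m2", "m3"), c("m2", "m3", "m4")) # 0.5
#' @export
pair_distance <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) {
    return(structure(0, both_empty = TRUE))
  }
  1 - length(intersect(set_a, set_b)) / u
}

#' Pairwise shared-mutation distance matrix
#'
#' @param sets Named list of mutation-key sets ([mutation_sets()]), or a
#'   variant table to pass through it.
#' @param min_alt Presence threshold when `sets` is a variant table.
#' @return A `dist` object over the sample names.
#' @export
shared_mutation_distance <- function(sets, min_alt = 2) {
  if (is.data.frame(sets)) {
    sets <- mutation_sets(sets, min_alt = min_alt)
  }
  n <- length(sets)
  labs <- names(sets)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        m[i, j] <- m[j, i] <- pair_distance(sets[[i]], sets[[j]])
      }
    }
  }
  stats::as.dist(m)
}

leaf_node <- function(label) {
  list(members = label, height = 0, children = list())
}

node_key <- function(members) paste(members, collapse = "\u0001")

#' Build a sample progression tree by complete-linkage clustering
#'
#' Agglomerative hierarchical clustering of a mouse's tumor samples on
#' their shared-mutation distances ([shared_mutation_distance()]) with
#' complete (maximum) linkage. Ties between candidate merges are broken
#' deterministically by the lexicographically smallest sorted member list,
#' so the result is invariant to input order.
#'
#' @param x A `dist` object, a square distance matrix with dimnames, a
#'   named list of mutation sets, or a variant table (with a `sample`
#'   column; if a `mouse` column is present it must be constant).
#' @param min_alt Presence threshold when `x` is a variant table.
#' @return A `sample_tree`: leaves at height 0, internal nodes at their
#'   merge heights. `tidy()` lists every internal node with its height and
#'   members.
#' @examples
#' d <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3,
#'   dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
#' )
#' build_tree(as.dist(d))
#' @export
build_tree <- function(x, min_alt = 2) {
  if (is.data.frame(x)) {
    if ("mouse" %in% names(x) && length(unique(x$mouse)) > 1) {
      abort("progression trees are per mouse: got samples from multiple mice")
    }
    x <- mutation_sets(x, min_alt = min_alt)
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- shared_mutation_distance(x)
  }
  m <- as.matrix(x)
  labs <- rownames(m)
  if (is.null(labs) || length(labs) < 2) {
    abort("at least 2 labelled samples are required")
  }
  if (anyDuplicated(labs)) {
    abort("sample labels must be unique")
  }

  nodes <- lapply(labs, leaf_node)
  names(nodes) <- labs
  d <- m
  merges <- list()
  while (length(nodes) > 1) {
    keys <- names(nodes)
    dm <- d[keys, keys, drop = FALSE]
    diag(dm) <- Inf
    dmin <- min(dm)
    cand <- which(dm <= dmin + 1e-15 & upper.tri(dm), arr.ind = TRUE)
    union_keys <- vapply(seq_len(nrow(cand)), function(r) {
      node_key(sort(c(
        nodes[[cand[r, 1]]]$members, nodes[[cand[r, 2]]]$members
      )))
    }, character(1))
    pick <- cand[order(union_keys)[1], ]
    a <- keys[pick[1]]
    b <- keys[pick[2]]
    members <- sort(c(nodes[[a]]$members, nodes[[b]]$members))
    new <- list(
      members = members, height = dmin,
      children = sort_children(list(nodes[[a]], nodes[[b]]))
    )
    nk <- node_key(members)
    # complete linkage update
    others <- setdiff(keys, c(a, b))
    d <- rbind(
      cbind(d, stats::setNames(rep(NA_real_, nrow(d)), NULL)),
      rep(NA_real_, ncol(d) + 1)
    )
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- nk
    for (o in others) {
      d[nk, o] <- d[o, nk] <- max(d[a, o], d[b, o])
    }
    d[nk, nk] <- 0
    nodes[[a]] <- NULL
    nodes[[b]] <- NULL
    nodes[[nk]] <- new
    merges[[length(merges) + 1]] <- list(height = dmin, members = members)
  }
  structure(
    list(root = nodes[[1]], labels = sort(labs), merges = merges),
    class = "sample_tree"
  )
}

sort_children <- function(children) {
  keys <- vapply(
    children, function(ch) node_key(ch$members), character(1)
  )
  children[order(keys)]
}

collapse_node <- function(node, tol) {
  if (length(node$children) == 0) {
    return(node)
  }
  node$children <- lapply(node$children, collapse_node, tol = tol)
  kept <- list()
  for (ch in node$children) {
    if (length(ch$children) > 0 && node$height - ch$height <= tol) {
      kept <- c(kept, ch$children)
    } else {
      kept <- c(kept, list(ch))
    }
  }
  node$children <- sort_children(kept)
  node
}

#' Collapse zero-length internal branches into polytomies
#'
#' Internal edges whose length (parent merge height minus child merge
#' height) is within `tol` of zero are contracted to the parent node,
#' turning runs of equal-height merges into a single polytomy. Leaves are
#' never removed.
#'
#' @param tree A [build_tree()] result.
#' @param tol Length tolerance (default 1e-12).
#' @return The collapsed `sample_tree`.
#' @export
collapse_zero_branches <- function(tree, tol = 1e-12) {
  stopifnot(inherits(tree, "sample_tree"))
  tree$root <- collapse_node(tree$root, tol)
  tree$merges <- tree_nodes(tree)
  tree
}

# flat tibble of internal nodes (height + member sets)
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) > 0) {
      out[[length(out) + 1]] <<- list(height = node$height, members = node$members)
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  walk(tree$root)
  out
}

# all clades (member sets of every node, leaves included)
tree_clades <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node$members
    lapply(node$children, walk)
    invisible(NULL)
  }
  walk(tree$root)
  out
}

#' @export
print.sample_tree <- function(x, ...) {
  cat("<sample_tree>", length(x$labels), "samples\n")
  cat("  ", format_newick(x), "\n", sep = "")
  invisible(x)
}

#' Assign mutations to tree branches and classify them
#'
#' Each mutation is assigned to the branch above the largest clade all of
#' whose samples carry it (for carrier sets that match a clade exactly this
#' is that clade's branch; carrier sets that conflict with the topology
#' fall back to the largest clade fully contained in the carriers, and are
#' flagged). Mutations on the root branch — carried by every sample — are
#' truncal; mutations on a leaf branch are private; everything else is
#' shared.
#'
#' @param tree A [build_tree()] (optionally collapsed) tree.
#' @param sets Mutation sets ([mutation_sets()]) or a variant table; names
#'   must cover the tree's leaves.
#' @param min_alt Presence threshold when `sets` is a variant table.
#' @return A `branch_assignment` tibble: one row per mutation with `key`,
#'   `branch` (comma-separated clade members), `n_carriers`, `category`
#'   (`"truncal"`, `"shared"`, `"private"`) and `clade_conflict`.
#' @export
assign_branches <- function(tree, sets, min_alt = 2) {
  stopifnot(inherits(tree, "sample_tree"))
  if (is.data.frame(sets)) {
    sets <- mutation_sets(sets, min_alt = min_alt)
  }
  if (!all(tree$labels %in% names(sets))) {
    sets <- c(sets, setNames(
      rep(list(character(0)), sum(!tree$labels %in% names(sets))),
      setdiff(tree$labels, names(sets))
    ))
  }
  sets <- sets[tree$labels]
  long <- tibble(
    sample = rep(names(sets), lengths(sets)),
    key = unlist(sets, use.names = FALSE)
  )
  if (nrow(long) == 0) {
    return(structure(
      tibble(
        key = character(), branch = character(), n_carriers = integer(),
        category = character(), clade_conflict = logical()
      ),
      class = c("branch_assignment", class(tibble()))
    ))
  }
  carriers <- split(long$sample, long$key)
  clades <- tree_clades(tree)
  clade_sizes <- lengths(clades)
  ord <- order(-clade_sizes, vapply(clades, node_key, character(1)))
  clades <- clades[ord]
  n_leaves <- length(tree$labels)

  assigned <- purrr::map_dfr(names(carriers), function(k) {
    s <- carriers[[k]]
    if (length(s) == 0) {
      abort("mutation carried by zero samples cannot be assigned")
    }
    for (cl in clades) {
      if (all(cl %in% s)) {
        return(tibble(
          key = k,
          branch = paste(cl, collapse = ","),
          n_carriers = length(s),
          category = if (length(cl) == n_leaves) {
            "truncal"
          } else if (length(cl) == 1) "private" else "shared",
          clade_conflict = length(cl) != length(s)
        ))
      }
    }
    abort("no clade contained in carrier set (corrupt tree)")
  })
  structure(assigned, class = c("branch_assignment", class(assigned)))
}

#' Truncal/shared/private fractions by anatomic site class
#'
#' Pools the per-sample mutation occurrences of every sample in a site
#' class (primary, metastasis, cell line), classifies each occurrence by
#' its mutation's branch assignment, and reports the fraction of each
#' category per class (fractions sum to 1 within a class). Classes with no
#' mutations are omitted.
#'
#' @param assignment A [assign_branches()] result.
#' @param sets Mutation sets or variant table, as used for the assignment.
#' @param sample_info Data frame mapping `sample` to `site_class`.
#' @param min_alt Presence threshold when `sets` is a variant table.
#' @return Tibble with `site_class`, `category`, `n` and `fraction`.
#' @export
truncal_private_fractions <- function(assignment, sets, sample_info,
                                      min_alt = 2) {
  if (is.data.frame(sets)) {
    sets <- mutation_sets(sets, min_alt = min_alt)
  }
  long <- tibble(
    sample = rep(names(sets), lengths(sets)),
    key = unlist(sets, use.names = FALSE)
  )
  long <- dplyr::inner_join(
    long, sample_info[, c("sample", "site_class")],
    by = "sample"
  )
  long <- dplyr::inner_join(
    long, assignment[, c("key", "category")],
    by = "key"
  )
  out <- dplyr::count(long, .data$site_class, .data$category)
  dplyr::mutate(
    dplyr::group_by(out, .data$site_class),
    fraction = .data$n / sum(.data$n)
  ) |> dplyr::ungroup()
}

format_node <- function(node, parent_height) {
  len <- format(parent_height - node$height,
    digits = 12, scientific = FALSE, trim = TRUE
  )
  if (length(node$children) == 0) {
    paste0(node$members, ":", len)
  } else {
    paste0(
      "(",
      paste(
        vapply(node$children, format_node,
          character(1),
          parent_height = node$height
        ),
        collapse = ","
      ),
      "):", len
    )
  }
}

format_newick <- function(tree) {
  root <- tree$root
  inner <- paste(
    vapply(root$children, format_node, character(1),
      parent_height = root$height
    ),
    collapse = ","
  )
  paste0("(", inner, ");")
}

#' Write a sample tree as Newick
#'
#' Branch lengths are parent merge height minus child height (leaves sit
#' at height 0); polytomies from [collapse_zero_branches()] are emitted
#' directly.
#'
#' @param tree A `sample_tree`.
#' @param path Output file path; with `path = NULL` the Newick string is
#'   returned instead.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "sample_tree"))
  s <- format_newick(tree)
  if (is.null(path)) {
    return(s)
  }
  writeLines(s, path)
  invisible(s)
}
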