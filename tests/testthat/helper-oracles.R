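# Independent reference implementations used to cross-check the package.

# ln sample odds ratio by direct 2x2 arithmetic, +0.5 on all cells when any
# cell is zero
oracle_log_odds <- function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
  cells <- c(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (any(cells == 0)) cells <- cells + 0.5
  log((cells[2] * cells[3]) / (cells[1] * cells[4]))
}

# tandem-repeat detection via a regex backreference: three consecutive
# copies of any N-free motif of length 1..6
oracle_tandem_fail <- function(s) {
  any(vapply(1:6, function(k) {
    grepl(sprintf("([ACGT]{%d})\\1\\1", k), s, perl = TRUE)
  }, logical(1)))
}

# naive O(n^3) complete-linkage agglomeration: cluster distance recomputed
# from the original leaf matrix at every step; ties broken by the
# lexicographically smallest sorted member union
oracle_complete_linkage <- function(m) {
  labs <- rownames(m)
  clusters <- as.list(labs)
  merges <- list()
  clust_dist <- function(a, b) max(m[a, b])
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- clust_dist(clusters[[i]], clusters[[j]])
        u <- sort(c(clusters[[i]], clusters[[j]]))
        key <- paste(u, collapse = "")
        if (is.null(best) || d < best$d - 1e-15 ||
          (d <= best$d + 1e-15 && key < best$key)) {
          best <- list(i = i, j = j, d = d, u = u, key = key)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(height = best$d, members = best$u)
    clusters[[best$i]] <- best$u
    clusters[[best$j]] <- NULL
  }
  merges
}

# canonical signature of a merge sequence for equality checks
merge_signature <- function(merges) {
  paste(vapply(merges, function(mg) {
    paste0(
      sprintf("%.10f", mg$height), "|",
      paste(sort(mg$members), collapse = ",")
    )
  }, character(1)), collapse = ";")
}

random_distance_matrix <- function(n) {
  labs <- sprintf("s%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  vals <- stats::runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  m
}

random_dna20 <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, character(1))
}

# adversarial windows: near-miss and just-over tandem structures
adversarial_dna20 <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    k <- sample(1:6, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    copies <- sample(2:4, 1) # 2 copies = must pass, 3+ = must fail
    core <- strrep(motif, copies)
    pad <- paste(
      sample(c("A", "C", "G", "T"), max(0, 20 - nchar(core)), replace = TRUE),
      collapse = ""
    )
    s <- substr(paste0(core, pad), 1, 20)
    if (nchar(s) < 20) s <- substr(strrep(s, 3), 1, 20)
    out[i] <- s
  }
  out
}
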