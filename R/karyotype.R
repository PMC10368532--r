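#' Call a focal copy-number event from the exons spanning a region
#'
#' A focal event is called only when every exon in the region clears the
#' absolute log2 read-depth-ratio threshold with a consistent sign: all
#' exons at or above `+threshold` give an amplification, all at or below
#' `-threshold` a deletion; anything else (including mixed signs) is
#' neutral, since a coherent focal event cannot point both ways.
#'
#' @param exons_in_region Data frame of exon rows with a `log2` column (a
#'   bare numeric vector is also accepted).
#' @param threshold Absolute log2 threshold (> 0, default 0.4).
#' @return `"amplification"`, `"deletion"` or `"neutral"`.
#' @examples
#' focal_call(data.frame(log2 = c(-0.5, -0.6, -0.45)))
#' @export
focal_call <- function(exons_in_region, threshold = 0.4) {
  lr <- if (is.data.frame(exons_in_region)) exons_in_region$log2 else exons_in_region
  if (length(lr) == 0) {
    abort("focal region contains no exons")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be > 0")
  }
  if (all(lr >= threshold)) {
    "amplification"
  } else if (all(lr <= -threshold)) {
    "deletion"
  } else {
    "neutral"
  }
}

assign_exons_to_arms <- function(exons, arms) {
  check_arm_table(arms)
  mid <- floor((exons$start + exons$end) / 2)
  ex_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(mid + 1, mid + 1)
  )
  arm_gr <- GenomicRanges::GRanges(
    arms$chrom, IRanges::IRanges(arms$start + 1, arms$end)
  )
  hits <- GenomicRanges::findOverlaps(ex_gr, arm_gr, select = "first")
  arms$arm[hits]
}

#' Arm-level copy-number calls from per-exon log2 ratios
#'
#' Summarizes each chromosome arm by the weight-weighted mean of its exons'
#' log2 read-depth ratios (exons map to the arm containing their midpoint)
#' and calls a gain at or above `+broad_threshold`, a loss at or below
#' `-broad_threshold`, neutral otherwise. Arms without exons are reported
#' as `"no-call"`.
#'
#' @param exons Data frame with `chrom`, `start`, `end`, `weight`, `log2`.
#' @param arms Arm definition table ([arm_table()]).
#' @param broad_threshold Arm-level threshold (default 0.2, inclusive).
#' @param center If `TRUE`, median-center the exon log2 ratios first so a
#'   genome-wide ploidy shift does not saturate every arm call (default
#'   `FALSE`; [karyotype_profile()] centers by default).
#' @return Tibble with one row per arm: `arm`, `n_exons`, `mean_log2`,
#'   `call`.
#' @export
arm_calls <- function(exons, arms, broad_threshold = 0.2, center = FALSE) {
  req <- c("chrom", "start", "end", "weight", "log2")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0) {
    abort(paste0("`exons` is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(exons$weight < 0)) {
    abort("exon weights must be non-negative")
  }
  ex <- as_tibble(exons)
  if (center && nrow(ex) > 0) {
    ex$log2 <- ex$log2 - median(ex$log2)
  }
  ex$arm <- assign_exons_to_arms(ex, arms)
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(ex[!is.na(ex$arm), ], .data$arm),
    n_exons = dplyr::n(),
    mean_log2 = sum(.data$weight * .data$log2) / sum(.data$weight),
    .groups = "drop"
  )
  out <- dplyr::left_join(arms[, c("arm", "length")], stats_tbl, by = "arm")
  out$n_exons <- dplyr::coalesce(out$n_exons, 0L)
  out$call <- dplyr::case_when(
    out$n_exons == 0 ~ "no-call",
    out$mean_log2 >= broad_threshold ~ "gain",
    out$mean_log2 <= -broad_threshold ~ "loss",
    TRUE ~ "neutral"
  )
  out[, c("arm", "n_exons", "mean_log2", "call")]
}

#' Aneuploidy score and fraction of genome altered
#'
#' The aneuploidy score counts arms called gained or lost; the fCNA
#' transforms it onto the genome scale as the arm-length-weighted fraction
#' altered (an arm-count mode, score divided by the number of scored arms,
#' is available for cross-checks).
#'
#' @param calls Output of [arm_calls()].
#' @param arms Matching arm definition table.
#' @param mode `"length"` (default) or `"count"`.
#' @return A one-row tibble with `aneuploidy_score` and `fcna`.
#' @examples
#' arms <- arm_table("mm10")
#' calls <- tibble::tibble(
#'   arm = arms$arm, n_exons = 1,
#'   mean_log2 = 0, call = "neutral"
#' )
#' aneuploidy_and_fcna(calls, arms)
#' @export
aneuploidy_and_fcna <- function(calls, arms, mode = c("length", "count")) {
  mode <- match.arg(mode)
  altered <- calls$call %in% c("gain", "loss")
  score <- sum(altered)
  fcna <- if (mode == "length") {
    len <- setNames(arms$length, arms$arm)
    sum(len[calls$arm[altered]]) / sum(len[calls$arm])
  } else {
    score / nrow(calls)
  }
  tibble(aneuploidy_score = as.integer(score), fcna = fcna)
}

#' Select tumor ploidy from a cellularity-ploidy probability grid
#'
#' Restricts the grid to the cellularity value nearest the independent
#' purity estimate and returns the ploidy with the largest predicted
#' probability there; ties resolve to the lowest ploidy.
#'
#' @param grid Data frame with columns `cellularity`, `ploidy`,
#'   `probability`.
#' @param purity_estimate Purity estimate in (0, 1\].
#' @return The selected ploidy (a single number).
#' @export
select_ploidy <- function(grid, purity_estimate) {
  req <- c("cellularity", "ploidy", "probability")
  miss <- setdiff(req, names(grid))
  if (length(miss) > 0) {
    abort(paste0("`grid` is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(grid) == 0) {
    abort("empty cellularity-ploidy grid")
  }
  check_fraction(purity_estimate, "purity_estimate", lo = 0, lo_open = TRUE)
  nearest <- grid$cellularity[which.min(abs(grid$cellularity - purity_estimate))]
  g <- grid[grid$cellularity == nearest, ]
  g <- g[order(g$ploidy), ]
  g$ploidy[which.max(g$probability)]
}

#' Call whole-genome doubling from ploidy
#'
#' @param ploidy Tumor ploidy (> 0).
#' @param cutoff Ploidy at or above which WGD is called (default 3).
#' @return Logical.
#' @export
call_wgd <- function(ploidy, cutoff = 3) {
  if (any(ploidy <= 0)) {
    abort("`ploidy` must be > 0")
  }
  ploidy >= cutoff
}

#' Select heterozygous SNPs from normal-tissue allele counts
#'
#' Keeps records whose normal B-allele frequency lies strictly between 0.2
#' and 0.8 with normal coverage of at least `min_coverage` reads.
#'
#' @param records Data frame with `normal_ref` and `normal_alt` columns
#'   (or precomputed `baf_normal`).
#' @param min_coverage Minimum normal coverage (default 15).
#' @return The heterozygous subset as a tibble, with `baf_normal` filled
#'   in.
#' @export
select_het_snps <- function(records, min_coverage = 15) {
  r <- as_tibble(records)
  if (!all(c("normal_ref", "normal_alt") %in% names(r))) {
    abort("`records` must carry normal_ref and normal_alt counts")
  }
  cov <- r$normal_ref + r$normal_alt
  r$baf_normal <- ifelse(cov > 0, r$normal_alt / cov, NA_real_)
  r[cov >= min_coverage & !is.na(r$baf_normal) &
    r$baf_normal > 0.2 & r$baf_normal < 0.8, ]
}

#' Mean mirrored B-allele-frequency deviation
#'
#' Summarizes allelic imbalance over a set of heterozygous SNPs as the
#' mean of `abs(baf_tumor - 0.5)`; 0 indicates allelic balance and values
#' approach 0.5 under complete single-allele dropout.
#'
#' @param records Data frame with a `baf_tumor` column (or `tumor_ref` and
#'   `tumor_alt` counts), typically one segment's or arm's het SNPs.
#' @return Mean mirrored deviation, or `NA` for an empty segment.
#' @examples
#' allelic_imbalance(data.frame(baf_tumor = c(0.2, 0.8))) # 0.3
#' @export
allelic_imbalance <- function(records) {
  r <- as_tibble(records)
  if (!"baf_tumor" %in% names(r)) {
    if (!all(c("tumor_ref", "tumor_alt") %in% names(r))) {
      abort("`records` must carry baf_tumor or tumor_ref/tumor_alt counts")
    }
    tot <- r$tumor_ref + r$tumor_alt
    r$baf_tumor <- ifelse(tot > 0, r$tumor_alt / tot, NA_real_)
  }
  if (nrow(r) == 0) {
    warn("empty segment: no heterozygous SNPs, returning NA")
    return(NA_real_)
  }
  mean(abs(r$baf_tumor - 0.5), na.rm = TRUE)
}

#' Full karyotype profile of one sample
#'
#' Convenience wrapper running the arm-level pipeline end to end for one
#' sample: median-centers the exon log2 ratios (so ploidy shifts are read
#' from the grid, not from saturated arm calls), calls arm gains/losses,
#' derives the aneuploidy score and fCNA, selects ploidy from the
#' cellularity-ploidy grid at the purity estimate, calls WGD, and — when a
#' BAF table is supplied — summarizes per-arm allelic imbalance over
#' heterozygous SNPs.
#'
#' @param exons Per-exon log2 table (`chrom`, `start`, `end`, `weight`,
#'   `log2`).
#' @param arms Arm table ([arm_table()]).
#' @param grid Optional cellularity-ploidy grid ([select_ploidy()]).
#' @param purity Purity estimate, required with `grid`.
#' @param baf Optional BAF table with `chrom`, `pos`, `normal_ref`,
#'   `normal_alt`, `tumor_ref`, `tumor_alt`.
#' @param broad_threshold,center,wgd_cutoff,min_het_coverage Stage
#'   parameters; see the individual functions.
#' @return A `karyotype_profile` object with elements `arms` (per-arm
#'   calls, plus `baf_deviation` when BAF data were given) and `summary`
#'   (one-row tibble: `aneuploidy_score`, `fcna`, `ploidy`, `wgd`,
#'   `purity`). `tidy()` returns the per-arm table, `glance()` the
#'   summary.
#' @export
karyotype_profile <- function(exons, arms, grid = NULL, purity = NULL,
                              baf = NULL, broad_threshold = 0.2,
                              center = TRUE, wgd_cutoff = 3,
                              min_het_coverage = 15) {
  calls <- arm_calls(exons, arms,
    broad_threshold = broad_threshold, center = center
  )
  an <- aneuploidy_and_fcna(calls, arms)
  ploidy <- NA_real_
  wgd <- NA
  if (!is.null(grid)) {
    if (is.null(purity)) {
      abort("`purity` is required to select ploidy from a grid")
    }
    ploidy <- select_ploidy(grid, purity)
    wgd <- call_wgd(ploidy, cutoff = wgd_cutoff)
  }
  if (!is.null(baf)) {
    het <- select_het_snps(baf, min_coverage = min_het_coverage)
    het$arm <- assign_exons_to_arms(
      tibble(chrom = het$chrom, start = het$pos - 1, end = het$pos), arms
    )
    dev <- dplyr::summarise(
      dplyr::group_by(het[!is.na(het$arm), ], .data$arm),
      baf_deviation = allelic_imbalance(dplyr::pick(dplyr::everything())),
      n_het_snps = dplyr::n(),
      .groups = "drop"
    )
    calls <- dplyr::left_join(calls, dev, by = "arm")
  }
  structure(
    list(
      arms = calls,
      summary = tibble(
        aneuploidy_score = an$aneuploidy_score,
        fcna = an$fcna,
        ploidy = ploidy,
        wgd = wgd,
        purity = purity %||% NA_real_
      )
    ),
    class = "karyotype_profile"
  )
}

#' @export
print.karyotype_profile <- function(x, ...) {
  cat("<karyotype_profile>\n")
  s <- x$summary
  cat(sprintf(
    "  aneuploidy score %d, fCNA %.3f, ploidy %s, WGD %s\n",
    s$aneuploidy_score, s$fcna,
    ifelse(is.na(s$ploidy), "?", format(s$ploidy)),
    ifelse(is.na(s$wgd), "?", s$wgd)
  ))
  altered <- x$arms[x$arms$call %in% c("gain", "loss"), ]
  if (nrow(altered) > 0) {
    cat(
      "  altered arms:",
      paste(altered$arm, altered$call, collapse = ", "), "\n"
    )
  }
  invisible(x)
}
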