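#' Log odds ratio of base alteration between tumor and normal
#'
#' For one pileup position, compares the altered/reference read counts of
#' the tumor against its matched normal via the 2x2 sample odds ratio
#' `(tumor_alt * normal_ref) / (tumor_ref * normal_alt)`, returned on the
#' natural-log scale. When any cell is zero, the Haldane–Anscombe
#' correction (+0.5 on every cell) is applied, so positions with no
#' alterations in either compartment score exactly 0.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt Non-negative read
#'   counts (vectorized).
#' @return Numeric vector of natural-log odds ratios.
#' @examples
#' position_log_odds(70, 30, 98, 2) # log(21)
#' position_log_odds(50, 50, 50, 50) # 0
#' @export
position_log_odds <- function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
  n <- length(tumor_ref)
  stopifnot(
    length(tumor_alt) == n, length(normal_ref) == n, length(normal_alt) == n
  )
  m <- cbind(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (any(m < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(rowSums(m) == 0)) {
    abort("all four counts are zero: odds ratio undefined at this position")
  }
  zero <- rowSums(m == 0) > 0
  m[zero, ] <- m[zero, , drop = FALSE] + 0.5
  unname(log((m[, "tumor_alt"] * m[, "normal_ref"]) /
    (m[, "tumor_ref"] * m[, "normal_alt"])))
}

#' Z-transform per-position log odds ratios within a gene window
#'
#' Centers and scales the log odds ratios of one gene's cut-site window
#' against the mean and population (n-denominator) standard deviation over
#' its positions. A window with zero spread returns all-zero z values.
#'
#' @param ln_odds_ratios Numeric vector of per-position log odds ratios
#'   (at least 2 positions).
#' @return Numeric vector of z scores with mean 0 and unit population
#'   standard deviation (when the input has spread).
#' @examples
#' gene_z_scores(c(-1, 1))
#' @export
gene_z_scores <- function(ln_odds_ratios) {
  if (length(ln_odds_ratios) < 2) {
    abort("at least 2 window positions are required for the z-transform")
  }
  mu <- mean(ln_odds_ratios)
  s <- sqrt(mean((ln_odds_ratios - mu)^2))
  if (s == 0) {
    return(rep(0, length(ln_odds_ratios)))
  }
  (ln_odds_ratios - mu) / s
}

#' Summarize per-gene z scores into a sample editing score
#'
#' Averages, for each gene, the z scores at offsets within
#' `central_halfwidth` of the cut site (Cas9 cuts bluntly ~3 bp upstream of
#' the PAM, so editing-induced alterations concentrate within a couple of
#' bases of the expected site), then averages those per-gene central means
#' across genes.
#'
#' @param z_by_gene Data frame with columns `gene`, `position_offset` and
#'   `z`.
#' @param central_halfwidth Offsets with `abs(position_offset) <=
#'   central_halfwidth` contribute to the score (default 2).
#' @return A single editing score.
#' @export
sample_editing_score <- function(z_by_gene, central_halfwidth = 2) {
  req <- c("gene", "position_offset", "z")
  if (!all(req %in% names(z_by_gene)) || nrow(z_by_gene) == 0) {
    abort("`z_by_gene` must be a non-empty data frame with columns gene, position_offset, z")
  }
  central <- dplyr::filter(
    z_by_gene, abs(.data$position_offset) <= central_halfwidth
  )
  if (nrow(central) == 0 ||
    !setequal(unique(z_by_gene$gene), unique(central$gene))) {
    abort("every gene must cover offsets within the central window")
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(central, .data$gene),
    cut_site_z = mean(.data$z), .groups = "drop"
  )
  mean(per_gene$cut_site_z)
}

#' Score sgRNA editing efficiency from cut-site pileups
#'
#' Runs the full editing-efficiency statistic over a table of paired
#' tumor/normal cut-site pileups: a per-position log odds ratio of base
#' alteration (tumor vs matched normal, [position_log_odds()]), a
#' z-transform against the mean log odds ratio over each gene's window
#' ([gene_z_scores()]), and a per-sample score averaging the central-window
#' z across genes ([sample_editing_score()]).
#'
#' @param pileups Data frame in the layout emitted by
#'   [simulate_cutsite_pileup()]: columns `gene`, `sample`, `compartment`
#'   (`"tumor"`/`"normal"`), `position_offset`, `ref_count`, `alt_count`.
#' @param central_halfwidth Half-width of the central window entering the
#'   sample score (default 2 bases).
#' @param fisher_p If `TRUE` (default), a two-sided Fisher exact p-value is
#'   computed for every position and stored alongside the odds ratio; the
#'   p-values do not enter the score.
#' @return An `editing_score` object: a list of tibbles `positions`
#'   (per-position `ln_odds_ratio`, `p_value`, `z`), `genes` (per-gene
#'   central-window z) and `samples` (per-sample `score`). `tidy()` returns
#'   the position table, `glance()` the per-sample scores.
#' @examples
#' pu <- simulate_cutsite_pileup(0.5, 200, seed = 1)
#' score_editing(pu, fisher_p = FALSE)
#' @export
score_editing <- function(pileups, central_halfwidth = 2, fisher_p = TRUE) {
  req <- c(
    "gene", "sample", "compartment", "position_offset", "ref_count", "alt_count"
  )
  miss <- setdiff(req, names(pileups))
  if (length(miss) > 0) {
    abort(paste0("`pileups` is missing columns: ", paste(miss, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    as_tibble(pileups),
    id_cols = c("sample", "gene", "position_offset"),
    names_from = "compartment",
    values_from = c("ref_count", "alt_count")
  )
  need <- c("ref_count_tumor", "alt_count_tumor", "ref_count_normal", "alt_count_normal")
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    abort("pileups must pair a tumor and a normal compartment at every position")
  }
  wide$ln_odds_ratio <- position_log_odds(
    wide$ref_count_tumor, wide$alt_count_tumor,
    wide$ref_count_normal, wide$alt_count_normal
  )
  wide$p_value <- if (fisher_p) {
    vapply(seq_len(nrow(wide)), function(i) {
      fisher.test(matrix(
        c(
          wide$alt_count_tumor[i], wide$ref_count_tumor[i],
          wide$alt_count_normal[i], wide$ref_count_normal[i]
        ),
        nrow = 2
      ))$p.value
    }, numeric(1))
  } else {
    NA_real_
  }
  positions <- dplyr::mutate(
    dplyr::group_by(wide, .data$sample, .data$gene),
    z = gene_z_scores(.data$ln_odds_ratio)
  )
  positions <- dplyr::ungroup(positions)

  genes <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(positions, abs(.data$position_offset) <= central_halfwidth),
      .data$sample, .data$gene
    ),
    cut_site_z = mean(.data$z), .groups = "drop"
  )
  samples <- dplyr::summarise(
    dplyr::group_by(genes, .data$sample),
    score = mean(.data$cut_site_z), .groups = "drop"
  )
  structure(
    list(
      positions = positions[, c(
        "sample", "gene", "position_offset", "ln_odds_ratio", "p_value", "z"
      )],
      genes = genes,
      samples = samples,
      central_halfwidth = central_halfwidth
    ),
    class = "editing_score"
  )
}

#' @export
print.editing_score <- function(x, ...) {
  cat("<editing_score>\n")
  cat(sprintf(
    "  %d samples, %d gene windows, central half-width %d\n",
    nrow(x$samples), nrow(x$genes), x$central_halfwidth
  ))
  print(x$samples, n = 5)
  invisible(x)
}

#' Call a targeted gene altered from cut-site reads and coverage
#'
#' A gene is considered altered when at least `min_pattern_reads` reads
#' carry the same alteration pattern at the expected cut site, or when
#' coverage of the targeted region drops below half the region median
#' coverage of a healthy control (homozygous deletions can remove the
#' region without leaving altered reads, and frameshift indels need not
#' depress coverage, so the two clauses are alternative evidence modes by
#' default; `mode = "and"` requires both).
#'
#' @param cut_site_reads Character vector of per-read alteration patterns
#'   observed at the cut site (one entry per altered read; e.g. a CIGAR-like
#'   or allele string). Unaltered reads are simply omitted.
#' @param region_coverage Mean coverage of the targeted region in this
#'   sample.
#' @param control_median_coverage Median coverage of the region in a
#'   healthy control (> 0).
#' @param mode Combine the two clauses with `"or"` (default) or `"and"`.
#' @param min_pattern_reads Reads with an identical pattern required
#'   (default 2).
#' @param coverage_fraction Coverage cutoff as a fraction of the control
#'   median (default 0.5).
#' @return One-row tibble: `altered`, `evidence`
#'   (`"pattern_reads"`, `"coverage_drop"`, `"both"` or `"none"`),
#'   `supporting_read_count`, `coverage_fraction_of_control_median`.
#' @examples
#' call_gene_altered(rep("del5", 3), 100, 100)
#' @export
call_gene_altered <- function(cut_site_reads, region_coverage,
                              control_median_coverage,
                              mode = c("or", "and"),
                              min_pattern_reads = 2,
                              coverage_fraction = 0.5) {
  mode <- match.arg(mode)
  if (!is.numeric(control_median_coverage) || control_median_coverage <= 0) {
    abort("`control_median_coverage` must be > 0")
  }
  support <- if (length(cut_site_reads) == 0) {
    0L
  } else {
    max(table(cut_site_reads))
  }
  frac <- region_coverage / control_median_coverage
  pattern_hit <- support >= min_pattern_reads
  coverage_hit <- frac < coverage_fraction
  altered <- if (mode == "or") pattern_hit || coverage_hit else pattern_hit && coverage_hit
  evidence <- if (pattern_hit && coverage_hit) {
    "both"
  } else if (pattern_hit) {
    "pattern_reads"
  } else if (coverage_hit) {
    "coverage_drop"
  } else {
    "none"
  }
  tibble(
    altered = altered,
    evidence = evidence,
    supporting_read_count = as.integer(support),
    coverage_fraction_of_control_median = frac
  )
}
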