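#' Build deduplicated 96-class trinucleotide mutation spectra
#'
#' Maps somatic SNVs to their pyrimidine trinucleotide class
#' ([pyrimidine_class()]), removes duplicate mutations observed in several
#' samples of the same mouse (identical `chrom`, `pos`, `ref`, `alt` count
#' once per mouse), and tallies counts and frequencies over all 96 classes
#' per cohort.
#'
#' @param snvs Data frame of SNVs with columns `chrom`, `pos`, `ref`,
#'   `alt`, `trinuc_context` and `mouse` (or a `sample` column plus
#'   `sample_to_mouse`). Rows whose `ref`/`alt` are not single bases are
#'   rejected.
#' @param sample_to_mouse Optional named character vector mapping sample
#'   ids to mouse ids, used when `snvs` lacks a `mouse` column.
#' @param cohort Optional: either a single label for all mutations, or a
#'   named character vector mapping mouse ids to cohort labels (e.g.
#'   `"metastatic"` vs `"primary+cell-line"`). Defaults to one `"all"`
#'   cohort, the whole-cohort summation mode.
#' @return A `trinuc_spectrum` tibble: one row per cohort and class with
#'   `count` and `frequency` (frequencies sum to 1 within each cohort with
#'   nonzero total).
#' @examples
#' snvs <- tibble::tibble(
#'   mouse = "m1", chrom = "chr1", pos = c(100, 100, 200),
#'   ref = c("C", "C", "G"), alt = c("T", "T", "A"),
#'   trinuc_context = c("ACA", "ACA", "TGT")
#' )
#' trinuc_spectrum(snvs) # duplicate at pos 100 counts once
#' @export
trinuc_spectrum <- function(snvs, sample_to_mouse = NULL, cohort = NULL) {
  v <- as_tibble(snvs)
  if (!"mouse" %in% names(v)) {
    if (is.null(sample_to_mouse) || !"sample" %in% names(v)) {
      abort("`snvs` needs a `mouse` column or a `sample` column plus `sample_to_mouse`")
    }
    v$mouse <- unname(sample_to_mouse[v$sample])
  }
  req <- c("chrom", "pos", "ref", "alt", "trinuc_context")
  miss <- setdiff(req, names(v))
  if (length(miss) > 0) {
    abort(paste0("`snvs` is missing columns: ", paste(miss, collapse = ", ")))
  }
  v <- v[nchar(v$ref) == 1 & nchar(v$alt) == 1, ]
  v <- dplyr::distinct(
    v, .data$mouse, .data$chrom, .data$pos, .data$ref, .data$alt,
    .keep_all = TRUE
  )
  v$class <- if (nrow(v) > 0) {
    pyrimidine_class(v$ref, v$alt, v$trinuc_context)
  } else {
    character(0)
  }
  v$cohort <- if (is.null(cohort)) {
    "all"
  } else if (is.null(names(cohort))) {
    if (length(cohort) != 1) {
      abort("unnamed `cohort` must be a single label")
    }
    cohort
  } else {
    unname(cohort[v$mouse])
  }
  scaffold <- tidyr::expand_grid(
    cohort = unique(v$cohort), class = trinuc_classes()
  )
  counts <- dplyr::count(v, .data$cohort, .data$class, name = "count")
  out <- dplyr::left_join(scaffold, counts, by = c("cohort", "class"))
  out$count <- dplyr::coalesce(out$count, 0L)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$cohort),
    frequency = if (sum(.data$count) > 0) .data$count / sum(.data$count) else 0
  )
  out <- dplyr::ungroup(out)
  structure(out, class = c("trinuc_spectrum", class(out)))
}

#' Cosine similarity between two spectra
#'
#' @param x,y Numeric vectors (e.g. class frequencies aligned on
#'   [trinuc_classes()]).
#' @return Cosine similarity in \[0, 1\] for non-negative inputs.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
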