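#' Re-derive a variant allele fraction from read counts
#'
#' @param alt,depth Alt-supporting and total read counts (vectorized);
#'   `alt` must not exceed `depth`.
#' @return Numeric VAF vector, `alt / depth`; zero-depth entries return 0
#'   and are flagged in the `"zero_depth"` attribute.
#' @examples
#' rederive_vaf(3, 30)
#' @export
rederive_vaf <- function(alt, depth) {
  if (any(depth < 0) || any(alt < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(alt > depth)) {
    abort("alt count exceeds depth")
  }
  zero <- depth == 0
  out <- ifelse(zero, 0, alt / depth)
  attr(out, "zero_depth") <- zero
  out
}

#' Somatic variant filter profiles
#'
#' `filter_profile()` builds an arbitrary threshold set;
#' `murine_filter_profile()` and `msk_filter_profile()` return the two
#' profiles used for murine exomes and for a human targeted panel. The
#' murine profile requires tumor coverage strictly above 20x, normal
#' coverage strictly above 10x and tumor VAF of at least 0.1. The panel
#' profile requires at least 10 tumor reads, at least 5 alt-supporting
#' reads, tumor VAF of at least 5% and normal VAF strictly below 7%.
#'
#' @param min_tumor_depth,min_normal_depth Depth thresholds (reads).
#' @param depth_inclusive If `TRUE` the depth thresholds are `>=`, if
#'   `FALSE` strictly `>`.
#' @param min_tumor_alt Minimum alt-supporting tumor reads (inclusive).
#' @param min_tumor_vaf Minimum tumor VAF (inclusive).
#' @param max_normal_vaf Maximum normal VAF (exclusive), or `NULL` to skip.
#' @param name Profile label carried into filter reports.
#' @return A `filter_profile` object.
#' @export
filter_profile <- function(min_tumor_depth = 0, min_normal_depth = 0,
                           min_tumor_alt = 0, min_tumor_vaf = 0,
                           max_normal_vaf = NULL, depth_inclusive = TRUE,
                           name = "custom") {
  for (v in c(min_tumor_depth, min_normal_depth, min_tumor_alt, min_tumor_vaf)) {
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      abort("filter thresholds must be single non-negative numbers")
    }
  }
  if (min_tumor_vaf > 1) {
    abort("`min_tumor_vaf` must be at most 1")
  }
  structure(
    list(
      min_tumor_depth = min_tumor_depth,
      min_normal_depth = min_normal_depth,
      min_tumor_alt = min_tumor_alt,
      min_tumor_vaf = min_tumor_vaf,
      max_normal_vaf = max_normal_vaf,
      depth_inclusive = depth_inclusive,
      name = name
    ),
    class = "filter_profile"
  )
}

#' @rdname filter_profile
#' @export
murine_filter_profile <- function() {
  filter_profile(
    min_tumor_depth = 20, min_normal_depth = 10, min_tumor_vaf = 0.1,
    depth_inclusive = FALSE, name = "murine"
  )
}

#' @rdname filter_profile
#' @export
msk_filter_profile <- function() {
  filter_profile(
    min_tumor_depth = 10, min_tumor_alt = 5, min_tumor_vaf = 0.05,
    max_normal_vaf = 0.07, depth_inclusive = TRUE, name = "msk"
  )
}

#' @export
print.filter_profile <- function(x, ...) {
  cmp <- if (x$depth_inclusive) ">=" else ">"
  cat(sprintf(
    "<filter_profile \"%s\"> tumor depth %s %g, normal depth %s %g, tumor alt >= %g, tumor VAF >= %g%s\n",
    x$name, cmp, x$min_tumor_depth, cmp, x$min_normal_depth, x$min_tumor_alt,
    x$min_tumor_vaf,
    if (!is.null(x$max_normal_vaf)) {
      sprintf(", normal VAF < %g", x$max_normal_vaf)
    } else ""
  ))
  invisible(x)
}

#' Apply a somatic filter profile to a variant table
#'
#' Evaluates every enabled threshold on each variant; a variant is kept iff
#' all thresholds pass. VAFs are re-derived from the read counts
#' ([rederive_vaf()]). Rejected variants carry the identifier of the first
#' failing rule (rules are checked in the order tumor depth, normal depth,
#' tumor alt reads, tumor VAF, normal VAF). The operation is idempotent:
#' re-filtering the kept set changes nothing.
#'
#' @param variants Data frame with columns `tumor_depth`, `tumor_alt`,
#'   `normal_depth`, `normal_alt` (other columns pass through).
#' @param profile A [filter_profile()].
#' @return The input as a tibble with columns `tumor_vaf`, `normal_vaf`,
#'   `kept` (logical) and `filter_reason` (`NA` for kept variants) appended.
#' @examples
#' v <- tibble::tibble(
#'   tumor_depth = c(25, 20), tumor_alt = c(5, 5),
#'   normal_depth = c(12, 12), normal_alt = c(0, 0)
#' )
#' apply_filter(v, murine_filter_profile())
#' @export
apply_filter <- function(variants, profile) {
  if (!inherits(profile, "filter_profile")) {
    abort("`profile` must be a filter_profile")
  }
  req <- c("tumor_depth", "tumor_alt", "normal_depth", "normal_alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    abort(paste0("`variants` is missing columns: ", paste(miss, collapse = ", ")))
  }
  v <- as_tibble(variants)
  v$tumor_vaf <- as.numeric(rederive_vaf(v$tumor_alt, v$tumor_depth))
  v$normal_vaf <- as.numeric(rederive_vaf(v$normal_alt, v$normal_depth))
  n <- nrow(v)
  reason <- rep(NA_character_, n)
  fail <- function(cur, hit, id) ifelse(is.na(cur) & hit, id, cur)
  depth_ok <- function(x, thr) {
    if (profile$depth_inclusive) x >= thr else x > thr
  }
  reason <- fail(reason, !depth_ok(v$tumor_depth, profile$min_tumor_depth), "tumor_depth")
  reason <- fail(reason, !depth_ok(v$normal_depth, profile$min_normal_depth), "normal_depth")
  reason <- fail(reason, v$tumor_alt < profile$min_tumor_alt, "tumor_alt")
  reason <- fail(reason, v$tumor_vaf < profile$min_tumor_vaf, "tumor_vaf")
  if (!is.null(profile$max_normal_vaf)) {
    reason <- fail(reason, v$normal_vaf >= profile$max_normal_vaf, "normal_vaf")
  }
  v$kept <- is.na(reason)
  v$filter_reason <- reason
  v
}

tandem_repeat_fail <- function(s) {
  # fail iff some motif of length 1..6 occurs >= 3 times in tandem,
  # entirely inside the 20-nt window; motifs containing N never match
  n <- nchar(s)
  for (k in 1:6) {
    if (3 * k > n) break
    for (start in 1:(n - 3 * k + 1)) {
      motif <- substr(s, start, start + k - 1)
      if (grepl("N", motif, fixed = TRUE)) next
      copies <- 1
      pos <- start + k
      while (pos + k - 1 <= n && substr(s, pos, pos + k - 1) == motif) {
        copies <- copies + 1
        pos <- pos + k
      }
      if (copies >= 3) {
        return(TRUE)
      }
    }
  }
  FALSE
}

any_occurrence_fail <- function(s) {
  n <- nchar(s)
  for (k in 1:6) {
    if (3 * k > n) break
    subs <- substring(s, 1:(n - k + 1), k:n)
    subs <- subs[!grepl("N", subs, fixed = TRUE)]
    if (any(table(subs) >= 3)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Screen indel downstream context for repetitive sequence
#'
#' Indel calls inside short tandem repeats are a classic false-positive
#' mode; this screen fails any call whose 20 nucleotides of downstream
#' context contain a motif of length 1 to 6 repeated at least three times.
#' The default `"tandem"` mode requires the three copies to be consecutive
#' (the microsatellite rationale); `"any"` counts non-adjacent occurrences
#' too, for sensitivity analyses. `N` bases never match a motif.
#'
#' @param downstream_20nt Character vector of 20-nucleotide strings over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param mode `"tandem"` (default) or `"any"`.
#' @return Character vector, `"pass"` or `"fail"` per window.
#' @examples
#' repeat_filter("ACACACACACGTGTTCCGAT") # fail: AC x5
#' repeat_filter("ACGTGATCGTAGCTGACTGA") # pass
#' @export
repeat_filter <- function(downstream_20nt, mode = c("tandem", "any")) {
  mode <- match.arg(mode)
  if (any(nchar(downstream_20nt) != 20)) {
    abort("downstream context strings must be exactly 20 nucleotides")
  }
  if (any(grepl("[^ACGTN]", downstream_20nt))) {
    abort("downstream context may only contain A, C, G, T, N")
  }
  f <- if (mode == "tandem") tandem_repeat_fail else any_occurrence_fail
  ifelse(vapply(downstream_20nt, f, logical(1), USE.NAMES = FALSE),
    "fail", "pass"
  )
}

bed_to_granges <- function(bed, pad = 0) {
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(bed))
  if (length(miss) > 0) {
    abort(paste0("BED table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(bed$end <= bed$start)) {
    abort("malformed interval: end must be greater than start")
  }
  GenomicRanges::GRanges(
    bed$chrom,
    IRanges::IRanges(pmax(1, bed$start + 1 - pad), bed$end + pad)
  )
}

#' Remove variants falling in sgRNA-targeted regions
#'
#' Mutations at engineered cut sites are drivers introduced by the editing
#' itself; downstream mutation statistics (burden, spectra, progression
#' trees) use only the remaining nondriver somatic mutations. A variant is
#' removed when its reference span overlaps any targeted interval padded by
#' `pad` bases on each side.
#'
#' @param variants Data frame with 1-based `chrom`, `pos`, `ref` columns.
#' @param targeted_regions BED-style data frame (`chrom`, `start`, `end`,
#'   0-based half-open), or `NULL`/empty for a no-op.
#' @param pad Padding in bases (default 50).
#' @return The variants outside all padded regions, as a tibble.
#' @export
exclude_sgrna_regions <- function(variants, targeted_regions, pad = 50) {
  v <- as_tibble(variants)
  if (is.null(targeted_regions) || nrow(targeted_regions) == 0) {
    return(v)
  }
  targets <- bed_to_granges(targeted_regions, pad = pad)
  span <- GenomicRanges::GRanges(
    v$chrom,
    IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1)
  )
  hit <- IRanges::overlapsAny(span, targets)
  v[!hit, ]
}

#' Somatic mutational burden in mutations per megabase
#'
#' @param n_exonic_variants Number of kept exonic somatic mutations.
#' @param callable_size_mb Callable territory in Mb (e.g. the exome target
#'   span, [callable_size_mb()]); must be > 0.
#' @return Mutations per Mb.
#' @examples
#' mutational_burden(34, 100) # 0.34
#' @export
mutational_burden <- function(n_exonic_variants, callable_size_mb) {
  if (!is.numeric(callable_size_mb) || callable_size_mb <= 0) {
    abort("`callable_size_mb` must be > 0")
  }
  n_exonic_variants / callable_size_mb
}

#' @rdname mutational_burden
#' @param targets BED-style data frame of callable intervals.
#' @export
callable_size_mb <- function(targets) {
  if (any(targets$end <= targets$start)) {
    abort("malformed interval: end must be greater than start")
  }
  sum(targets$end - targets$start) / 1e6
}
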