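VARIANT_COUNT_COLS <- c("tumor_depth", "tumor_alt", "normal_depth", "normal_alt")

validate_variant_counts <- function(v, path) {
  bad <- which(
    v$tumor_alt > v$tumor_depth | v$normal_alt > v$normal_depth |
      v$tumor_alt < 0 | v$normal_alt < 0
  )
  if (length(bad) > 0) {
    abort(paste0(
      "malformed variant rows in ", path, " (alt > depth or negative) at line(s): ",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  invisible(v)
}

#' Read a somatic variant table
#'
#' Reads either a tab-separated table with the package's column layout or
#' a minimal VCF v4.2 with per-sample `DP` and `AD` FORMAT fields (two
#' genotype columns: tumor first, matched normal second; `AD` as
#' `ref,alt`). Malformed rows (alt count exceeding depth) are rejected
#' with their line numbers.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return Tibble with at least `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_depth`, `tumor_alt`, `normal_depth`, `normal_alt`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    v <- readr::read_tsv(path, show_col_types = FALSE)
    req <- c("chrom", "pos", "ref", "alt", VARIANT_COUNT_COLS)
    miss <- setdiff(req, names(v))
    if (length(miss) > 0) {
      abort(paste0(
        "variant table ", path, " is missing required columns: ",
        paste(miss, collapse = ", ")
      ))
    }
    return(validate_variant_counts(v, path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_samples <- colnames(vcf@gt)[-1]
  if (length(gt_samples) < 2) {
    abort(paste0("VCF ", path, " needs two genotype columns (tumor, normal)"))
  }
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  alt_of <- function(x) as.integer(vapply(strsplit(x, ",", fixed = TRUE), `[`, character(1), 2))
  v <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    tumor_depth = as.integer(dp[, 1]),
    tumor_alt = alt_of(ad[, 1]),
    normal_depth = as.integer(dp[, 2]),
    normal_alt = alt_of(ad[, 2])
  )
  validate_variant_counts(v, path)
}

#' Write a somatic variant table
#'
#' The TSV writer round-trips every column; the VCF writer emits a minimal
#' VCF v4.2 with `DP`/`AD` FORMAT fields and tumor/normal genotype columns
#' (additional columns are dropped).
#'
#' @param variants Variant data frame.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(variants, path)
    return(invisible(path))
  }
  v <- variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "TUMOR", "NORMAL",
      sep = "\t"
    )
  )
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
    "DP:AD",
    paste0(v$tumor_depth, ":", v$tumor_depth - v$tumor_alt, ",", v$tumor_alt),
    paste0(v$normal_depth, ":", v$normal_depth - v$normal_alt, ",", v$normal_alt),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write BED interval tables
#'
#' BED files are headerless, tab-separated, 0-based half-open. Columns
#' beyond the third are kept as `name`, etc.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` (and `name`
#'   when present).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE,
    comment = "#"
  )
  if (ncol(b) < 3) {
    abort(paste0("BED file ", path, " needs at least 3 columns"))
  }
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "name"
  if (any(b$end <= b$start)) {
    abort(paste0("BED file ", path, ": end must exceed start on every line"))
  }
  b
}

#' @rdname read_bed
#' @param bed BED-style data frame (`chrom`, `start`, `end`, ...).
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read/write SEG-like per-exon log2 ratio tables
#'
#' Tab-separated with a header; requires `chrom`, `start`, `end`,
#' `weight`, `log2` (0-based half-open intervals, non-negative weights).
#'
#' @param path File path.
#' @return Tibble of validated exon rows.
#' @export
read_seg <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chrom", "start", "end", "weight", "log2")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0) {
    abort(paste0(
      "SEG table ", path, " is missing columns: ", paste(miss, collapse = ", ")
    ))
  }
  if (any(s$end <= s$start)) {
    abort(paste0("SEG table ", path, ": end must exceed start"))
  }
  if (any(s$weight < 0)) {
    abort(paste0("SEG table ", path, ": weights must be non-negative"))
  }
  s
}

#' @rdname read_seg
#' @param seg SEG-like data frame.
#' @export
write_seg <- function(seg, path) {
  readr::write_tsv(seg, path)
  invisible(path)
}

#' Read a B-allele-frequency table
#'
#' Tab-separated with a header; requires `chrom`, `pos` and tumor/normal
#' ref/alt counts; BAF columns are recomputed from the counts.
#'
#' @param path File path.
#' @return Tibble with `baf_normal` and `baf_tumor` filled in.
#' @export
read_baf <- function(path) {
  b <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chrom", "pos", "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
  miss <- setdiff(req, names(b))
  if (length(miss) > 0) {
    abort(paste0(
      "BAF table ", path, " is missing columns: ", paste(miss, collapse = ", ")
    ))
  }
  nd <- b$normal_ref + b$normal_alt
  td <- b$tumor_ref + b$tumor_alt
  b$baf_normal <- ifelse(nd > 0, b$normal_alt / nd, NA_real_)
  b$baf_tumor <- ifelse(td > 0, b$tumor_alt / td, NA_real_)
  b
}

#' Read a cellularity-ploidy probability grid
#'
#' @param path Tab-separated file with header columns `cellularity`,
#'   `ploidy`, `probability`.
#' @return Tibble grid for [select_ploidy()].
#' @export
read_grid <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("cellularity", "ploidy", "probability")
  miss <- setdiff(req, names(g))
  if (length(miss) > 0) {
    abort(paste0(
      "grid table ", path, " is missing columns: ", paste(miss, collapse = ", ")
    ))
  }
  if (any(g$probability < 0)) {
    abort(paste0("grid table ", path, ": probabilities must be non-negative"))
  }
  g
}

#' Serialize a cohort configuration to YAML and back
#'
#' The write/read round trip is lossless: `read_run_config()` re-validates
#' through [cohort_config()] and returns an identical object.
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the rebuilt `cohort_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  plain <- unclass(config)
  plain$signature_mix <- as.list(config$signature_mix)
  plain$arm_events <- as.list(config$arm_events)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$signature_mix <- unlist(plain$signature_mix)
  plain$arm_events <- unlist(plain$arm_events) %||% character(0)
  do.call(cohort_config, plain)
}
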