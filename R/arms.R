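#' Chromosome-arm definition tables
#'
#' Returns the arm table used for arm-level copy-number calling and for the
#' synthetic cohort generator. The mouse (mm10) model treats the 19
#' acrocentric autosomes as single q arms spanning the whole chromosome
#' (mouse centromeres are telocentric, so there is no usable p arm). The
#' human (GRCh37) model uses the 39 autosomal arms conventionally scored in
#' aneuploidy analyses (the p arms of the acrocentric chromosomes 13, 14,
#' 15, 21 and 22 are excluded); arm boundaries are approximate centromere
#' midpoints from the GRCh37 cytoband annotation.
#'
#' @param genome `"mm10"` (default) or `"grch37"`.
#' @return A tibble with columns `arm`, `chrom`, `start`, `end` (0-based
#'   half-open coordinates) and `length` (bases).
#' @examples
#' arm_table("mm10")
#' @export
arm_table <- function(genome = c("mm10", "grch37")) {
  genome <- match.arg(genome)
  if (genome == "mm10") {
    len <- c(
      chr1 = 195471971, chr2 = 182113224, chr3 = 160039680, chr4 = 156508116,
      chr5 = 151834684, chr6 = 149736546, chr7 = 145441459, chr8 = 129401213,
      chr9 = 124595110, chr10 = 130694993, chr11 = 122082543, chr12 = 120129022,
      chr13 = 120421639, chr14 = 124902244, chr15 = 104043685, chr16 = 98207768,
      chr17 = 94987271, chr18 = 90702639, chr19 = 61431566
    )
    out <- tibble(
      arm = paste0(names(len), "q"),
      chrom = names(len),
      start = 0,
      end = unname(len)
    )
  } else {
    # chromosome length and centromere midpoint (GRCh37, approximate)
    tab <- tibble(
      chrom = paste0("chr", 1:22),
      len = c(
        249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
        159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
        115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
        59128983, 63025520, 48129895, 51304566
      ),
      cen = c(
        125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
        59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
        17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
        26500000, 27500000, 13200000, 14700000
      )
    )
    acro <- paste0("chr", c(13, 14, 15, 21, 22))
    p <- tibble(
      arm = paste0(sub("chr", "", tab$chrom), "p"), chrom = tab$chrom,
      start = 0, end = tab$cen
    )[!tab$chrom %in% acro, ]
    q <- tibble(
      arm = paste0(sub("chr", "", tab$chrom), "q"), chrom = tab$chrom,
      start = tab$cen, end = tab$len
    )
    out <- dplyr::arrange(dplyr::bind_rows(p, q), .data$chrom, .data$start)
  }
  dplyr::mutate(out, length = .data$end - .data$start)
}

check_arm_table <- function(arms) {
  req <- c("arm", "chrom", "start", "end", "length")
  miss <- setdiff(req, names(arms))
  if (length(miss) > 0) {
    abort(paste0("arm table is missing columns: ", paste(miss, collapse = ", ")))
  }
  gr <- GenomicRanges::GRanges(
    arms$chrom, IRanges::IRanges(arms$start + 1, arms$end)
  )
  hits <- GenomicRanges::findOverlaps(gr, gr)
  if (length(hits) > nrow(arms)) {
    abort("arm definitions overlap within the table")
  }
  invisible(arms)
}
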