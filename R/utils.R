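DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

#' The 96 pyrimidine-context single-nucleotide substitution classes
#'
#' Classes are written `X[R>A]Y` where `R` is the pyrimidine reference base
#' (C or T), `A` the alternate base, and `X`/`Y` the flanking bases, the
#' ordering conventionally used for mutational spectra.
#'
#' @return Character vector of the 96 class labels.
#' @examples
#' head(trinuc_classes())
#' @export
trinuc_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (up in DNA_BASES) {
      for (dn in DNA_BASES) {
        out <- c(out, paste0(up, "[", s, "]", dn))
      }
    }
  }
  out
}

#' Map an SNV to its pyrimidine trinucleotide class
#'
#' Substitutions whose reference base is a purine are reverse-complemented
#' (alternate base and flanking context included) so that every SNV lands in
#' one of the 96 pyrimidine-context classes.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context The 3-mer centered on the variant position, on the same
#'   strand as `ref`.
#' @return Character vector of class labels, e.g. `"A[C>T]G"`.
#' @examples
#' pyrimidine_class("G", "A", "TGT") # reverse-complements to A[C>T]A
#' @export
pyrimidine_class <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  bad <- !nchar(context) == 3 | substr(context, 2, 2) != ref |
    !ref %in% DNA_BASES | !alt %in% DNA_BASES | ref == alt
  if (any(bad)) {
    abort(paste0(
      "invalid SNV context at entries: ",
      paste(utils::head(which(bad), 5), collapse = ", "),
      " (context must be a 3-mer with the reference base at its center)"
    ))
  }
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("AG", "TC", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  paste0(
    substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3)
  )
}

# stage-scoped child seeds derived from one top-level seed (kept < 2^31)
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 97) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min),
      class = "mosaicevo_config_error"
    )
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (x > lo || (!lo_open && x == lo)) && x <= hi
  if (!ok) {
    abort(paste0(
      "`", name, "` must be a fraction in ",
      if (lo_open) "(" else "[", lo, ", ", hi, "]"
    ), class = "mosaicevo_config_error")
  }
  invisible(x)
}
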