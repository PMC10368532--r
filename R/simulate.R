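#' Default trinucleotide signature mixture
#'
#' A C>T-dominated mixture emulating the spontaneous-deamination mutational
#' process that dominates renal tumors: 55% of mass spread over the four
#' `N[C>T]G` classes, 15% over the remaining C>T classes, and the rest
#' uniform over all other classes.
#'
#' @return Named numeric vector over the 96 classes, summing to 1.
#' @export
default_signature_mix <- function() {
  cls <- trinuc_classes()
  mix <- setNames(rep(0, length(cls)), cls)
  ctg <- grepl("\\[C>T\\]G$", cls)
  ct <- grepl("\\[C>T\\]", cls) & !ctg
  other <- !ctg & !ct
  mix[ctg] <- 0.55 / sum(ctg)
  mix[ct] <- 0.15 / sum(ct)
  mix[other] <- 0.30 / sum(other)
  mix
}

#' Expected variant allele fraction under the purity/copy-number model
#'
#' For a heterozygous somatic mutation of multiplicity `m` on a region of
#' tumor total copy number `C` in a sample of purity `p`, the expected VAF
#' is `p * m / (2 * (1 - p) + p * C)`: the tumor contributes `p * C` locus
#' copies of which `p * m` carry the variant, and contaminating normal cells
#' contribute `2 * (1 - p)`.
#'
#' @param purity Tumor cell fraction in (0, 1].
#' @param copy_number Total tumor copy number at the locus.
#' @param multiplicity Number of tumor copies carrying the variant.
#' @return Expected VAF (vectorized).
#' @examples
#' expected_vaf(1, 2, 1) # 0.5
#' expected_vaf(0.6, 3, 1)
#' @export
expected_vaf <- function(purity, copy_number, multiplicity = 1) {
  purity * multiplicity / (2 * (1 - purity) + purity * copy_number)
}

#' Cohort simulation configuration
#'
#' Bundles and validates every parameter of the synthetic tumor cohort.
#' Defaults emulate the structure of a multi-sample murine renal tumor
#' study: 19 mice with several tumor samples each, a small truncal trunk
#' with mostly private point mutations, recurrent gain of chromosome 5 and
#' losses of chromosomes 12 and 16, moderate exome depth, and highly
#' efficient cut-site editing.
#'
#' @param n_mice Number of mice.
#' @param samples_per_mouse Tumor samples per mouse (each mouse also gets one
#'   matched normal).
#' @param n_truncal_mutations Somatic SNVs shared by all samples of a mouse.
#' @param n_private_mutations_per_sample Somatic SNVs unique to each sample.
#' @param n_clade_mutations SNVs shared within each clade when
#'   `topology = "nested"`.
#' @param n_indels_per_sample Private somatic indels per sample (these carry
#'   the 20-nt downstream context used by the tandem-repeat screen).
#' @param indel_tandem_fraction Fraction of simulated indels whose downstream
#'   context is forced to be a tandem repeat, giving the repeat screen
#'   positive cases; the rest use a uniform nucleotide model.
#' @param purity Tumor cell fraction in (0, 1], shared by all samples.
#' @param mean_depth Mean sequencing depth (reads); per-site depths are
#'   Poisson.
#' @param arm_events Named character vector of arm-level events, e.g.
#'   `c(chr5q = "gain", chr12q = "loss")`; applied to every tumor sample.
#' @param wgd Logical; if `TRUE` the whole karyotype is doubled.
#' @param editing_rate Fraction of tumor reads altered at the sgRNA cut
#'   site, in \[0, 1\].
#' @param signature_mix Named probability vector over the 96 trinucleotide
#'   classes; must sum to 1.
#' @param noise_sd_log2 Standard deviation of per-exon log2 read-depth
#'   ratio noise.
#' @param background_error Per-base background alteration rate at
#'   non-cut-site positions and in normals.
#' @param genome Arm table to simulate on (`"mm10"` or `"grch37"`).
#' @param topology `"star"` (truncal trunk plus one private branch per
#'   sample) or `"nested"` (two clades of samples with clade-shared
#'   mutations) for tree-recovery experiments.
#' @param n_exons_per_arm,n_snps_per_arm Exome targets and germline SNPs
#'   simulated per chromosome arm.
#' @param targeted_genes Names of sgRNA-targeted genes.
#' @param window_halfwidth Half-width (bases) of the cut-site pileup window.
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return A validated `cohort_config` object (a named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_mice = 19,
                          samples_per_mouse = 4,
                          n_truncal_mutations = 5,
                          n_private_mutations_per_sample = 15,
                          n_clade_mutations = 8,
                          n_indels_per_sample = 3,
                          indel_tandem_fraction = 0.2,
                          purity = 0.7,
                          mean_depth = 80,
                          arm_events = c(chr5q = "gain", chr12q = "loss", chr16q = "loss"),
                          wgd = FALSE,
                          editing_rate = 0.8,
                          signature_mix = default_signature_mix(),
                          noise_sd_log2 = 0.1,
                          background_error = 0.002,
                          genome = c("mm10", "grch37"),
                          topology = c("star", "nested"),
                          n_exons_per_arm = 40,
                          n_snps_per_arm = 30,
                          targeted_genes = c("Nf2", "Setd2", "Cdkn2a"),
                          window_halfwidth = 25,
                          seed = 1L) {
  genome <- match.arg(genome)
  topology <- match.arg(topology)
  check_count(n_mice, "n_mice", min = 1)
  check_count(samples_per_mouse, "samples_per_mouse", min = 1)
  check_count(n_truncal_mutations, "n_truncal_mutations")
  check_count(n_private_mutations_per_sample, "n_private_mutations_per_sample")
  check_count(n_clade_mutations, "n_clade_mutations")
  check_count(n_indels_per_sample, "n_indels_per_sample")
  check_fraction(indel_tandem_fraction, "indel_tandem_fraction")
  check_fraction(purity, "purity", lo = 0, lo_open = TRUE)
  if (!is.numeric(mean_depth) || length(mean_depth) != 1 || mean_depth <= 0) {
    abort("`mean_depth` must be a single value > 0",
      class = "mosaicevo_config_error"
    )
  }
  check_fraction(editing_rate, "editing_rate")
  check_fraction(background_error, "background_error")
  check_fraction(noise_sd_log2, "noise_sd_log2", hi = Inf)
  if (abs(sum(signature_mix) - 1) > 1e-9) {
    abort("`signature_mix` must sum to 1", class = "mosaicevo_config_error")
  }
  if (!all(names(signature_mix) %in% trinuc_classes())) {
    abort("`signature_mix` has names outside the 96 trinucleotide classes",
      class = "mosaicevo_config_error"
    )
  }
  arms <- arm_table(genome)
  if (length(arm_events) > 0) {
    if (is.null(names(arm_events)) || !all(names(arm_events) %in% arms$arm)) {
      abort(paste0("`arm_events` must be named by arms of the ", genome, " table"),
        class = "mosaicevo_config_error"
      )
    }
    if (!all(arm_events %in% c("gain", "loss"))) {
      abort("`arm_events` states must be \"gain\" or \"loss\"",
        class = "mosaicevo_config_error"
      )
    }
  }
  if (!is.logical(wgd) || length(wgd) != 1 || is.na(wgd)) {
    abort("`wgd` must be TRUE or FALSE", class = "mosaicevo_config_error")
  }
  check_count(n_exons_per_arm, "n_exons_per_arm", min = 1)
  check_count(n_snps_per_arm, "n_snps_per_arm", min = 1)
  check_count(window_halfwidth, "window_halfwidth", min = 1)
  check_count(seed, "seed")
  cfg <- list(
    n_mice = as.integer(n_mice),
    samples_per_mouse = as.integer(samples_per_mouse),
    n_truncal_mutations = as.integer(n_truncal_mutations),
    n_private_mutations_per_sample = as.integer(n_private_mutations_per_sample),
    n_clade_mutations = as.integer(n_clade_mutations),
    n_indels_per_sample = as.integer(n_indels_per_sample),
    indel_tandem_fraction = indel_tandem_fraction,
    purity = purity,
    mean_depth = mean_depth,
    arm_events = arm_events,
    wgd = wgd,
    editing_rate = editing_rate,
    signature_mix = signature_mix,
    noise_sd_log2 = noise_sd_log2,
    background_error = background_error,
    genome = genome,
    topology = topology,
    n_exons_per_arm = as.integer(n_exons_per_arm),
    n_snps_per_arm = as.integer(n_snps_per_arm),
    targeted_genes = targeted_genes,
    window_halfwidth = as.integer(window_halfwidth),
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  %d mice x %d samples, purity %.2f, depth %gx, %s genome\n",
    x$n_mice, x$samples_per_mouse, x$purity, x$mean_depth, x$genome
  ))
  cat(sprintf(
    "  clone tree: %s; arm events: %s; WGD: %s; editing rate %.2f\n",
    x$topology,
    if (length(x$arm_events)) {
      paste(names(x$arm_events), x$arm_events, collapse = ", ")
    } else "none",
    x$wgd, x$editing_rate
  ))
  invisible(x)
}

# total tumor copy number and B-allele copies per arm for one mouse
arm_truth <- function(config, arms) {
  state <- setNames(rep("neutral", nrow(arms)), arms$arm)
  state[names(config$arm_events)] <- config$arm_events
  cn <- ifelse(state == "gain", 3L, ifelse(state == "loss", 1L, 2L))
  # which allele the event hits is random per mouse/arm
  b_affected <- stats::runif(nrow(arms)) < 0.5
  nb <- ifelse(
    state == "gain", ifelse(b_affected, 2L, 1L),
    ifelse(state == "loss", ifelse(b_affected, 0L, 1L), 1L)
  )
  mult <- if (config$wgd) 2L else 1L
  tibble(
    arm = arms$arm, chrom = arms$chrom, state = unname(state),
    copy_number = cn * mult, b_copies = nb * mult
  )
}

#' Simulate trinucleotide-classed SNVs from a signature mixture
#'
#' Draws `n` single-nucleotide variants whose 96-class frequencies follow
#' `signature_mix`. Each variant is reported on a random reference strand,
#' so roughly half carry a purine reference base with the
#' reverse-complemented context — exercising the pyrimidine normalization
#' performed by [trinuc_spectrum()].
#'
#' @param signature_mix Named probability vector over (a subset of) the 96
#'   classes; must sum to 1.
#' @param n Number of variants.
#' @param seed Optional integer seed.
#' @return Tibble with columns `class` (pyrimidine class), `ref`, `alt`,
#'   `trinuc_context` (as observed on the reference strand).
#' @examples
#' simulate_trinuc_mutations(c("A[C>T]G" = 1), 3, seed = 1)
#' @export
simulate_trinuc_mutations <- function(signature_mix, n, seed = NULL) {
  check_count(n, "n")
  if (abs(sum(signature_mix) - 1) > 1e-9) {
    abort("`signature_mix` must sum to 1", class = "mosaicevo_config_error")
  }
  if (is.null(names(signature_mix)) ||
    !all(names(signature_mix) %in% trinuc_classes())) {
    abort("`signature_mix` must be named by trinucleotide classes",
      class = "mosaicevo_config_error"
    )
  }
  draw <- function() {
    if (n == 0) {
      return(tibble(
        class = character(), ref = character(), alt = character(),
        trinuc_context = character()
      ))
    }
    cls <- sample(names(signature_mix), n, replace = TRUE, prob = signature_mix)
    up <- substr(cls, 1, 1)
    ref <- substr(cls, 3, 3)
    alt <- substr(cls, 5, 5)
    dn <- substr(cls, 7, 7)
    ctx <- paste0(up, ref, dn)
    flip <- stats::runif(n) < 0.5
    ref[flip] <- chartr("CT", "GA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
    tibble(class = cls, ref = ref, alt = alt, trinuc_context = ctx)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a paired tumor/normal cut-site pileup
#'
#' Emits per-position reference/altered read counts over a window of
#' `2 * window_halfwidth + 1` positions centered on an expected sgRNA cut
#' site. The normal compartment carries only the background alteration
#' rate; the tumor additionally carries editing-induced alterations at
#' positions within 2 bases of the cut site, at approximately
#' `editing_rate`.
#'
#' @param editing_rate Fraction of tumor reads altered at the cut site.
#' @param depth Mean read depth (per-position depths are Poisson).
#' @param window_halfwidth Half-width of the window in bases (default 25,
#'   i.e. a 50-bp window around the cut site).
#' @param background_error Background per-base alteration rate.
#' @param gene,sample Identifiers carried into the output.
#' @param seed Optional integer seed.
#' @return Tibble with columns `gene`, `sample`, `compartment`
#'   (`"tumor"`/`"normal"`), `position_offset`, `ref_count`, `alt_count`.
#' @export
simulate_cutsite_pileup <- function(editing_rate, depth, window_halfwidth = 25,
                                    background_error = 0.002,
                                    gene = "gene1", sample = "sample1",
                                    seed = NULL) {
  check_fraction(editing_rate, "editing_rate")
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0) {
    abort("`depth` must be a single value > 0", class = "mosaicevo_config_error")
  }
  check_count(window_halfwidth, "window_halfwidth", min = 1)
  draw <- function() {
    off <- seq(-window_halfwidth, window_halfwidth)
    n <- length(off)
    cut <- abs(off) <= 2
    rate_t <- ifelse(cut, editing_rate + (1 - editing_rate) * background_error,
      background_error
    )
    d_t <- pmax(1L, rpois(n, depth))
    d_n <- pmax(1L, rpois(n, depth))
    a_t <- rbinom(n, d_t, rate_t)
    a_n <- rbinom(n, d_n, background_error)
    dplyr::bind_rows(
      tibble(
        gene = gene, sample = sample, compartment = "tumor",
        position_offset = off, ref_count = d_t - a_t, alt_count = a_t
      ),
      tibble(
        gene = gene, sample = sample, compartment = "normal",
        position_offset = off, ref_count = d_n - a_n, alt_count = a_n
      )
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

random_dna <- function(n, len) {
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1)
  )
}

tandem_dna20 <- function(n) {
  vapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    motif <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    copies <- ceiling(20 / k) + 2
    substr(strrep(motif, copies), 1, 20)
  }, character(1))
}

# binomial tumor/normal read counts for a block of mutations
draw_counts <- function(n, vaf, mean_depth, background_error) {
  d_t <- pmax(1L, rpois(n, mean_depth))
  d_n <- pmax(1L, rpois(n, mean_depth))
  tibble(
    tumor_depth = d_t,
    tumor_alt = rbinom(n, d_t, vaf),
    normal_depth = d_n,
    normal_alt = rbinom(n, d_n, background_error)
  )
}

#' Simulate a multi-mouse tumor cohort with known ground truth
#'
#' Generates, fully in silico, a cohort of mice each carrying several tumor
#' samples that share a clonal tree: truncal mutations present in every
#' sample, optional clade-shared mutations (nested topology), and private
#' mutations unique to one sample. Every sample receives caller-style
#' variant tables with binomial read counts at the purity/copy-number
#' expected VAF (see [expected_vaf()]), paired tumor/normal cut-site
#' pileups for each targeted gene, per-exon log2 read-depth ratios
#' reflecting the configured arm events (and WGD), germline-SNP B-allele
#' frequency tables, and a cellularity–ploidy probability grid.
#'
#' Variant tables are emitted in "union re-genotyped" form: every mutation
#' of a mouse appears as a row in every sample of that mouse, with alt
#' count 0 where the mutation is absent, mirroring pipelines that
#' re-interrogate reads across all samples of an animal.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle`: a list with tibbles `samples`, `variants`,
#'   `pileups`, `seg`, `baf`, `grids`, `targets` (exome BED intervals),
#'   `sgrna_targets` (targeted-region BED intervals), and a `truth` list
#'   holding per-arm copy-number states, ploidy, WGD status and the clade
#'   membership of every sample.
#' @examples
#' bundle <- simulate_cohort(cohort_config(n_mice = 2, seed = 7))
#' dplyr::count(bundle$variants, branch == "truncal")
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config()",
      class = "mosaicevo_config_error"
    )
  }
  arms <- arm_table(config$genome)
  with_seed(derive_seed(config$seed, "cohort"), {
    mice <- sprintf("mouse%02d", seq_len(config$n_mice))
    site_cycle <- c("primary", "primary", "metastasis", "cell-line")
    samples <- purrr::map_dfr(mice, function(m) {
      idx <- seq_len(config$samples_per_mouse)
      clade <- if (config$topology == "nested") {
        ifelse(idx <= ceiling(config$samples_per_mouse / 2), "clade_1", "clade_2")
      } else {
        rep(NA_character_, length(idx))
      }
      tibble(
        mouse = m,
        sample = sprintf("%s_s%d", m, idx),
        site_class = site_cycle[(idx - 1) %% length(site_cycle) + 1],
        purity = config$purity,
        clade = clade
      )
    })

    # targeted genes: fixed loci, one per (spread-out) arm
    gidx <- ((seq_along(config$targeted_genes) - 1) * 3) %% nrow(arms) + 1
    sgrna_targets <- tibble(
      gene = config$targeted_genes,
      chrom = arms$chrom[gidx],
      cut_pos = round(arms$start[gidx] + 0.4 * arms$length[gidx])
    )
    sgrna_bed <- tibble(
      chrom = sgrna_targets$chrom,
      start = sgrna_targets$cut_pos - config$window_halfwidth - 1,
      end = sgrna_targets$cut_pos + config$window_halfwidth,
      name = sgrna_targets$gene
    )

    # exome targets: evenly spaced 200-bp exons per arm
    targets <- purrr::map_dfr(seq_len(nrow(arms)), function(i) {
      s <- round(seq(arms$start[i] + 1e4, arms$end[i] - 1e4,
        length.out = config$n_exons_per_arm
      ))
      tibble(chrom = arms$chrom[i], start = s, end = s + 200L)
    })

    per_mouse <- purrr::map(mice, function(m) {
      simulate_mouse(config, arms, samples[samples$mouse == m, ],
        sgrna_targets,
        targets = targets
      )
    })

    bundle <- list(
      config = config,
      samples = samples,
      variants = purrr::map_dfr(per_mouse, "variants"),
      pileups = purrr::map_dfr(per_mouse, "pileups"),
      seg = purrr::map_dfr(per_mouse, "seg"),
      baf = purrr::map_dfr(per_mouse, "baf"),
      grids = purrr::map_dfr(per_mouse, "grids"),
      targets = targets,
      sgrna_targets = sgrna_bed,
      truth = list(
        ploidy = if (config$wgd) 4 else 2,
        wgd = config$wgd,
        arm_states = purrr::map_dfr(per_mouse, "arm_states"),
        clades = samples[, c("mouse", "sample", "clade")]
      )
    )
    structure(bundle, class = "cohort_bundle")
  })
}

simulate_mouse <- function(config, arms, mouse_samples, sgrna_targets, targets) {
  m <- mouse_samples$mouse[1]
  truth <- arm_truth(config, arms)
  truth$mouse <- m
  p <- config$purity
  cn_of_arm <- setNames(truth$copy_number, truth$arm)
  arm_of_chrom <- setNames(arms$arm, arms$chrom)

  place_snvs <- function(n, branch) {
    if (n == 0) {
      return(NULL)
    }
    i <- sample.int(nrow(arms), n, replace = TRUE, prob = arms$length)
    ctx <- simulate_trinuc_mutations(config$signature_mix, n)
    tibble(
      chrom = arms$chrom[i],
      pos = floor(stats::runif(n, arms$start[i] + 1, arms$end[i])),
      ref = ctx$ref, alt = ctx$alt,
      variant_class = "SNV",
      trinuc_context = ctx$trinuc_context,
      downstream_20nt = NA_character_,
      branch = branch,
      in_sgrna_region = FALSE
    )
  }

  muts <- dplyr::bind_rows(
    place_snvs(config$n_truncal_mutations, "truncal"),
    if (config$topology == "nested") {
      dplyr::bind_rows(
        place_snvs(config$n_clade_mutations, "clade_1"),
        place_snvs(config$n_clade_mutations, "clade_2")
      )
    },
    purrr::map_dfr(mouse_samples$sample, function(s) {
      snvs <- place_snvs(config$n_private_mutations_per_sample, s)
      n_ind <- config$n_indels_per_sample
      if (n_ind > 0) {
        i <- sample.int(nrow(arms), n_ind, replace = TRUE, prob = arms$length)
        tandem <- stats::runif(n_ind) < config$indel_tandem_fraction
        down <- character(n_ind)
        down[tandem] <- tandem_dna20(sum(tandem))
        down[!tandem] <- random_dna(sum(!tandem), 20)
        ins <- stats::runif(n_ind) < 0.5
        anchor <- random_dna(n_ind, 1)
        extra <- random_dna(n_ind, 2)
        snvs <- dplyr::bind_rows(snvs, tibble(
          chrom = arms$chrom[i],
          pos = floor(stats::runif(n_ind, arms$start[i] + 1, arms$end[i])),
          ref = ifelse(ins, anchor, paste0(anchor, extra)),
          alt = ifelse(ins, paste0(anchor, extra), anchor),
          variant_class = ifelse(ins, "insertion", "deletion"),
          trinuc_context = NA_character_,
          downstream_20nt = down,
          branch = s,
          in_sgrna_region = FALSE
        ))
      }
      snvs
    }),
    # truncal driver indels at each sgRNA cut site
    {
      n_g <- nrow(sgrna_targets)
      tibble(
        chrom = sgrna_targets$chrom,
        pos = sgrna_targets$cut_pos,
        ref = random_dna(n_g, 4),
        alt = substr(random_dna(n_g, 1), 1, 1),
        variant_class = "deletion",
        trinuc_context = NA_character_,
        downstream_20nt = random_dna(n_g, 20),
        branch = "truncal",
        in_sgrna_region = TRUE
      )
    }
  )
  muts$mouse <- m
  muts$exonic <- TRUE

  carried <- function(branch, s, clade) {
    branch == "truncal" | branch == s | (!is.na(clade) & branch == clade)
  }

  variants <- purrr::map_dfr(seq_len(nrow(mouse_samples)), function(i) {
    s <- mouse_samples$sample[i]
    clade <- mouse_samples$clade[i]
    present <- carried(muts$branch, s, clade)
    cn <- unname(cn_of_arm[arm_of_chrom[muts$chrom]])
    vaf <- ifelse(present, expected_vaf(p, cn, 1), 0)
    counts <- draw_counts(nrow(muts), vaf, config$mean_depth, config$background_error)
    dplyr::bind_cols(
      tibble(
        mouse = m, sample = s, site_class = mouse_samples$site_class[i]
      ),
      muts[, c(
        "chrom", "pos", "ref", "alt", "variant_class", "trinuc_context",
        "downstream_20nt", "exonic", "branch", "in_sgrna_region"
      )],
      counts
    )
  })

  pileups <- purrr::map_dfr(mouse_samples$sample, function(s) {
    purrr::map_dfr(sgrna_targets$gene, function(g) {
      simulate_cutsite_pileup(
        config$editing_rate, config$mean_depth,
        window_halfwidth = config$window_halfwidth,
        background_error = config$background_error,
        gene = g, sample = s
      )
    })
  })

  # per-exon log2 read-depth ratios; expected value log2((p*C + 2(1-p))/2)
  exon_arm <- arm_of_chrom[targets$chrom]
  exon_mu <- unname(log2((p * cn_of_arm[exon_arm] + 2 * (1 - p)) / 2))
  seg <- purrr::map_dfr(mouse_samples$sample, function(s) {
    tibble(
      mouse = m, sample = s,
      chrom = targets$chrom, start = targets$start, end = targets$end,
      weight = stats::runif(nrow(targets), 0.5, 1.5),
      log2 = exon_mu + rnorm(nrow(targets), 0, config$noise_sd_log2)
    )
  })

  # germline het SNPs shared across the mouse's samples
  snp_i <- rep(seq_len(nrow(arms)), each = config$n_snps_per_arm)
  snp_pos <- floor(stats::runif(length(snp_i), arms$start[snp_i] + 1, arms$end[snp_i]))
  b_of_arm <- setNames(truth$b_copies, truth$arm)
  exp_baf <- unname(((1 - p) + p * b_of_arm[arms$arm[snp_i]]) /
    (2 * (1 - p) + p * cn_of_arm[arms$arm[snp_i]]))
  baf <- purrr::map_dfr(mouse_samples$sample, function(s) {
    d_n <- pmax(1L, rpois(length(snp_i), config$mean_depth))
    d_t <- pmax(1L, rpois(length(snp_i), config$mean_depth))
    a_n <- rbinom(length(snp_i), d_n, 0.5)
    a_t <- rbinom(length(snp_i), d_t, exp_baf)
    tibble(
      mouse = m, sample = s,
      chrom = arms$chrom[snp_i], pos = snp_pos,
      normal_ref = d_n - a_n, normal_alt = a_n,
      tumor_ref = d_t - a_t, tumor_alt = a_t,
      baf_normal = a_n / d_n, baf_tumor = a_t / d_t
    )
  })

  true_ploidy <- if (config$wgd) 4 else 2
  grid_cells <- seq(0.1, 1, by = 0.05)
  grid_ploidy <- seq(1, 6, by = 0.5)
  grids <- purrr::map_dfr(mouse_samples$sample, function(s) {
    g <- tidyr::expand_grid(cellularity = grid_cells, ploidy = grid_ploidy)
    prob <- dnorm(g$cellularity - p, sd = 0.08) *
      dnorm(g$ploidy - true_ploidy, sd = 0.4)
    prob <- prob / sum(prob) + stats::runif(nrow(g), 0, 1e-6)
    tibble(
      mouse = m, sample = s,
      cellularity = g$cellularity, ploidy = g$ploidy, probability = prob
    )
  })

  list(
    variants = variants, pileups = pileups, seg = seg, baf = baf,
    grids = grids, arm_states = truth
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf(
    "  %d mice, %d tumor samples; %d variant rows, %d pileup rows, %d exon ratios\n",
    x$config$n_mice, nrow(x$samples), nrow(x$variants), nrow(x$pileups),
    nrow(x$seg)
  ))
  cat(sprintf(
    "  truth: ploidy %g, WGD %s, arm events: %s\n",
    x$truth$ploidy, x$truth$wgd,
    if (length(x$config$arm_events)) {
      paste(names(x$config$arm_events), x$config$arm_events, collapse = ", ")
    } else "none"
  ))
  invisible(x)
}
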