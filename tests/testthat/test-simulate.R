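test_that("bundle dimensions are forced by the configuration", {
  cfg <- cohort_config(n_mice = 3, samples_per_mouse = 2, seed = 7)
  b <- simulate_cohort(cfg)
  expect_s3_class(b, "cohort_bundle")
  expect_equal(nrow(b$samples), 6)
  expect_equal(length(unique(b$samples$mouse)), 3)
  expect_setequal(unique(b$pileups$gene), cfg$targeted_genes)
  # 51-position windows, tumor + normal, per sample and gene
  expect_equal(
    nrow(b$pileups),
    6 * length(cfg$targeted_genes) * 2 * (2 * cfg$window_halfwidth + 1)
  )
  expect_equal(
    nrow(b$seg),
    6 * cfg$n_exons_per_arm * nrow(arm_table("mm10"))
  )
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_mice = 2, samples_per_mouse = 2, seed = 11)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$pileups, b2$pileups)
  expect_identical(b1$seg, b2$seg)
  expect_identical(b1$baf, b2$baf)
  expect_identical(b1$grids, b2$grids)
  b3 <- simulate_cohort(cohort_config(n_mice = 2, samples_per_mouse = 2, seed = 12))
  expect_false(identical(b1$variants, b3$variants))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(purity = 0), "purity", class = "mosaicevo_config_error")
  expect_error(cohort_config(purity = 1.2), "purity", class = "mosaicevo_config_error")
  expect_error(cohort_config(n_mice = -1), "n_mice", class = "mosaicevo_config_error")
  expect_error(cohort_config(mean_depth = 0), "mean_depth", class = "mosaicevo_config_error")
  expect_error(
    cohort_config(signature_mix = c("A[C>T]G" = 0.5)),
    "signature_mix",
    class = "mosaicevo_config_error"
  )
  expect_error(
    cohort_config(arm_events = c(chr99q = "gain")),
    "arm_events",
    class = "mosaicevo_config_error"
  )
})

test_that("clone-tree invariants hold: truncal in all samples, private in one", {
  b <- simulate_cohort(cohort_config(
    n_mice = 3, samples_per_mouse = 3,
    n_truncal_mutations = 20, n_private_mutations_per_sample = 10,
    seed = 3
  ))
  present <- b$variants[b$variants$tumor_alt >= 2, ]
  per_mut <- dplyr::count(
    present, .data$mouse, .data$chrom, .data$pos, .data$ref, .data$alt,
    .data$branch
  )
  truncal <- per_mut[per_mut$branch == "truncal", ]
  private <- per_mut[grepl("_s\\d+$", per_mut$branch), ]
  expect_true(all(truncal$n == 3))
  expect_true(all(private$n == 1))
})

test_that("simulated VAFs follow the purity/copy-number expectation on a grid", {
  arms <- arm_table("mm10")
  all_loss <- stats::setNames(rep("loss", nrow(arms)), arms$arm)
  # the bound is the normal quantile for a family error rate of 0.001 over
  # the 9 grid cells (a raw 3*SE per cell would false-alarm in ~2% of runs)
  z_star <- stats::qnorm(1 - 0.001 / (2 * 9))
  for (p in c(0.3, 0.6, 1.0)) {
    for (C in c(1, 2, 4)) {
      cfg <- cohort_config(
        n_mice = 3, samples_per_mouse = 2,
        n_truncal_mutations = 100, n_private_mutations_per_sample = 0,
        n_indels_per_sample = 0,
        purity = p, mean_depth = 100,
        arm_events = if (C == 1) all_loss else character(0),
        wgd = (C == 4),
        seed = 1000 + round(100 * p) + C
      )
      b <- simulate_cohort(cfg)
      v <- b$variants[b$variants$branch == "truncal" & !b$variants$in_sgrna_region, ]
      vaf <- v$tumor_alt / v$tumor_depth
      se <- stats::sd(vaf) / sqrt(length(vaf))
      expect_lt(
        abs(mean(vaf) - expected_vaf(p, C, 1)), z_star * se + 1e-6
      )
    }
  }
})

test_that("exon log2 ratios center on log2(C/2) adjusted for purity", {
  p <- 0.6
  b <- simulate_cohort(cohort_config(
    n_mice = 1, samples_per_mouse = 2, purity = p,
    noise_sd_log2 = 0.1, seed = 5
  ))
  arms <- arm_table("mm10")
  arm_of <- setNames(arms$arm, arms$chrom)
  seg <- b$seg
  seg$arm <- arm_of[seg$chrom]
  for (spec in list(
    list(arm = "chr5q", C = 3), list(arm = "chr12q", C = 1),
    list(arm = "chr1q", C = 2)
  )) {
    lr <- seg$log2[seg$arm == spec$arm]
    expected <- log2((p * spec$C + 2 * (1 - p)) / 2)
    expect_lt(abs(mean(lr) - expected), 3 * 0.1 / sqrt(length(lr)))
  }
})

test_that("cut-site pileups expose editing only near the cut site", {
  pu <- simulate_cutsite_pileup(0.5, 200, window_halfwidth = 25, seed = 2)
  expect_equal(sort(unique(pu$position_offset)), -25:25)
  expect_equal(nrow(pu), 2 * 51)
  center <- pu[pu$compartment == "tumor" & pu$position_offset == 0, ]
  frac <- center$alt_count / (center$alt_count + center$ref_count)
  se <- sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(frac - 0.5), 3 * se)

  # null case: tumor and normal alteration rates differ only by noise
  null <- simulate_cutsite_pileup(0, 500, seed = 3)
  rates <- tapply(
    null$alt_count / (null$alt_count + null$ref_count),
    null$compartment, mean
  )
  expect_lt(abs(rates["tumor"] - rates["normal"]), 0.005)
  expect_error(simulate_cutsite_pileup(0.5, -10), "depth")
})

test_that("trinucleotide draws follow the signature mixture", {
  one <- simulate_trinuc_mutations(c("A[C>T]G" = 1), 100, seed = 1)
  expect_equal(nrow(one), 100)
  expect_true(all(one$class == "A[C>T]G"))
  # observed strand may flip, but normalization must restore the class
  expect_equal(
    unique(pyrimidine_class(one$ref, one$alt, one$trinuc_context)), "A[C>T]G"
  )

  empty <- simulate_trinuc_mutations(c("A[C>T]G" = 1), 0)
  expect_equal(nrow(empty), 0)

  uniform <- setNames(
    rep(1 / 96, 96), trinuc_classes()
  )
  draws <- simulate_trinuc_mutations(uniform, 96000, seed = 4)
  counts <- table(factor(draws$class, levels = trinuc_classes()))
  tol <- 3 * sqrt(1000 * (1 - 1 / 96))
  expect_true(all(abs(counts - 1000) <= tol))

  expect_error(
    simulate_trinuc_mutations(c("A[C>T]G" = 0.5), 10),
    "sum to 1"
  )
})
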