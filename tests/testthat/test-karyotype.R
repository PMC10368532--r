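test_that("focal calls require every exon to clear the threshold coherently", {
  expect_equal(focal_call(data.frame(log2 = c(-0.5, -0.6, -0.45))), "deletion")
  expect_equal(focal_call(data.frame(log2 = c(-0.5, -0.2, -0.6))), "neutral")
  expect_equal(focal_call(data.frame(log2 = c(0.5, -0.5))), "neutral")
  expect_equal(focal_call(c(0.4, 0.7)), "amplification") # inclusive
  expect_error(focal_call(numeric(0)), "no exons")
  expect_error(focal_call(c(1, 2), threshold = 0), "threshold")

  # invariant to exon ordering and uniform weight rescaling
  ex <- data.frame(log2 = c(-0.5, -0.6, -0.45), weight = c(1, 2, 3))
  expect_equal(focal_call(ex[3:1, ]), focal_call(ex))
  ex$weight <- ex$weight * 10
  expect_equal(focal_call(ex), "deletion")
})

make_arm_exons <- function(arms, log2_by_arm, n = 10) {
  purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    s <- round(seq(arms$start[i] + 100, arms$end[i] - 300, length.out = n))
    tibble::tibble(
      chrom = arms$chrom[i], start = s, end = s + 200,
      weight = 1, log2 = log2_by_arm[arms$arm[i]]
    )
  })
}

test_that("arm calls use the weighted mean at an inclusive 0.2 threshold", {
  arms <- arm_table("mm10")
  lr <- setNames(rep(0, nrow(arms)), arms$arm)
  lr["chr12q"] <- -0.58 # single-copy loss at purity 1
  lr["chr5q"] <- 0.2 # exact boundary
  ex <- make_arm_exons(arms, lr)
  calls <- arm_calls(ex, arms)
  expect_equal(calls$call[calls$arm == "chr12q"], "loss")
  expect_equal(calls$call[calls$arm == "chr5q"], "gain")
  expect_equal(calls$call[calls$arm == "chr1q"], "neutral")

  # weights matter: one heavy extreme exon can flip the mean
  ex2 <- ex[ex$chrom == "chr1", ]
  ex2$log2 <- c(2, rep(0, 9))
  ex2$weight <- c(10, rep(0.1, 9))
  one_arm <- arm_calls(ex2, arms)
  expect_equal(one_arm$call[one_arm$arm == "chr1q"], "gain")
  # arms with no exons are no-calls
  expect_true(all(one_arm$call[one_arm$arm != "chr1q"] == "no-call"))

  bad_arms <- arms
  bad_arms$start[2] <- 0
  bad_arms$chrom[2] <- bad_arms$chrom[1]
  expect_error(arm_calls(ex, bad_arms), "overlap")
})

test_that("aneuploidy score counts altered arms and fCNA weights by length", {
  arms <- tibble::tibble(
    arm = c("a1", "a2", "a3"), chrom = c("c1", "c2", "c3"),
    start = 0, end = c(100, 50, 850), length = c(100, 50, 850)
  )
  calls <- tibble::tibble(
    arm = arms$arm, n_exons = 5, mean_log2 = c(0.5, -0.5, 0),
    call = c("gain", "loss", "neutral")
  )
  res <- aneuploidy_and_fcna(calls, arms)
  expect_equal(res$aneuploidy_score, 2L)
  expect_equal(res$fcna, 0.15)
  expect_equal(
    aneuploidy_and_fcna(calls, arms, mode = "count")$fcna, 2 / 3
  )
  none <- calls
  none$call <- "neutral"
  expect_equal(aneuploidy_and_fcna(none, arms)$fcna, 0)
  all_alt <- calls
  all_alt$call <- "gain"
  expect_equal(aneuploidy_and_fcna(all_alt, arms)$fcna, 1)
  expect_equal(aneuploidy_and_fcna(all_alt, arms)$aneuploidy_score, 3L)
})

test_that("ploidy selection restricts to nearest cellularity, ties go low", {
  grid <- tibble::tibble(
    cellularity = c(0.6, 0.6, 0.9, 0.9),
    ploidy = c(2, 4, 2, 4),
    probability = c(0.1, 0.8, 0.9, 0.05)
  )
  expect_equal(select_ploidy(grid, 0.6), 4)
  expect_equal(select_ploidy(grid, 0.95), 2)
  expect_equal(select_ploidy(grid[1, ], 0.3), 2)
  tie <- tibble::tibble(
    cellularity = 0.5, ploidy = c(4, 2), probability = 0.5
  )
  expect_equal(select_ploidy(tie, 0.5), 2)
  expect_error(select_ploidy(grid[0, ], 0.5), "empty")
})

test_that("WGD is called from ploidy at an inclusive cutoff of 3", {
  expect_true(call_wgd(4))
  expect_false(call_wgd(2))
  expect_true(call_wgd(3))
  expect_false(call_wgd(2.9))
  expect_error(call_wgd(0), "ploidy")
})

test_that("heterozygous SNP selection enforces strict BAF bounds and coverage", {
  rec <- tibble::tibble(
    normal_ref = c(10, 18, 7, 8, 4),
    normal_alt = c(10, 2, 7, 2, 10)
  )
  kept <- select_het_snps(rec)
  # row1: BAF 0.5 cov 20; row2: BAF 0.1; row3: cov 14; row4: cov 10 and
  # BAF 0.2 exact; row5: BAF 0.714 cov 14
  expect_equal(nrow(kept), 1)
  expect_equal(kept$baf_normal, 0.5)
  # relaxing coverage admits rows 3 and 5, but never the boundary BAFs
  expect_equal(nrow(select_het_snps(rec, min_coverage = 14)), 3)
  expect_equal(nrow(select_het_snps(rec, min_coverage = 10)), 3)
})

test_that("allelic imbalance is the mean mirrored BAF deviation", {
  expect_equal(allelic_imbalance(data.frame(baf_tumor = c(0.5, 0.5))), 0)
  expect_equal(allelic_imbalance(data.frame(baf_tumor = c(0.2, 0.8))), 0.3)
  expect_equal(
    allelic_imbalance(data.frame(tumor_ref = c(8, 2), tumor_alt = c(2, 8))),
    0.3
  )
  expect_warning(out <- allelic_imbalance(data.frame(baf_tumor = numeric(0))), "empty")
  expect_true(is.na(out))
})

test_that("a simulated one-copy loss at purity 1 drives BAF to the extremes", {
  b <- simulate_cohort(cohort_config(
    n_mice = 1, samples_per_mouse = 1, purity = 1,
    arm_events = c(chr12q = "loss"), n_snps_per_arm = 60, seed = 8
  ))
  het <- select_het_snps(b$baf)
  dev <- allelic_imbalance(het[het$chrom == "chr12", ])
  expect_equal(dev, 0.5, tolerance = 1e-6)
  balanced <- allelic_imbalance(het[het$chrom == "chr1", ])
  expect_lt(balanced, 0.1)
})

test_that("karyotype_profile recovers simulated arm events, fCNA and WGD", {
  arms <- arm_table("mm10")
  b <- simulate_cohort(cohort_config(
    n_mice = 1, samples_per_mouse = 1, purity = 0.6,
    noise_sd_log2 = 0.1, wgd = TRUE, seed = 13
  ))
  kp <- karyotype_profile(
    b$seg, arms,
    grid = b$grids, purity = 0.6, baf = b$baf
  )
  expect_equal(
    kp$arms$call[match(c("chr5q", "chr12q", "chr16q"), kp$arms$arm)],
    c("gain", "loss", "loss")
  )
  expect_equal(glance(kp)$ploidy, 4)
  expect_true(glance(kp)$wgd)
  true_fcna <- sum(arms$length[arms$arm %in% c("chr5q", "chr12q", "chr16q")]) /
    sum(arms$length)
  expect_lt(abs(glance(kp)$fcna - true_fcna), 0.05)
  expect_identical(tidy(kp), kp$arms)
  # loss arms show allelic imbalance exceeding neutral arms
  expect_gt(
    kp$arms$baf_deviation[kp$arms$arm == "chr12q"],
    kp$arms$baf_deviation[kp$arms$arm == "chr1q"]
  )
})
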