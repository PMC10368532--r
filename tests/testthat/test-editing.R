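test_that("position log odds matches direct 2x2 arithmetic", {
  expect_equal(position_log_odds(70, 30, 98, 2), log(21), tolerance = 1e-12)
  expect_equal(position_log_odds(50, 50, 50, 50), 0)
  # symmetric zero cells cancel under the Haldane-Anscombe correction
  expect_equal(position_log_odds(100, 0, 100, 0), 0)
  expect_error(position_log_odds(0, 0, 0, 0), "undefined")
  expect_error(position_log_odds(-1, 2, 3, 4), "non-negative")

  withr::with_seed(42, {
    for (i in 1:300) {
      tab <- stats::rpois(4, 20)
      if (sum(tab) == 0) next
      expect_equal(
        position_log_odds(tab[1], tab[2], tab[3], tab[4]),
        oracle_log_odds(tab[1], tab[2], tab[3], tab[4])
      )
    }
  })
})

test_that("gene z-transform centers and scales by the population sd", {
  x <- c(0, 0, 0, 4)
  expect_equal(gene_z_scores(x), (x - 1) / sqrt(3))
  expect_equal(gene_z_scores(c(-1, 1)), c(-1, 1))
  expect_equal(gene_z_scores(rep(2.5, 10)), rep(0, 10))
  expect_error(gene_z_scores(1), "2 window positions")

  withr::with_seed(9, {
    for (i in 1:20) {
      z <- gene_z_scores(stats::rnorm(25))
      expect_equal(mean(z), 0, tolerance = 1e-9)
      expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
    }
  })
})

test_that("sample score is the mean over genes of central-window mean z", {
  one <- tibble::tibble(
    gene = "g1", position_offset = c(-1, 0, 1), z = c(1, 2, 3)
  )
  expect_equal(sample_editing_score(one), 2)
  two <- dplyr::bind_rows(
    tibble::tibble(gene = "g1", position_offset = c(-1, 0, 1), z = 1),
    tibble::tibble(gene = "g2", position_offset = c(-1, 0, 1), z = 3)
  )
  expect_equal(sample_editing_score(two), 2)
  # off-center positions are excluded
  off <- dplyr::bind_rows(one, tibble::tibble(
    gene = "g1", position_offset = c(-10, 10), z = c(100, 100)
  ))
  expect_equal(sample_editing_score(off), 2)
  expect_error(sample_editing_score(one[0, ]), "non-empty")
})

test_that("score_editing pairs compartments and stores Fisher p-values", {
  pu <- dplyr::bind_rows(
    simulate_cutsite_pileup(0.6, 100, gene = "g1", seed = 1),
    simulate_cutsite_pileup(0.6, 100, gene = "g2", seed = 2)
  )
  es <- score_editing(pu)
  expect_s3_class(es, "editing_score")
  expect_true(all(es$positions$p_value >= 0 & es$positions$p_value <= 1))
  expect_equal(nrow(es$samples), 1)
  # per-gene z normalization holds inside the result
  per_gene <- split(es$positions$z, es$positions$gene)
  for (z in per_gene) {
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  }
  # tidy/glance accessors
  expect_identical(tidy(es), es$positions)
  expect_equal(glance(es)$n_samples, 1)
  expect_error(
    score_editing(pu[pu$compartment == "tumor", ]),
    "pair a tumor and a normal"
  )
})

test_that("sample score increases with simulated editing rate", {
  rates <- c(0, 0.1, 0.25, 0.5, 0.9)
  means <- vapply(seq_along(rates), function(i) {
    scores <- vapply(1:20, function(r) {
      pu <- simulate_cutsite_pileup(rates[i], 100, seed = 7000 + 100 * i + r)
      score_editing(pu, fisher_p = FALSE)$samples$score
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("gene-altered calls combine read-pattern and coverage evidence", {
  hit <- call_gene_altered(rep("del5", 3), 100, 100)
  expect_true(hit$altered)
  expect_equal(hit$evidence, "pattern_reads")
  expect_equal(hit$supporting_read_count, 3L)

  drop <- call_gene_altered(character(0), 40, 100)
  expect_true(drop$altered)
  expect_equal(drop$evidence, "coverage_drop")

  neither <- call_gene_altered("ins1", 90, 100)
  expect_false(neither$altered)
  expect_equal(neither$evidence, "none")

  # two different patterns with one read each do not qualify
  mixed <- call_gene_altered(c("del5", "ins2"), 90, 100)
  expect_false(mixed$altered)

  # strict mode requires both clauses
  both_needed <- call_gene_altered(rep("del5", 3), 90, 100, mode = "and")
  expect_false(both_needed$altered)
  expect_true(
    call_gene_altered(rep("del5", 3), 40, 100, mode = "and")$altered
  )
  expect_error(call_gene_altered("x", 10, 0), "control_median_coverage")
})
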