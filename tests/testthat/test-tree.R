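test_that("pair distance is 1 minus the shared fraction over the union", {
  expect_equal(pair_distance(c("m1", "m2", "m3"), c("m2", "m3", "m4")), 0.5)
  expect_equal(pair_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(pair_distance(c("a"), c("b")), 1)
  both <- pair_distance(character(0), character(0))
  expect_equal(as.numeric(both), 0)
  expect_true(attr(both, "both_empty"))
})

test_that("pair distance is a metric on random triples", {
  withr::with_seed(5, {
    universe <- sprintf("k%03d", 1:40)
    for (i in 1:200) {
      a <- sample(universe, sample(1:20, 1))
      b <- sample(universe, sample(1:20, 1))
      c <- sample(universe, sample(1:20, 1))
      dab <- pair_distance(a, b)
      dba <- pair_distance(b, a)
      dac <- pair_distance(a, c)
      dcb <- pair_distance(c, b)
      expect_identical(as.numeric(dab), as.numeric(dba))
      expect_lte(dab, dac + dcb + 1e-12)
      expect_equal(pair_distance(a, a), 0)
    }
  })
})

test_that("complete linkage merges follow the worked example", {
  m <- matrix(
    c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3,
    dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
  )
  tr <- build_tree(stats::as.dist(m))
  expect_equal(length(tr$merges), 2)
  expect_equal(tr$merges[[1]]$height, 0.1)
  expect_equal(tr$merges[[1]]$members, c("s1", "s2"))
  expect_equal(tr$merges[[2]]$height, 0.9)

  # two identical samples merge at height 0
  sets <- list(a = c("m1", "m2"), b = c("m1", "m2"))
  tr0 <- build_tree(sets)
  expect_equal(tr0$root$height, 0)

  # pairwise equidistant points: caterpillar by the lexicographic tie rule
  n <- 4
  eq <- matrix(0.6, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  diag(eq) <- 0
  treq <- build_tree(stats::as.dist(eq))
  expect_equal(treq$merges[[1]]$members, c("s1", "s2"))
  expect_equal(treq$merges[[2]]$members, c("s1", "s2", "s3"))
  expect_true(all(vapply(treq$merges, `[[`, numeric(1), "height") == 0.6))
  # ... and collapsing the zero-length internal edges leaves one polytomy
  poly <- collapse_zero_branches(treq)
  expect_equal(length(poly$root$children), n)
})

test_that("build_tree agrees with the naive complete-linkage oracle", {
  withr::with_seed(14, {
    for (i in 1:60) {
      n <- sample(2:8, 1)
      m <- random_distance_matrix(n)
      got <- build_tree(stats::as.dist(m))$merges
      want <- oracle_complete_linkage(m)
      expect_equal(merge_signature(got), merge_signature(want))
    }
    # invariance under leaf relabeling/permutation of the input order
    for (i in 1:10) {
      m <- random_distance_matrix(4)
      ref <- merge_signature(build_tree(stats::as.dist(m))$merges)
      perms <- list(
        c(1, 2, 4, 3), c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2)
      )
      for (p in perms) {
        mp <- m[p, p]
        expect_equal(
          merge_signature(build_tree(stats::as.dist(mp))$merges), ref
        )
      }
    }
  })
})

test_that("tree construction refuses mixed-mouse variant tables", {
  v <- tibble::tibble(
    mouse = c("m1", "m2"), sample = c("s1", "s2"),
    chrom = "chr1", pos = 1:2, ref = "C", alt = "T", tumor_alt = 10
  )
  expect_error(build_tree(v), "multiple mice")
})

test_that("zero-length branch collapse contracts equal-height merges only", {
  m <- matrix(
    c(
      0, 0.2, 0.2, 0.9,
      0.2, 0, 0.2, 0.9,
      0.2, 0.2, 0, 0.9,
      0.9, 0.9, 0.9, 0
    ), 4,
    dimnames = list(paste0("s", 1:4), paste0("s", 1:4))
  )
  tr <- collapse_zero_branches(build_tree(stats::as.dist(m)))
  # s1..s3 form one trichotomy at 0.2, s4 joins at 0.9
  expect_equal(length(tr$root$children), 2)
  sizes <- sort(vapply(tr$root$children, function(n) length(n$members), integer(1)))
  expect_equal(sizes, c(1L, 3L))
  tri <- Filter(function(n) length(n$members) == 3, tr$root$children)[[1]]
  expect_equal(length(tri$children), 3)

  # strictly increasing heights: the tree is unchanged
  m2 <- matrix(
    c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3,
    dimnames = list(paste0("s", 1:3), paste0("s", 1:3))
  )
  t2 <- build_tree(stats::as.dist(m2))
  expect_identical(collapse_zero_branches(t2)$root, t2$root)
})

test_that("branch assignment separates truncal, shared, private and conflicts", {
  sets <- list(
    S1 = c("t1", "t2", "a", "p1", "x"),
    S2 = c("t1", "t2", "a", "p2"),
    S3 = c("t1", "t2", "p3", "x")
  )
  tr <- build_tree(sets)
  # S1,S2 share more and merge first
  expect_equal(tr$merges[[1]]$members, c("S1", "S2"))
  asg <- assign_branches(tr, sets)
  cat_of <- setNames(asg$category, asg$key)
  expect_equal(unname(cat_of[c("t1", "t2")]), rep("truncal", 2))
  expect_equal(unname(cat_of["a"]), "shared")
  expect_equal(unname(cat_of[c("p1", "p2", "p3")]), rep("private", 3))
  # x is carried by {S1, S3}, which is not a clade: assigned to the largest
  # contained clade (a single leaf) and flagged
  expect_equal(unname(cat_of["x"]), "private")
  expect_true(asg$clade_conflict[asg$key == "x"])
  expect_false(any(asg$clade_conflict[asg$key != "x"]))
  # conservation: every mutation assigned exactly once
  expect_equal(sort(asg$key), sort(unique(unlist(sets))))
})

test_that("site-class fractions pool per-sample occurrences and sum to 1", {
  sets <- list(
    S1 = c(paste0("t", 1:5), paste0("p1_", 1:5)),
    S2 = c(paste0("t", 1:5), paste0("p2_", 1:5))
  )
  info <- tibble::tibble(
    sample = c("S1", "S2"), site_class = c("primary", "metastasis")
  )
  tr <- build_tree(sets)
  asg <- assign_branches(tr, sets)
  fr <- truncal_private_fractions(asg, sets, info)
  expect_equal(
    fr$fraction[fr$site_class == "primary" & fr$category == "truncal"], 0.5
  )
  expect_equal(
    fr$fraction[fr$site_class == "metastasis" & fr$category == "private"], 0.5
  )
  sums <- tapply(fr$fraction, fr$site_class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  all_truncal <- list(S1 = c("t1", "t2"), S2 = c("t1", "t2"))
  tr2 <- build_tree(all_truncal)
  fr2 <- truncal_private_fractions(
    assign_branches(tr2, all_truncal), all_truncal, info
  )
  expect_true(all(fr2$fraction == 1))
  expect_true(all(fr2$category == "truncal"))
})

test_that("nested clade structure is recovered from simulated cohorts", {
  hits <- 0
  for (r in 1:5) {
    b <- simulate_cohort(cohort_config(
      n_mice = 1, samples_per_mouse = 4, topology = "nested",
      n_truncal_mutations = 10, n_clade_mutations = 8,
      n_private_mutations_per_sample = 10, seed = 500 + r
    ))
    v <- exclude_sgrna_regions(b$variants, b$sgrna_targets)
    tr <- collapse_zero_branches(build_tree(v))
    want <- lapply(
      split(b$truth$clades$sample, b$truth$clades$clade), sort
    )
    got <- lapply(tr$root$children, `[[`, "members")
    ok <- length(got) == 2 &&
      any(vapply(got, identical, logical(1), want[[1]])) &&
      any(vapply(got, identical, logical(1), want[[2]]))
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})
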