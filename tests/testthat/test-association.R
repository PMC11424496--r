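test_that("wilcoxon gate is calibrated under the null and powered under shift", {
  withr::with_seed(61, {
    null_p <- vapply(1:500, function(i) {
      vals <- 2^rnorm(100, log2(10), 1)
      mask <- random_mask(100, 20)
      wilcoxon_de(vals, mask)$p_value
    }, numeric(1))
  })
  # null rejection rate near nominal alpha, within Monte-Carlo error
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(mean(null_p <= 0.05), 0.05 + 2.5 * se)
  expect_gt(mean(null_p <= 0.05), 0.05 - 4 * se)

  withr::with_seed(62, {
    vals <- 2^rnorm(100, log2(10), 1)
    mask <- random_mask(100, 20)
    vals[mask == 1] <- vals[mask == 1] + 10
    expect_lt(wilcoxon_de(vals, mask)$p_value, 0.05)
  })
})

test_that("wilcoxon gate refuses degenerate groupings", {
  vals <- 2^rnorm(20, log2(10), 1)
  all_mut <- wilcoxon_de(vals, rep(1, 20))
  expect_false(all_mut$testable)
  expect_match(all_mut$reason, "minimum")
  expect_false(wilcoxon_de(vals, c(1, rep(0, 19)))$testable)
})

test_that("fold changes are reported raw and log2 with pseudocount", {
  vals <- c(rep(4, 5), rep(1, 15))
  de <- wilcoxon_de(vals, c(rep(1, 5), rep(0, 15)))
  expect_equal(de$fold_change, 4)
  expect_equal(de$log2_fc, log2(5 / 2))
  expect_equal(de$n_mut, 5)
  expect_equal(de$n_wt, 15)
})

test_that("disjoint masks give permutation p of exactly 1 under pseudocount", {
  mut <- c(rep(1, 5), rep(0, 15))
  dys <- c(rep(0, 15), rep(1, 5))
  pt <- overlap_permutation_test(mut, dys, n_perm = 200, seed = 3)
  expect_equal(pt$n_obser, 0L)
  expect_equal(pt$p_perm, 1)
})

test_that("strict-inequality mode reproduces the printed formula and warns at 0", {
  mut <- c(rep(1, 5), rep(0, 15))
  dys <- c(rep(0, 15), rep(1, 5))
  expect_warning(
    pt <- overlap_permutation_test(mut, dys, n_perm = 200, seed = 3,
                                   p_mode = "as_printed"),
    "strict")
  expect_equal(pt$p_perm, pt$n_gt / pt$n_perm)
})

test_that("nested masks reach the hypergeometric tail floor", {
  withr::with_seed(12, {
    dys <- random_mask(100, 10)
    mut <- dys  # carriers identical to the dysregulated set, n_obser = 10
  })
  pt <- overlap_permutation_test(mut, dys, n_perm = 1000, seed = 5)
  p_exact <- phyper(9, 10, 90, 10, lower.tail = FALSE)
  # the exact tail is ~6e-14; the estimate must sit within Monte-Carlo noise
  se <- sqrt(pt$p_perm * (1 - pt$p_perm) / pt$n_perm)
  expect_lte(abs(pt$p_perm - p_exact), 3 * se + 1 / (pt$n_perm + 1))
  expect_equal(pt$n_ge, 0L)
})

test_that("permutation test is deterministic under a fixed seed", {
  withr::with_seed(9, {
    mut <- random_mask(80, 12); dys <- random_mask(80, 15)
  })
  a <- overlap_permutation_test(mut, dys, n_perm = 300, seed = 11)
  b <- overlap_permutation_test(mut, dys, n_perm = 300, seed = 11)
  expect_identical(a, b)
})

test_that("observed overlap never exceeds either margin", {
  withr::with_seed(41, {
    for (i in 1:30) {
      n <- sample(20:120, 1)
      mut <- random_mask(n, sample.int(n - 1, 1))
      dys <- random_mask(n, sample.int(n - 1, 1))
      pt <- overlap_permutation_test(mut, dys, n_perm = 100, seed = i)
      expect_lte(pt$n_obser, min(pt$n_mut, pt$n_dys))
      expect_gte(pt$p_perm, 0)
      expect_lte(pt$p_perm, 1)
    }
  })
})

test_that("null permutation p-values are approximately uniform", {
  withr::with_seed(99, {
    ps <- vapply(1:500, function(i) {
      n <- 200
      mut <- random_mask(n, sample(50:150, 1))
      dys <- random_mask(n, sample(50:150, 1))
      overlap_permutation_test(mut, dys, n_perm = 400, seed = i)$p_perm
    }, numeric(1))
  })
  ks <- max(abs(sort(ps) - ppoints(500, a = 0)))
  expect_lt(ks, 0.1)
})

test_that("the screen selects a planted causal ER and is reproducible", {
  suppressMessages({
    sim <- simulate_cohort(simulation_config(n_pairs = 4, n_er_genes = 8,
                                             seed = 7))
    prof <- detect_dysregulation(sim$expression, sim$pairs)
    tab1 <- run_association(sim$expression, sim$mutation, prof, sim$er_genes,
                            seed = 7)
    tab2 <- run_association(sim$expression, sim$mutation, prof, sim$er_genes,
                            seed = 7)
  })
  causal <- sim$truth$causal
  hit <- tab1[tab1$er_gene == causal$er_gene & tab1$ligand == causal$ligand, ]
  expect_true(hit$de_pass)
  expect_true(hit$selected)
  expect_identical(tab1, tab2)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_association_table(tab1, f1)
  write_association_table(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("association output is identical across worker counts", {
  suppressMessages({
    sim <- simulate_cohort(simulation_config(n_samples = 80, n_pairs = 3,
                                             n_er_genes = 5, seed = 19))
    prof <- detect_dysregulation(sim$expression, sim$pairs)
    serial <- run_association(sim$expression, sim$mutation, prof,
                              sim$er_genes, seed = 19, workers = 1)
    forked <- run_association(sim$expression, sim$mutation, prof,
                              sim$er_genes, seed = 19, workers = 4)
  })
  expect_identical(serial, forked)
})

test_that("ERs below the carrier minimum are excluded from testing", {
  suppressMessages({
    sim <- simulate_cohort(simulation_config(n_samples = 50, n_pairs = 2,
                                             n_er_genes = 3, n_causal_ers = 0,
                                             seed = 23))
  })
  m <- sim$mutation
  m["ER003", ] <- 0; m["ER003", 1] <- 1  # single carrier
  suppressMessages({
    prof <- detect_dysregulation(sim$expression, sim$pairs)
    tab <- run_association(sim$expression, m, prof, sim$er_genes, seed = 23)
  })
  expect_false("ER003" %in% tab$er_gene)
  expect_error(
    suppressMessages(run_association(sim$expression, m, prof, c("NOTHERE"))),
    "none of the ER genes")
})

test_that("sample misalignment is rejected", {
  suppressMessages({
    sim <- simulate_cohort(simulation_config(n_samples = 30, n_pairs = 2,
                                             n_er_genes = 3, seed = 29))
    prof <- detect_dysregulation(sim$expression, sim$pairs)
  })
  shuffled <- sim$mutation[, rev(colnames(sim$mutation))]
  expect_error(
    run_association(sim$expression, shuffled, prof, sim$er_genes),
    "sample-aligned")
})

test_that("optional BH correction is attached across tested candidates", {
  suppressMessages({
    sim <- simulate_cohort(simulation_config(n_samples = 100, n_pairs = 4,
                                             n_er_genes = 6, seed = 37))
    prof <- detect_dysregulation(sim$expression, sim$pairs)
    tab <- run_association(sim$expression, sim$mutation, prof, sim$er_genes,
                           seed = 37, fdr = TRUE)
  })
  tested <- !is.na(tab$p_perm)
  expect_true(all(is.na(tab$p_perm_fdr[!tested])))
  if (any(tested)) {
    expect_equal(tab$p_perm_fdr[tested],
                 p.adjust(tab$p_perm[tested], method = "BH"))
  }
})
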