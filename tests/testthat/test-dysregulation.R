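test_that("Mahalanobis distances match hand evaluation on the cross design", {
  x <- matrix(c(0, 0, 2, 0, 0, 2, -2, 0, 0, -2), 2, 5,
              dimnames = list(c("LIG", "REC"), sprintf("S%d", 1:5)))
  md <- mahalanobis_pair_distances(x)
  expect_true(md$testable)
  # mean (0,0), unbiased covariance 2*I -> d((2,0)) = sqrt(4/2) = sqrt(2)
  expect_equal(unname(md$d["S1"]), 0)          # the sample at the mean
  expect_equal(unname(md$d[2:5]), rep(sqrt(2), 4))
  expect_equal(md$S, diag(2, 2), ignore_attr = TRUE)
})

test_that("distances agree with the explicit-inverse brute force", {
  for (i in 1:25) {
    x <- toy_pair(n = 40, rho = 0.5, seed = 100 + i)
    md <- mahalanobis_pair_distances(x)
    expect_equal(unname(md$d), unname(brute_mahalanobis(x)), tolerance = 1e-10)
  }
})

test_that("distances are invariant under invertible affine maps", {
  withr::with_seed(202, {
    for (i in 1:20) {
      x <- toy_pair(n = 50, rho = 0.4, seed = 300 + i)
      repeat {
        A <- matrix(rnorm(4), 2, 2)
        if (abs(det(A)) > 0.1) break
      }
      b <- rnorm(2)
      y <- A %*% x + b
      rownames(y) <- rownames(x)
      d0 <- mahalanobis_pair_distances(x)$d
      d1 <- mahalanobis_pair_distances(y)$d
      expect_equal(unname(d1), unname(d0), tolerance = 1e-8)
    }
  })
})

test_that("with identity empirical covariance the distance is Euclidean", {
  withr::with_seed(7, {
    raw <- matrix(rnorm(2 * 60), 2, 60)
    # whiten so that the empirical covariance is exactly the identity
    w <- solve(chol(cov(t(raw)))) # upper-tri inverse
    x <- t(t(raw) %*% w)
    dimnames(x) <- list(c("LIG", "REC"), sprintf("S%02d", 1:60))
    d <- mahalanobis_pair_distances(x)$d
    eu <- sqrt(colSums((x - rowMeans(x))^2))
    expect_equal(unname(d), unname(eu), tolerance = 1e-8)
  })
})

test_that("squared mode returns the raw quadratic form", {
  x <- toy_pair(n = 30, seed = 9)
  expect_equal(mahalanobis_pair_distances(x, squared = TRUE)$d,
               mahalanobis_pair_distances(x)$d^2)
})

test_that("degenerate pairs are signalled as not testable", {
  x <- toy_pair(n = 20, seed = 4)
  x["REC", ] <- 2 * x["LIG", ]  # perfectly correlated genes
  md <- mahalanobis_pair_distances(x)
  expect_false(md$testable)
  expect_match(md$reason, "singular")
  expect_true(is.numeric(md$determinant))
  expect_error(mahalanobis_pair_distances(x[, 1:2]), "3 samples")
  expect_error(mahalanobis_pair_distances(x[1, , drop = FALSE]), "2 x n")
})

test_that("Grubbs screen flags the single gross outlier and only it", {
  d <- c(0.9, 0.95, 1.0, 1.05, 1.1, 10.0)
  # oracle: closed-form critical value for n = 6, alpha = 0.05
  n <- 6; t <- qt(1 - 0.05 / n, n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
  expect_gt((max(d) - mean(d)) / sd(d), crit)
  res <- grubbs_outliers(d, alpha = 0.05)
  expect_identical(res$outlier_indices, 6L)
  expect_true(all(res$trace$G[!is.na(res$trace$flagged_index)] >
                    res$trace$critical[!is.na(res$trace$flagged_index)]))
})

test_that("Grubbs screen is empty on constant input and flags the degenerate case", {
  res <- grubbs_outliers(rep(1.3, 10))
  expect_length(res$outlier_indices, 0L)
  expect_true(res$degenerate)
})

test_that("Grubbs flagged set is invariant to sample permutation", {
  withr::with_seed(31, {
    d <- c(rnorm(50), 8, 9)
    perm <- sample.int(52)
    a <- grubbs_outliers(d)$outlier_indices
    b <- grubbs_outliers(d[perm])$outlier_indices
    expect_setequal(perm[b], a)
  })
})

test_that("Grubbs flagged fraction respects the cap", {
  withr::with_seed(8, {
    d <- c(rnorm(40), rnorm(20, 10))  # heavy contamination
    res <- grubbs_outliers(d, max_outlier_fraction = 0.1)
    expect_lte(length(res$outlier_indices), floor(0.1 * 60))
  })
})

test_that("null Grubbs flagging rate is near alpha on Gaussian sets", {
  withr::with_seed(510, {
    flagged <- vapply(1:500, function(i) {
      length(grubbs_outliers(rnorm(60))$outlier_indices) > 0
    }, logical(1))
  })
  # family-wise rate ~ alpha = 0.05; +-2 Monte-Carlo SEs around it
  se <- sqrt(0.05 * 0.95 / 500)
  expect_gt(mean(flagged), 0.05 - 2.5 * se)
  expect_lt(mean(flagged), 0.05 + 2.5 * se)
})

test_that("detect_dysregulation flags a planted displaced sample", {
  x <- toy_pair(n = 100, rho = 0.6, shift_idx = 17, shift = 10, seed = 77)
  e <- rbind(x, toy_expression(2, 100, seed = 78, genes = c("BG1", "BG2"),
                               samples = colnames(x)))
  pairs <- data.frame(ligand = "LIG", receptor = "REC")
  suppressMessages(prof <- detect_dysregulation(e, pairs))
  expect_equal(nrow(prof$pairs), 1L)
  expect_equal(unname(prof$flags[1, 17]), 1)
})

test_that("untestable pairs land in the skipped report with a reason", {
  e <- toy_expression(4, 30, seed = 21, genes = c("A", "B", "C", "D"))
  e["B", ] <- 3 * e["A", ]
  pairs <- data.frame(ligand = c("A", "A", "X"), receptor = c("B", "C", "D"))
  suppressMessages(prof <- detect_dysregulation(e, pairs))
  expect_equal(prof$pairs$pair_id, "A:C")
  expect_setequal(prof$skipped$reason, c("singular covariance", "gene absent"))
  # every input pair is either tested or skipped, never both
  all_ids <- c(prof$pairs$pair_id,
               paste(prof$skipped$ligand, prof$skipped$receptor, sep = ":"))
  expect_setequal(all_ids, c("A:B", "A:C", "X:D"))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("profile round-trips through its writer as a readable table", {
  x <- toy_pair(n = 40, shift_idx = 3, shift = 9, seed = 15)
  suppressMessages(prof <- detect_dysregulation(
    as.matrix(x), data.frame(ligand = "LIG", receptor = "REC")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dysregulation_profile(prof, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$ligand, "LIG")
  expect_equal(sum(back[, -(1:2)]), sum(prof$flags))
})
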