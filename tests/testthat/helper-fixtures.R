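# Shared fixture builders and independent oracles.

# Brute-force rooted Mahalanobis distances: explicit 2x2 inverse and a
# per-sample quadratic form. Deliberately independent of the package's
# implementation path.
brute_mahalanobis <- function(x) {
  mu <- rowMeans(x)
  S <- cov(t(x))
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
  apply(x, 2, function(v) {
    d <- v - mu
    sqrt(drop(t(d) %*% inv %*% d))
  })
}

# Small named expression matrix with positive values.
toy_expression <- function(n_genes = 4, n_samples = 6, seed = 1,
                           genes = sprintf("G%02d", seq_len(n_genes)),
                           samples = sprintf("S%02d", seq_len(n_samples))) {
  withr::with_seed(seed, {
    matrix(round(2^rnorm(n_genes * n_samples, log2(10), 1), 6),
           n_genes, n_samples, dimnames = list(genes, samples))
  })
}

# Correlated bivariate pair on the log2 scale, returned as a 2 x n TPM
# matrix with optional ligand displacement for chosen samples.
toy_pair <- function(n = 100, rho = 0.6, shift_idx = integer(0),
                     shift = 0, seed = 1,
                     genes = c("LIG", "REC")) {
  withr::with_seed(seed, {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    z1[shift_idx] <- z1[shift_idx] + shift
    x <- 2^(log2(10) + rbind(z1, z2))
    dimnames(x) <- list(genes, sprintf("S%03d", seq_len(n)))
    x
  })
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

maf_fixture_lines <- function(rows) {
  c("#version 2.4",
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
    vapply(rows, function(r) paste(r, collapse = "\t"), character(1)))
}

random_mask <- function(n, k) {
  m <- rep(0, n)
  m[sample.int(n, k)] <- 1
  m
}
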