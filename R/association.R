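# Step 2 of the screen: Wilcoxon differential-expression gate and the
# marginal-preserving permutation test on carrier/dysregulated overlap.

#' Wilcoxon rank-sum differential expression, carriers vs. wild type
#'
#' Two-sided rank-sum test of one gene's expression between mutation
#' carriers and wild-type samples. The exact null distribution is used when
#' either group has fewer than 8 samples and the data are tie-free;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used.
#'
#' Fold change is reported raw (`mean_mut / mean_wt`) and as
#' `log2((mean_mut + 1) / (mean_wt + 1))`, the 1-TPM pseudocount keeping the
#' log defined at zero means.
#'
#' @param expr_row Numeric vector: one gene's expression across samples.
#' @param mut_mask Binary (0/1 or logical) vector, same length; 1 = carrier.
#' @param min_group Minimum size of each group for the test to run.
#'   Default 3.
#' @return List with `testable`, and when testable: `p_value`,
#'   `fold_change`, `log2_fc`, `n_mut`, `n_wt`; otherwise a `reason`.
#' @export
wilcoxon_de <- function(expr_row, mut_mask, min_group = 3) {
  if (length(expr_row) != length(mut_mask)) {
    stop("`expr_row` and `mut_mask` must have the same length", call. = FALSE)
  }
  mut <- as.logical(mut_mask)
  n_mut <- sum(mut); n_wt <- sum(!mut)
  if (n_mut < min_group || n_wt < min_group) {
    return(list(testable = FALSE,
                reason = sprintf("group below minimum (%d mutant, %d wild type, need >= %d)",
                                 n_mut, n_wt, min_group),
                n_mut = n_mut, n_wt = n_wt))
  }
  x <- expr_row[mut]; y <- expr_row[!mut]
  use_exact <- (n_mut < 8L || n_wt < 8L) && !anyDuplicated(expr_row)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = use_exact, correct = TRUE))
  mean_mut <- mean(x); mean_wt <- mean(y)
  list(testable = TRUE,
       p_value = as.numeric(wt$p.value),
       fold_change = if (mean_wt > 0) mean_mut / mean_wt else Inf,
       log2_fc = log2((mean_mut + 1) / (mean_wt + 1)),
       n_mut = n_mut, n_wt = n_wt)
}

#' Permutation test on the carrier/dysregulated sample overlap
#'
#' Measures how unexpectedly often mutation carriers coincide with samples
#' flagged as dysregulated for one interaction pair. The observed overlap is
#' `n_obser = |carriers intersect dysregulated|`. Each of `n_perm`
#' permutations redraws the carrier set as a uniform random subset of the
#' same size (a marginal-preserving label shuffle), giving a background
#' overlap distribution.
#'
#' Two p-value modes:
#' \describe{
#'   \item{`"pseudocount"` (default)}{`p = (1 + #(perm >= n_obser)) / (n_perm + 1)`,
#'     the add-one estimator that keeps p in (0, 1].}
#'   \item{`"as_printed"`}{`p = #(perm > n_obser) / n_perm`, the literal
#'     strict-inequality form; it returns 0 whenever no permutation exceeds
#'     the observation, and warns when `n_obser = 0` where it degenerates.}
#' }
#' The raw counts `n_ge` (permutations with overlap >= observed) and `n_gt`
#' are returned so callers can form the unbiased tail estimate `n_ge/n_perm`.
#'
#' @param mut_mask,dys_mask Equal-length binary (or logical) vectors over
#'   aligned samples; each must have at least one 1.
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param seed Integer seed; the RNG state of the caller is left untouched.
#' @param p_mode `"pseudocount"` or `"as_printed"`.
#' @return List with `n_obser`, `n_mut`, `n_dys`, `p_perm`, `n_ge`, `n_gt`,
#'   `n_perm`, `seed`, `p_mode`.
#' @export
overlap_permutation_test <- function(mut_mask, dys_mask, n_perm = 1000,
                                     seed = 1,
                                     p_mode = c("pseudocount", "as_printed")) {
  p_mode <- match.arg(p_mode)
  if (length(mut_mask) != length(dys_mask)) {
    stop("masks must have the same length", call. = FALSE)
  }
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  mut <- as.logical(mut_mask); dys <- as.logical(dys_mask)
  n <- length(mut)
  n_mut <- sum(mut); n_dys <- sum(dys)
  if (n_mut < 1L || n_dys < 1L) {
    stop("both masks must flag at least one sample", call. = FALSE)
  }
  n_obser <- sum(mut & dys)
  dysn <- as.numeric(dys)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(dysn[sample.int(n, n_mut)]), numeric(1))
  })
  n_ge <- sum(perm >= n_obser)
  n_gt <- sum(perm > n_obser)
  p <- if (p_mode == "pseudocount") (1 + n_ge) / (n_perm + 1) else n_gt / n_perm
  if (p_mode == "as_printed" && n_obser == 0L) {
    warning("observed overlap is 0: the strict-inequality p-value is 0 whenever no permutation overlap is positive; consider p_mode = \"pseudocount\"",
            call. = FALSE)
  }
  list(n_obser = n_obser, n_mut = n_mut, n_dys = n_dys, p_perm = p,
       n_ge = n_ge, n_gt = n_gt, n_perm = n_perm, seed = seed, p_mode = p_mode)
}

#' Screen ER mutations against dysregulated interactions
#'
#' For every epigenetic-regulator (ER) gene with at least `min_mut_samples`
#' carriers and every interaction pair with at least one dysregulated
#' sample, the candidate (ER, pair) link is:
#' 1. gated on differential expression: [wilcoxon_de()] of the ligand and
#'    the receptor in carriers vs. wild type over all aligned samples; the
#'    gate passes when at least one gene has `p < de_alpha`;
#' 2. scored, if gated in, by [overlap_permutation_test()] between the ER's
#'    carrier mask and the pair's dysregulation mask. Links with
#'    `p_perm < assoc_alpha` are marked `selected`.
#'
#' Every candidate appears in the output (gated-out candidates carry
#' `p_perm = NA`). Each permutation test uses its own seed derived
#' deterministically from `seed`, the ER symbol and the pair identifier, so
#' the table is reproducible and independent of evaluation order and of
#' `workers`.
#'
#' @param e Expression matrix, sample-aligned with `m` and `profile`.
#' @param m Binary mutation matrix.
#' @param profile A `dysregulation_profile` from [detect_dysregulation()].
#' @param ers Character vector of ER gene symbols.
#' @param n_perm Permutations per test. Default 1000.
#' @param seed Master seed. Default 1.
#' @param p_mode Permutation p-value mode; see [overlap_permutation_test()].
#' @param de_alpha Differential-expression gate level. Default 0.05.
#' @param assoc_alpha Selection level on the permutation p. Default 0.05.
#' @param min_mut_samples Minimum carriers (and wild-type samples) per ER.
#'   Default 3.
#' @param fdr Add a Benjamini-Hochberg `p_perm_fdr` column across the tested
#'   candidates? Default `FALSE`.
#' @param workers Number of forked workers for the permutation stage
#'   (results are identical for any value). Default 1.
#' @return data.frame sorted by `p_perm` (NA last), then ER symbol, then
#'   pair: columns `er_gene`, `ligand`, `receptor`, `n_mut`, `n_dys`,
#'   `n_obser`, `de_p_ligand`, `de_p_receptor`, `log2_fc_ligand`,
#'   `log2_fc_receptor`, `de_pass`, `p_perm`, `selected` (and `p_perm_fdr`
#'   with `fdr = TRUE`).
#' @export
run_association <- function(e, m, profile, ers, n_perm = 1000, seed = 1,
                            p_mode = c("pseudocount", "as_printed"),
                            de_alpha = 0.05, assoc_alpha = 0.05,
                            min_mut_samples = 3, fdr = FALSE, workers = 1) {
  p_mode <- match.arg(p_mode)
  validate_expression(e); validate_mutation(m)
  stopifnot(inherits(profile, "dysregulation_profile"))
  samples <- colnames(e)
  if (!identical(samples, colnames(m)) ||
      !identical(samples, profile$sample_ids)) {
    stop("expression, mutation and dysregulation profile must be sample-aligned (use align_samples())",
         call. = FALSE)
  }
  ers <- unique(toupper(ers))
  ers_present <- intersect(ers, rownames(m))
  if (length(ers_present) == 0L) {
    stop("none of the ER genes occur in the mutation matrix", call. = FALSE)
  }
  carriers <- rowSums(m[ers_present, , drop = FALSE])
  n <- length(samples)
  eligible <- ers_present[carriers >= min_mut_samples &
                            (n - carriers) >= min_mut_samples]
  dropped <- setdiff(ers_present, eligible)
  if (length(dropped) > 0L) {
    message(sprintf("association: %d ER gene(s) below %d carriers (or wild-type floor) excluded",
                    length(dropped), min_mut_samples))
  }
  pair_df <- profile$pairs[profile$pairs$n_flagged >= 1L, , drop = FALSE]
  message(sprintf("association: %d eligible ER gene(s) x %d pair(s) with dysregulation",
                  length(eligible), nrow(pair_df)))
  if (length(eligible) == 0L || nrow(pair_df) == 0L) {
    return(empty_association_table(fdr))
  }

  de_cache <- new.env(parent = emptyenv())
  de_for <- function(er, gene) {
    key <- paste(er, gene, sep = "\r")
    if (!is.null(res <- de_cache[[key]])) return(res)
    res <- wilcoxon_de(e[gene, ], m[er, ], min_group = min_mut_samples)
    de_cache[[key]] <- res
    res
  }

  candidates <- list()
  for (er in eligible) {
    for (k in seq_len(nrow(pair_df))) {
      lig <- pair_df$ligand[k]; rec <- pair_df$receptor[k]
      de_l <- de_for(er, lig); de_r <- de_for(er, rec)
      p_l <- if (de_l$testable) de_l$p_value else NA_real_
      p_r <- if (de_r$testable) de_r$p_value else NA_real_
      de_pass <- isTRUE(p_l < de_alpha) || isTRUE(p_r < de_alpha)
      candidates[[length(candidates) + 1L]] <- list(
        er_gene = er, ligand = lig, receptor = rec,
        pair_id = pair_df$pair_id[k],
        de_p_ligand = p_l, de_p_receptor = p_r,
        log2_fc_ligand = if (de_l$testable) de_l$log2_fc else NA_real_,
        log2_fc_receptor = if (de_r$testable) de_r$log2_fc else NA_real_,
        de_pass = de_pass)
    }
  }

  score_one <- function(cand) {
    row <- data.frame(er_gene = cand$er_gene, ligand = cand$ligand,
                      receptor = cand$receptor,
                      n_mut = sum(m[cand$er_gene, ]),
                      n_dys = NA_integer_, n_obser = NA_integer_,
                      de_p_ligand = cand$de_p_ligand,
                      de_p_receptor = cand$de_p_receptor,
                      log2_fc_ligand = cand$log2_fc_ligand,
                      log2_fc_receptor = cand$log2_fc_receptor,
                      de_pass = cand$de_pass,
                      p_perm = NA_real_, selected = FALSE,
                      stringsAsFactors = FALSE)
    dys <- profile$flags[cand$pair_id, ]
    row$n_dys <- as.integer(sum(dys))
    row$n_obser <- as.integer(sum(m[cand$er_gene, ] > 0 & dys > 0))
    if (cand$de_pass) {
      pt <- overlap_permutation_test(
        m[cand$er_gene, ], dys, n_perm = n_perm,
        seed = derive_seed(seed, cand$er_gene, cand$pair_id),
        p_mode = p_mode)
      row$p_perm <- pt$p_perm
      row$selected <- pt$p_perm < assoc_alpha
    }
    row
  }

  rows <- if (workers > 1L) {
    parallel::mclapply(candidates, score_one, mc.cores = workers)
  } else {
    lapply(candidates, score_one)
  }
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab$p_perm), tab$p_perm, tab$er_gene, tab$ligand,
               tab$receptor)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (fdr) {
    tab$p_perm_fdr <- NA_real_
    tested <- !is.na(tab$p_perm)
    tab$p_perm_fdr[tested] <- p.adjust(tab$p_perm[tested], method = "BH")
  }
  message(sprintf("association: %d candidate(s), %d passed DE gate, %d selected",
                  nrow(tab), sum(tab$de_pass), sum(tab$selected)))
  tab
}

empty_association_table <- function(fdr) {
  tab <- data.frame(er_gene = character(0), ligand = character(0),
                    receptor = character(0), n_mut = integer(0),
                    n_dys = integer(0), n_obser = integer(0),
                    de_p_ligand = numeric(0), de_p_receptor = numeric(0),
                    log2_fc_ligand = numeric(0), log2_fc_receptor = numeric(0),
                    de_pass = logical(0), p_perm = numeric(0),
                    selected = logical(0), stringsAsFactors = FALSE)
  if (fdr) tab$p_perm_fdr <- numeric(0)
  tab
}

#' Write an association table
#'
#' Tab-separated serialization of the [run_association()] result with
#' full-precision numerics, so identical runs produce byte-identical files.
#'
#' @param tab Association data.frame.
#' @param path Output path.
#' @export
write_association_table <- function(tab, path) {
  out <- tab
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "g", digits = 17)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
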