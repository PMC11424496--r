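# Downstream computations: integrated ER-mutation signature groups,
# tumour-immune expression scores, and hypergeometric gene-set enrichment.

#' Stratify samples by integrated ER mutation status
#'
#' Counts, per sample, how many of the given epigenetic-regulator genes are
#' mutated and assigns the three-level signature used for patient
#' stratification: `0` = wild type (no ER mutated), `1` = single-mutation
#' (exactly one ER mutated), `2` = multiple-mutation (two or more).
#'
#' @param m Binary mutation matrix, genes x samples.
#' @param ers Character vector of ER gene symbols; at least one must be
#'   present in `m`.
#' @return data.frame with columns `sample_id`, `n_mutated_er`, `group`
#'   (integer in 0:2); the ER genes actually used are attached as the
#'   `er_genes_used` attribute.
#' @export
build_signature <- function(m, ers) {
  validate_mutation(m)
  ers <- unique(toupper(ers))
  used <- intersect(ers, rownames(m))
  if (length(used) == 0L) {
    stop("none of the ER genes occur in the mutation matrix", call. = FALSE)
  }
  k <- colSums(m[used, , drop = FALSE])
  out <- data.frame(sample_id = colnames(m),
                    n_mutated_er = as.integer(k),
                    group = as.integer(pmin(k, 2)),
                    stringsAsFactors = FALSE)
  attr(out, "er_genes_used") <- used
  out
}

mhc1_genes <- c("HLA-A", "HLA-B", "HLA-C", "B2M")
ctl_genes <- c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1")
cyt_genes <- c("GZMA", "PRF1")

#' Per-sample tumour-immune expression scores
#'
#' Three standard scores on the provided (TPM) expression scale:
#' \describe{
#'   \item{`mhc1`}{arithmetic mean of HLA-A, HLA-B, HLA-C and B2M --
#'     MHC class I expression.}
#'   \item{`ctl`}{arithmetic mean of CD8A, CD8B, GZMA, GZMB and PRF1 --
#'     cytotoxic T lymphocyte level.}
#'   \item{`cyt`}{cytolytic activity, the geometric mean of GZMA and PRF1;
#'     with `cyt_pseudocount = TRUE` (default) computed as
#'     `sqrt((GZMA + 1) * (PRF1 + 1))`, the TPM+1 convention of the
#'     cytolytic-activity literature.}
#' }
#' A score whose required genes are missing from the matrix is returned as
#' `NA` for all samples, with a message naming the genes; the remaining
#' scores are still computed.
#'
#' @param e Expression matrix, genes x samples.
#' @param cyt_pseudocount Add 1 TPM to GZMA and PRF1 inside the geometric
#'   mean? Default `TRUE`.
#' @return data.frame with columns `sample_id`, `mhc1`, `ctl`, `cyt`.
#' @export
immune_scores <- function(e, cyt_pseudocount = TRUE) {
  validate_expression(e)
  score_mean <- function(genes, label) {
    missing <- setdiff(genes, rownames(e))
    if (length(missing) > 0L) {
      message(sprintf("%s not computable: gene(s) absent: %s", label,
                      paste(missing, collapse = ", ")))
      return(rep(NA_real_, ncol(e)))
    }
    colMeans(e[genes, , drop = FALSE])
  }
  mhc1 <- score_mean(mhc1_genes, "mhc1")
  ctl <- score_mean(ctl_genes, "ctl")
  missing_cyt <- setdiff(cyt_genes, rownames(e))
  if (length(missing_cyt) > 0L) {
    message(sprintf("cyt not computable: gene(s) absent: %s",
                    paste(missing_cyt, collapse = ", ")))
    cyt <- rep(NA_real_, ncol(e))
  } else {
    eps <- if (cyt_pseudocount) 1 else 0
    cyt <- sqrt((e["GZMA", ] + eps) * (e["PRF1", ] + eps))
  }
  data.frame(sample_id = colnames(e), mhc1 = as.numeric(mhc1),
             ctl = as.numeric(ctl), cyt = as.numeric(cyt),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of a query gene set
#' against each set of a collection, over a background universe, with
#' Benjamini-Hochberg FDR across the collection. Query and sets are
#' restricted to the universe before testing.
#'
#' @param query Character vector of gene symbols (e.g. dysregulated
#'   ligand-receptor genes).
#' @param sets Named list of symbol vectors, e.g. from [read_gmt()].
#' @param universe Background symbol universe (e.g. all genes retained in
#'   the expression matrix after filtering).
#' @return data.frame sorted by `p_hyper` then `set_name`: columns
#'   `set_name`, `overlap_count`, `query_size`, `set_size`, `universe_size`,
#'   `p_hyper`, `fdr`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  universe <- unique(toupper(universe))
  query <- intersect(unique(toupper(query)), universe)
  if (length(query) == 0L) {
    stop("query is empty after restriction to the universe", call. = FALSE)
  }
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), universe)
    ov <- length(intersect(query, s))
    p <- if (length(s) == 0L) 1 else
      phyper(ov - 1L, length(s), length(universe) - length(s),
             length(query), lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = ov,
               query_size = length(query), set_size = length(s),
               universe_size = length(universe), p_hyper = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p_hyper, method = "BH")
  tab <- tab[order(tab$p_hyper, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
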