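# Synthetic cohort generator: log-normal ligand-receptor expression with
# planted outliers, and mutation carrier sets with tunable enrichment in the
# dysregulated samples, plus ground-truth labels.

#' Simulation configuration
#'
#' Parameters of [simulate_cohort()]. Expression is modelled log-normally:
#' pair genes are bivariate normal on the log2 scale with unit SD around
#' `log2(10)` (median TPM near 10, right-skewed on the natural scale) and
#' correlation `pair_correlation`; shifts (`outlier_shift`, `de_shift`) are
#' applied on the log2 scale, so they are expressed in per-gene log-scale
#' SD units / log2-fold units respectively.
#'
#' @param n_samples Cohort size. Default 200.
#' @param n_background_genes Independent log-normal noise genes. Default 50.
#' @param n_pairs Ligand-receptor pairs. Default 20.
#' @param pair_correlation Log-scale correlation of each pair, in `[0, 1)`.
#'   Default 0.6.
#' @param dysregulated_fraction Fraction of samples planted as outliers for
#'   each causal pair. Default 0.05.
#' @param outlier_shift Ligand displacement of planted outliers, in
#'   log-scale SDs. Default 6.
#' @param n_er_genes Epigenetic-regulator genes in the mutation matrix.
#'   Default 20.
#' @param n_causal_ers ERs whose carriers are enriched in the dysregulated
#'   samples of their pair (causal ER `j` is linked to pair `j`).
#'   Default 1.
#' @param carrier_fraction Fraction of samples mutated per ER. Default 0.1.
#' @param overlap_enrichment Fraction of each causal pair's dysregulated
#'   samples that are carriers of its ER, in `[0, 1]`. Default 0.8.
#' @param de_shift Additional log2-scale ligand shift in carriers of a
#'   causal ER (makes the differential-expression gate satisfiable).
#'   Default 1.
#' @param seed Master seed; every random component draws from its own
#'   stream derived from it. Default 1.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 200, n_background_genes = 50,
                              n_pairs = 20, pair_correlation = 0.6,
                              dysregulated_fraction = 0.05, outlier_shift = 6,
                              n_er_genes = 20, n_causal_ers = 1,
                              carrier_fraction = 0.1, overlap_enrichment = 0.8,
                              de_shift = 1, seed = 1) {
  cfg <- list(n_samples = n_samples,
              n_background_genes = n_background_genes,
              n_pairs = n_pairs, pair_correlation = pair_correlation,
              dysregulated_fraction = dysregulated_fraction,
              outlier_shift = outlier_shift, n_er_genes = n_er_genes,
              n_causal_ers = n_causal_ers,
              carrier_fraction = carrier_fraction,
              overlap_enrichment = overlap_enrichment,
              de_shift = de_shift, seed = as.integer(seed))
  fracs <- c("pair_correlation", "dysregulated_fraction", "carrier_fraction",
             "overlap_enrichment")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("`", f, "` must be in [0, 1]",
                                           call. = FALSE)
  }
  if (cfg$pair_correlation >= 1) stop("`pair_correlation` must be < 1",
                                      call. = FALSE)
  if (cfg$n_causal_ers > cfg$n_er_genes) {
    stop("`n_causal_ers` cannot exceed `n_er_genes`", call. = FALSE)
  }
  if (cfg$n_causal_ers > cfg$n_pairs) {
    stop("`n_causal_ers` cannot exceed `n_pairs`", call. = FALSE)
  }
  if (cfg$n_samples < 10) stop("`n_samples` must be at least 10", call. = FALSE)
  structure(cfg, class = "sim_config")
}

pad_id <- function(prefix, i) sprintf("%s%03d", prefix, i)

#' Simulate a tumour cohort with ground truth
#'
#' Generates an expression matrix, a binary mutation matrix, an interaction
#' set and an ER gene list with the statistical structure the screen
#' assumes, plus the ground-truth labels:
#' * each pair's two genes are correlated bivariate-normal on the log2
#'   scale, exponentiated to TPM-like values;
#' * for each *causal* pair (pair `j` for causal ER `j`,
#'   `j <= n_causal_ers`) a `dysregulated_fraction` subset of samples has
#'   its ligand displaced by `outlier_shift` log-scale SDs, breaking the
#'   pair correlation;
#' * causal-ER carrier sets contain an `overlap_enrichment` fraction of the
#'   pair's dysregulated samples, filled to `carrier_fraction` with random
#'   non-dysregulated samples; null ERs carry uniform random carrier sets
#'   of the same size;
#' * carriers of a causal ER additionally get a `de_shift` log2-unit ligand
#'   shift;
#' * background genes are independent log-normal noise.
#'
#' All randomness flows from `cfg$seed` through named per-component streams,
#' so e.g. adding pairs does not perturb the mutation draws.
#'
#' @param cfg A `sim_config` from [simulation_config()].
#' @return List with `expression`, `mutation`, `pairs`, `er_genes`, and
#'   `truth` (list: `causal` data.frame of (er_gene, ligand, receptor),
#'   `dysregulated` named list of sample IDs per causal pair id, `carriers`
#'   named list of sample IDs per ER).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  samples <- pad_id("S", seq_len(n))
  ligands <- pad_id("LG", seq_len(cfg$n_pairs))
  receptors <- pad_id("RC", seq_len(cfg$n_pairs))
  er_genes <- pad_id("ER", seq_len(cfg$n_er_genes))
  mu_log <- log2(10); sd_log <- 1
  rho <- cfg$pair_correlation

  # log2-scale pair expression, one RNG stream per pair
  z <- matrix(NA_real_, 2L * cfg$n_pairs, n,
              dimnames = list(as.vector(rbind(ligands, receptors)), samples))
  for (j in seq_len(cfg$n_pairs)) {
    zj <- withr::with_seed(derive_seed(cfg$seed, "pair", j), {
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      rbind(z1, z2)
    })
    z[ligands[j], ] <- mu_log + sd_log * zj[1L, ]
    z[receptors[j], ] <- mu_log + sd_log * zj[2L, ]
  }

  n_dys <- round(cfg$dysregulated_fraction * n)
  n_carrier <- round(cfg$carrier_fraction * n)
  need <- ceiling(cfg$overlap_enrichment * n_dys)
  if (cfg$n_causal_ers > 0L && n_carrier < need) {
    stop(sprintf(paste0("infeasible overlap: carrier_fraction x n_samples ",
                        "(%d) < overlap_enrichment x dysregulated count (%d)"),
                 n_carrier, need), call. = FALSE)
  }

  dys_sets <- list()
  for (j in seq_len(cfg$n_causal_ers)) {
    dys <- withr::with_seed(derive_seed(cfg$seed, "dys", j),
                            sort(sample.int(n, n_dys)))
    dys_sets[[paste(ligands[j], receptors[j], sep = ":")]] <- samples[dys]
    z[ligands[j], dys] <- z[ligands[j], dys] + cfg$outlier_shift * sd_log
  }

  mut <- matrix(0, cfg$n_er_genes, n, dimnames = list(er_genes, samples))
  carrier_sets <- list()
  for (j in seq_len(cfg$n_er_genes)) {
    idx <- withr::with_seed(derive_seed(cfg$seed, "mut", j), {
      if (j <= cfg$n_causal_ers) {
        dys <- match(dys_sets[[j]], samples)
        in_dys <- if (need > 0L) dys[sample.int(length(dys), need)] else integer(0)
        pool <- setdiff(seq_len(n), dys)
        fill <- if (n_carrier - need > 0L) pool[sample.int(length(pool), n_carrier - need)]
                else integer(0)
        sort(c(in_dys, fill))
      } else {
        sort(sample.int(n, n_carrier))
      }
    })
    mut[j, idx] <- 1
    carrier_sets[[er_genes[j]]] <- samples[idx]
    if (j <= cfg$n_causal_ers) {
      z[ligands[j], idx] <- z[ligands[j], idx] + cfg$de_shift
    }
  }

  bg <- NULL
  if (cfg$n_background_genes > 0L) {
    bg_genes <- pad_id("BG", seq_len(cfg$n_background_genes))
    bg <- withr::with_seed(derive_seed(cfg$seed, "background"), {
      matrix(rnorm(cfg$n_background_genes * n, mu_log, sd_log),
             cfg$n_background_genes, n, dimnames = list(bg_genes, samples))
    })
  }

  expr <- 2^rbind(z, bg)
  validate_expression(expr)
  validate_mutation(mut)
  truth <- list(
    causal = if (cfg$n_causal_ers > 0L) {
      data.frame(er_gene = er_genes[seq_len(cfg$n_causal_ers)],
                 ligand = ligands[seq_len(cfg$n_causal_ers)],
                 receptor = receptors[seq_len(cfg$n_causal_ers)],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(er_gene = character(0), ligand = character(0),
                 receptor = character(0), stringsAsFactors = FALSE)
    },
    dysregulated = dys_sets,
    carriers = carrier_sets)
  list(expression = expr, mutation = mut,
       pairs = data.frame(ligand = ligands, receptor = receptors,
                          stringsAsFactors = FALSE),
       er_genes = er_genes, truth = truth, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Writes the four pipeline input files (expression and mutation matrices,
#' pair list, ER gene list) in the formats the readers expect, plus the
#' ground truth as JSON.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             er_genes = file.path(dir, "er_genes.txt"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expression, paths[["expression"]])
  write_mutation_matrix(sim$mutation, paths[["mutations"]])
  utils::write.table(sim$pairs, paths[["pairs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$er_genes, paths[["er_genes"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(paths)
}
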