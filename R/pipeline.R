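# End-to-end orchestration: read inputs, filter, align, detect
# dysregulation, run the association screen, and write outputs with
# reproducibility metadata.

default_run_params <- function() {
  list(min_fraction = 0.7, min_tpm = 0,
       alpha = 0.05, max_outlier_fraction = 0.2,
       squared = FALSE, log_transform = FALSE,
       n_perm = 1000, seed = 1, p_mode = "pseudocount",
       de_alpha = 0.05, assoc_alpha = 0.05, min_mut_samples = 3,
       fdr = FALSE, workers = 1,
       maf_retained_classes = coding_variant_classes())
}

#' Run the full mutation-vs-dysregulation screen from files
#'
#' Executes the pipeline: read expression, pairs, ER list and mutations
#' (binary matrix or MAF); filter lowly expressed genes; align samples;
#' detect dysregulated interactions; run the association screen. All
#' outputs, a plain-text log, a JSON run summary and the resolved
#' configuration (with input checksums) are written to `out_dir`.
#'
#' @param config Either a named list or a path to a YAML file with entries:
#'   `expression` (TSV path), `pairs` (TSV path), `er_genes` (list path),
#'   one of `mutations` (binary TSV path) or `maf` (MAF path), `out_dir`,
#'   and any parameter of `default_run_params()` (alpha levels, `n_perm`,
#'   `seed`, `p_mode`, `min_fraction`, `min_mut_samples`, ...).
#' @return Invisibly, a list with the association table, the dysregulation
#'   profile, and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  for (field in c("expression", "pairs", "er_genes", "out_dir")) {
    if (is.null(config[[field]])) stop("config lacks required entry `",
                                       field, "`", call. = FALSE)
  }
  if (is.null(config$mutations) && is.null(config$maf)) {
    stop("config must provide `mutations` (binary matrix) or `maf`",
         call. = FALSE)
  }
  params <- modifyList(default_run_params(),
                       config[intersect(names(config),
                                        names(default_run_params()))])
  inputs <- c(expression = config$expression, pairs = config$pairs,
              er_genes = config$er_genes,
              if (!is.null(config$mutations)) c(mutations = config$mutations)
              else c(maf = config$maf))
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop("input file `", nm, "` not found: ", inputs[[nm]], call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  capture_msgs <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  e <- read_expression(config$expression)
  note("stage read: expression %d gene(s) x %d sample(s)", nrow(e), ncol(e))
  pairs <- withCallingHandlers(read_pairs(config$pairs), warning = function(w) {
    log_lines <<- c(log_lines, paste("warning:", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  ers <- read_gene_list(config$er_genes)
  note("stage read: %d interaction pair(s), %d ER gene(s)",
       nrow(pairs), length(ers))
  m <- if (!is.null(config$mutations)) {
    read_mutation_matrix(config$mutations)
  } else {
    maf_to_mutation_matrix(config$maf, colnames(e),
                           retained_classes = params$maf_retained_classes)
  }
  note("stage read: mutations %d gene(s) x %d sample(s)", nrow(m), ncol(m))

  n_before <- nrow(e)
  e <- filter_expressed_genes(e, min_fraction = params$min_fraction,
                              min_tpm = params$min_tpm)
  note("stage filter: %d -> %d gene(s) expressed in more than %.0f%% of samples",
       n_before, nrow(e), 100 * params$min_fraction)

  aligned <- capture_msgs(align_samples(e, m))
  e <- aligned$expression; m <- aligned$mutation
  note("stage align: %d shared sample(s)", ncol(e))

  profile <- capture_msgs(detect_dysregulation(
    e, pairs, alpha = params$alpha,
    max_outlier_fraction = params$max_outlier_fraction,
    squared = params$squared, log_transform = params$log_transform))
  note("stage detect: %d pair(s) tested, %d skipped",
       nrow(profile$pairs), nrow(profile$skipped))

  tab <- capture_msgs(run_association(
    e, m, profile, ers, n_perm = params$n_perm, seed = params$seed,
    p_mode = params$p_mode, de_alpha = params$de_alpha,
    assoc_alpha = params$assoc_alpha,
    min_mut_samples = params$min_mut_samples, fdr = params$fdr,
    workers = params$workers))
  note("stage associate: %d candidate(s), %d selected",
       nrow(tab), sum(tab$selected))

  paths <- c(profile = file.path(out_dir, "dysregulation_profile.tsv"),
             skipped = file.path(out_dir, "skipped_pairs.tsv"),
             associations = file.path(out_dir, "association_table.tsv"),
             config = file.path(out_dir, "run_config.yaml"),
             summary = file.path(out_dir, "run_summary.json"),
             log = file.path(out_dir, "log.txt"))
  write_dysregulation_profile(profile, paths[["profile"]], paths[["skipped"]])
  write_association_table(tab, paths[["associations"]])

  resolved <- c(list(tool = "perturbLR",
                     version = as.character(packageVersion("perturbLR")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        usetz = TRUE),
                     inputs = as.list(inputs),
                     input_md5 = as.list(tools::md5sum(unname(inputs))),
                     out_dir = out_dir),
                params)
  yaml::write_yaml(resolved, paths[["config"]])
  jsonlite::write_json(
    list(n_genes_after_filter = nrow(e), n_samples = ncol(e),
         n_pairs_tested = nrow(profile$pairs),
         n_pairs_skipped = nrow(profile$skipped),
         n_dysregulation_flags = sum(profile$flags),
         n_candidates = nrow(tab),
         n_de_gated_in = sum(tab$de_pass),
         n_selected = sum(tab$selected)),
    paths[["summary"]], auto_unbox = TRUE)
  writeLines(log_lines, paths[["log"]])
  invisible(list(associations = tab, profile = profile, paths = paths,
                 params = params))
}
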