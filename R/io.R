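# Readers, writers and input-filtering rules for the cohort data types.
#
# All matrices are plain numeric matrices with gene symbols (uppercased) as
# rownames and sample identifiers as colnames; interaction sets are
# data.frames with `ligand` and `receptor` columns.

read_tsv_matrix <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE,
                          colClasses = list(character = 1), na.strings = NULL)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop(what, " file is empty or has no sample columns: ", path, call. = FALSE)
  }
  genes <- toupper(trimws(as.character(dt[[1L]])))
  samples <- colnames(dt)[-1L]
  vals <- matrix(NA_real_, nrow(dt), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- dt[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' in %s file at gene '%s', sample '%s'",
                   as.character(col[i]), what, genes[i], samples[j]),
           call. = FALSE)
    }
    vals[, j] <- num
  }
  list(genes = genes, values = vals)
}

collapse_duplicates <- function(genes, values, fun_label, fun) {
  if (!anyDuplicated(genes)) {
    rownames(values) <- genes
    return(values)
  }
  dup <- unique(genes[duplicated(genes)])
  warning(sprintf("collapsing %d duplicated gene row(s) by %s: %s",
                  length(dup), fun_label,
                  paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
    fun(values[i, , drop = FALSE])
  }))
  colnames(out) <- colnames(values)
  # split() orders by name; restore first-appearance order
  out[unique(genes), , drop = FALSE]
}

#' Read a gene expression matrix
#'
#' Parses a tab-separated expression table (first column gene symbols, header
#' row of sample identifiers, TPM-scale values). Gene symbols are uppercased;
#' duplicated gene rows are collapsed by their arithmetic mean with a warning.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes x samples.
#' @seealso [write_expression()], [filter_expressed_genes()]
#' @export
read_expression <- function(path) {
  parsed <- read_tsv_matrix(path, "expression")
  m <- collapse_duplicates(parsed$genes, parsed$values, "mean",
                           function(x) colMeans(x))
  validate_expression(m)
}

#' Read a binary mutation matrix
#'
#' Same layout as [read_expression()]; entries must be 0 (wild type) or
#' 1 (mutated). Duplicated gene rows are collapsed by logical OR.
#'
#' @param path Path to a tab-separated file.
#' @return Binary numeric matrix, genes x samples.
#' @export
read_mutation_matrix <- function(path) {
  parsed <- read_tsv_matrix(path, "mutation")
  m <- collapse_duplicates(parsed$genes, parsed$values, "logical OR",
                           function(x) as.numeric(colSums(x) > 0))
  validate_mutation(m)
}

write_named_matrix <- function(m, path, id_col) {
  txt <- formatC(m, format = "g", digits = 17)
  out <- cbind(rownames(m), txt)
  colnames(out) <- c(id_col, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: values are serialized with 17 significant
#' digits so a write/read round trip reproduces the matrix bit-identically.
#'
#' @param m Numeric genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  write_named_matrix(m, path, "gene")
}

#' Write a binary mutation matrix
#' @rdname write_expression
#' @export
write_mutation_matrix <- function(m, path) {
  validate_mutation(m)
  write_named_matrix(m, path, "gene")
}

#' Variant classes that affect protein-coding capacity
#'
#' The MAF `Variant_Classification` values retained when binarizing somatic
#' mutations: non-silent coding changes plus splice and translation-start
#' disruptions.
#'
#' @return Character vector of classification labels.
#' @export
coding_variant_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Binarize a MAF file into a mutation matrix
#'
#' Reads a Mutation Annotation Format file (tab-separated, `#` comment lines
#' allowed) and produces a binary gene x sample matrix over the given sample
#' set: an entry is 1 iff the sample carries at least one variant of the gene
#' whose classification is in `retained_classes`. Variants of samples not in
#' `samples` are ignored. Genes are all symbols seen in the MAF, so a gene
#' whose only variants are filtered out appears as an all-zero row.
#'
#' @param path Path to a MAF file with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode` and `Variant_Classification` columns.
#' @param samples Character vector of sample identifiers (matrix columns).
#' @param retained_classes Variant classifications treated as
#'   protein-coding-altering; defaults to [coding_variant_classes()].
#' @return Binary numeric matrix, genes x samples, gene rows sorted.
#' @export
maf_to_mutation_matrix <- function(path, samples,
                                   retained_classes = coding_variant_classes()) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  if (length(samples) == 0L || anyDuplicated(samples)) {
    stop("`samples` must be a non-empty set of unique sample identifiers",
         call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("MAF file is empty: ", path, call. = FALSE)
  maf <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                           header = TRUE, data.table = FALSE,
                           check.names = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, colnames(maf))
  if (length(missing) > 0L) {
    stop("MAF file lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes <- sort(unique(toupper(trimws(as.character(maf$Hugo_Symbol)))))
  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- maf$Variant_Classification %in% retained_classes &
    maf$Tumor_Sample_Barcode %in% samples
  if (any(keep)) {
    g <- toupper(trimws(as.character(maf$Hugo_Symbol[keep])))
    s <- as.character(maf$Tumor_Sample_Barcode[keep])
    m[cbind(match(g, genes), match(s, samples))] <- 1
  }
  validate_mutation(m)
}

#' Build a ligand-receptor interaction set
#'
#' Uppercases symbols, drops self-pairs (ligand equal to receptor) and
#' removes duplicated unordered pairs, each with a warning.
#'
#' @param ligand,receptor Character vectors of gene symbols, same length.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
interaction_set <- function(ligand, receptor) {
  if (length(ligand) != length(receptor)) {
    stop("`ligand` and `receptor` must have the same length", call. = FALSE)
  }
  ligand <- toupper(trimws(as.character(ligand)))
  receptor <- toupper(trimws(as.character(receptor)))
  self <- ligand == receptor
  if (any(self)) {
    warning(sprintf("dropping %d self-pair(s) (ligand == receptor)", sum(self)),
            call. = FALSE)
    ligand <- ligand[!self]; receptor <- receptor[!self]
  }
  key <- paste(pmin(ligand, receptor), pmax(ligand, receptor))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicated interaction pair(s)", sum(dup)),
            call. = FALSE)
    ligand <- ligand[!dup]; receptor <- receptor[!dup]
  }
  if (length(ligand) == 0L) stop("interaction set is empty", call. = FALSE)
  data.frame(ligand = ligand, receptor = receptor, stringsAsFactors = FALSE)
}

#' Read a ligand-receptor pair list
#'
#' Two-column tab-separated file with header `ligand<TAB>receptor`.
#'
#' @param path Path to the pair file.
#' @return data.frame from [interaction_set()].
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("pair file must have two columns", call. = FALSE)
  interaction_set(dt[[1L]], dt[[2L]])
}

#' Read a gene list
#'
#' One-column text file of gene symbols (uppercased), optionally with a
#' second tab-separated annotation column (e.g. epigenetic-regulator class).
#'
#' @param path Path to the list file.
#' @param header Does the file carry a header row? Default `FALSE`.
#' @return Character vector of unique symbols; if an annotation column is
#'   present it is attached as the `annotation` attribute (named by gene).
#' @export
read_gene_list <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("gene list file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = header,
                          data.table = FALSE)
  genes <- toupper(trimws(as.character(dt[[1L]])))
  keep <- !duplicated(genes) & nzchar(genes)
  genes_u <- genes[keep]
  if (length(genes_u) == 0L) stop("gene list is empty: ", path, call. = FALSE)
  if (ncol(dt) >= 2L) {
    attr(genes_u, "annotation") <- setNames(as.character(dt[[2L]][keep]), genes_u)
  }
  genes_u
}

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, fields tab-separated -- name,
#' description, then member symbols.
#'
#' @param path Path to a GMT file.
#' @return Named list of uppercased symbol vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line (fewer than 3 fields)",
                             call. = FALSE)
    unique(toupper(trimws(f[-(1:2)])))
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Keep genes expressed in more than a fraction of samples
#'
#' A gene is retained when the fraction of samples with expression above
#' `min_tpm` is strictly greater than `min_fraction` (so with the default
#' 0.7, a gene expressed in exactly 70% of samples is removed).
#'
#' @param m Expression matrix, genes x samples.
#' @param min_fraction Required expressed fraction, in `[0, 1)`. Default 0.7.
#' @param min_tpm Detection threshold: "expressed" means value strictly
#'   greater than this. Default 0.
#' @return The filtered expression matrix (same samples).
#' @export
filter_expressed_genes <- function(m, min_fraction = 0.7, min_tpm = 0) {
  validate_expression(m)
  if (min_fraction < 0 || min_fraction >= 1) {
    stop("`min_fraction` must be in [0, 1)", call. = FALSE)
  }
  frac <- rowMeans(m > min_tpm)
  keep <- frac > min_fraction
  if (!any(keep)) {
    stop(sprintf(paste0("no gene is expressed in more than %.0f%% of samples; ",
                        "review `min_fraction`/`min_tpm`"), 100 * min_fraction),
         call. = FALSE)
  }
  m[keep, , drop = FALSE]
}

#' Restrict expression and mutation matrices to shared samples
#'
#' Both matrices are subset to the intersection of their sample identifiers,
#' in the order the samples appear in the expression matrix.
#'
#' @param e Expression matrix.
#' @param m Mutation matrix.
#' @return List with elements `expression` and `mutation`, sample-aligned.
#' @export
align_samples <- function(e, m) {
  validate_expression(e, "expression matrix")
  validate_mutation(m, "mutation matrix")
  common <- intersect(colnames(e), colnames(m))
  if (length(common) == 0L) {
    stop("expression and mutation matrices share no samples", call. = FALSE)
  }
  message(sprintf("aligned on %d shared sample(s)", length(common)))
  list(expression = e[, common, drop = FALSE],
       mutation = m[, common, drop = FALSE])
}
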