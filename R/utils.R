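# Internal helpers: deterministic seed streams and validation.

# Derive a 32-bit sub-seed from a master seed and a path of labels.
# Separate named streams keep, e.g., mutation draws unchanged when the
# number of pairs changes. Arithmetic stays below 2^53 so it is exact in
# doubles; the modulus is the Mersenne prime 2^31 - 1.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 17
  if (nzchar(labels)) {
    for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(((abs(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

stop_if_not_matrix <- function(x, arg) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(arg, " must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers in ", arg, call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifiers in ", arg, call. = FALSE)
  }
  invisible(x)
}

# Expression matrices: finite, non-negative TPM-scale values.
validate_expression <- function(x, arg = "expression matrix") {
  stop_if_not_matrix(x, arg)
  if (any(!is.finite(x))) stop("non-finite values in ", arg, call. = FALSE)
  if (any(x < 0)) stop("negative values in ", arg, call. = FALSE)
  invisible(x)
}

# Mutation matrices: binary status, 1 = mutated.
validate_mutation <- function(x, arg = "mutation matrix") {
  stop_if_not_matrix(x, arg)
  if (any(!is.finite(x)) || any(!(x %in% c(0, 1)))) {
    stop("entries of ", arg, " must all be 0 or 1", call. = FALSE)
  }
  invisible(x)
}
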