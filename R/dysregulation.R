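# Step 1 of the screen: per-pair Mahalanobis distances and iterated Grubbs
# outlier detection over samples.

#' Per-sample Mahalanobis distances for one ligand-receptor pair
#'
#' Each sample's two-gene expression vector \eqn{E_m = (e_{im}, e_{jm})} is
#' scored by its Mahalanobis distance to the cohort mean \eqn{\mu},
#' \deqn{d_m = \sqrt{(E_m - \mu)^T S^{-1} (E_m - \mu)},}
#' with \eqn{S} the unbiased (n-1 divisor) sample covariance. The rooted
#' distance is the default because the downstream Grubbs screen assumes
#' approximate normality of the scored values and rooted distances are
#' closer to normal than squared ones; `squared = TRUE` returns the raw
#' quadratic form instead.
#'
#' Pairs whose covariance is (near-)singular -- determinant below
#' `det_tol * (trace(S)/2)^2` -- are not testable; the returned object then
#' has `testable = FALSE` and carries the determinant.
#'
#' @param x Numeric 2 x n matrix: two gene rows (ligand, receptor), sample
#'   columns. At least 3 samples.
#' @param squared Return the squared distance (the raw quadratic form)?
#'   Default `FALSE`.
#' @param det_tol Relative singularity tolerance on `det(S)`. Default 1e-12.
#' @return List with elements `pair` (rownames of `x`), `sample_ids`, `d`
#'   (named distance vector), `mu`, `S`, `testable`, and, when not testable,
#'   `reason` and `determinant`.
#' @export
mahalanobis_pair_distances <- function(x, squared = FALSE, det_tol = 1e-12) {
  if (!is.matrix(x) || nrow(x) != 2L) {
    stop("`x` must be a 2 x n matrix (one ligand row, one receptor row)",
         call. = FALSE)
  }
  n <- ncol(x)
  if (n < 3L) stop("at least 3 samples are required", call. = FALSE)
  mu <- rowMeans(x)
  S <- cov(t(x))
  detS <- S[1L, 1L] * S[2L, 2L] - S[1L, 2L] * S[2L, 1L]
  scale2 <- ((S[1L, 1L] + S[2L, 2L]) / 2)^2
  out <- list(pair = rownames(x), sample_ids = colnames(x), mu = mu, S = S,
              testable = TRUE)
  if (!is.finite(detS) || detS <= det_tol * max(scale2, .Machine$double.xmin)) {
    out$testable <- FALSE
    out$reason <- "singular covariance"
    out$determinant <- detS
    return(out)
  }
  d2 <- mahalanobis(t(x), mu, S)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  d <- if (squared) d2 else sqrt(d2)
  out$d <- setNames(as.numeric(d), colnames(x))
  out$squared <- squared
  out
}

#' Grubbs critical value
#'
#' One-sided (maximum) critical value
#' \deqn{G_{crit}(n, \alpha) = \frac{n-1}{\sqrt n}
#'   \sqrt{\frac{t^2}{n - 2 + t^2}}}
#' with \eqn{t} the upper \eqn{\alpha/n} critical value of Student's t with
#' \eqn{n - 2} degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return Numeric critical value.
#' @export
grubbs_critical <- function(n, alpha) {
  t <- qt(alpha / n, df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterated one-sided Grubbs outlier screen
#'
#' Repeatedly tests the largest remaining value: the Grubbs statistic
#' \eqn{G = (\max d_m - \bar d) / s} is compared to [grubbs_critical()]; if
#' significant, the maximal sample is flagged, removed, and the test is
#' repeated on the remainder. Only unusually *large* values are flagged
#' (large distances indicate dysregulation). Iteration stops at the first
#' non-significant step, when fewer than 3 values remain, or when the
#' flagged fraction reaches `max_outlier_fraction` of the original sample
#' count -- a cap that prevents mass removal on heavy-tailed inputs.
#'
#' @param d Numeric vector of distances (length >= 3), optionally named.
#' @param alpha Per-iteration significance level. Default 0.05.
#' @param max_outlier_fraction Cap on the flagged fraction. Default 0.2.
#' @return List with `outlier_indices` (integer positions into `d`, in
#'   flagging order), `trace` (data.frame with one row per iteration: `G`,
#'   `critical`, `flagged_index`, `n`), `alpha` and `degenerate` (`TRUE`
#'   when the first iteration had zero spread).
#' @export
grubbs_outliers <- function(d, alpha = 0.05, max_outlier_fraction = 0.2) {
  if (length(d) < 3L) stop("at least 3 values are required", call. = FALSE)
  if (any(!is.finite(d))) stop("`d` must be finite", call. = FALSE)
  n0 <- length(d)
  max_flag <- floor(max_outlier_fraction * n0)
  remaining <- seq_len(n0)
  flagged <- integer(0)
  trace <- list()
  degenerate <- FALSE
  repeat {
    n <- length(remaining)
    if (n < 3L || length(flagged) >= max_flag) break
    dd <- d[remaining]
    s <- sd(dd)
    if (!is.finite(s) || s <= 0) {
      if (length(flagged) == 0L) degenerate <- TRUE
      break
    }
    i_max <- remaining[which.max(dd)]
    G <- (max(dd) - mean(dd)) / s
    crit <- grubbs_critical(n, alpha)
    if (G > crit) {
      flagged <- c(flagged, i_max)
      trace[[length(trace) + 1L]] <-
        data.frame(G = G, critical = crit, flagged_index = i_max, n = n)
      remaining <- setdiff(remaining, i_max)
    } else {
      trace[[length(trace) + 1L]] <-
        data.frame(G = G, critical = crit, flagged_index = NA_integer_, n = n)
      break
    }
  }
  list(outlier_indices = flagged,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(G = numeric(0), critical = numeric(0),
                    flagged_index = integer(0), n = integer(0)),
       alpha = alpha, degenerate = degenerate)
}

#' Detect dysregulated ligand-receptor interactions per sample
#'
#' For every interaction pair whose two genes are present in the expression
#' matrix, computes [mahalanobis_pair_distances()] and flags outlier samples
#' with [grubbs_outliers()]. Pairs with a missing gene or a singular
#' covariance are skipped with a reason.
#'
#' @param e Expression matrix, genes x samples (>= 3 samples).
#' @param pairs Interaction set data.frame (`ligand`, `receptor`), e.g. from
#'   [read_pairs()].
#' @param alpha Grubbs significance level. Default 0.05.
#' @param max_outlier_fraction Cap on the flagged fraction per pair.
#'   Default 0.2.
#' @param squared Use squared Mahalanobis distances (see
#'   [mahalanobis_pair_distances()]). Default `FALSE`.
#' @param log_transform Apply `log2(x + 1)` to the pair expression before
#'   computing distances. Default `FALSE` (raw TPM scale).
#' @return Object of class `dysregulation_profile`: list with `pairs`
#'   (tested pairs with `pair_id` and flag counts), `sample_ids`, `flags`
#'   (binary pairs x samples matrix, rownames = `pair_id`), `skipped`
#'   (data.frame of untested pairs with reasons) and the parameters used.
#' @export
detect_dysregulation <- function(e, pairs, alpha = 0.05,
                                 max_outlier_fraction = 0.2,
                                 squared = FALSE, log_transform = FALSE) {
  validate_expression(e)
  if (!is.data.frame(pairs) || !all(c("ligand", "receptor") %in% colnames(pairs))) {
    stop("`pairs` must be a data.frame with `ligand` and `receptor` columns",
         call. = FALSE)
  }
  samples <- colnames(e)
  tested <- list(); skipped <- list(); flag_rows <- list()
  for (k in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[k]; rec <- pairs$receptor[k]
    pid <- paste(lig, rec, sep = ":")
    if (!(lig %in% rownames(e)) || !(rec %in% rownames(e))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(ligand = lig, receptor = rec, reason = "gene absent")
      next
    }
    x <- e[c(lig, rec), , drop = FALSE]
    if (log_transform) x <- log2(x + 1)
    md <- mahalanobis_pair_distances(x, squared = squared)
    if (!md$testable) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(ligand = lig, receptor = rec, reason = md$reason)
      next
    }
    gr <- grubbs_outliers(md$d, alpha = alpha,
                          max_outlier_fraction = max_outlier_fraction)
    flags <- numeric(length(samples))
    flags[gr$outlier_indices] <- 1
    flag_rows[[pid]] <- flags
    tested[[length(tested) + 1L]] <-
      data.frame(ligand = lig, receptor = rec, pair_id = pid,
                 n_flagged = length(gr$outlier_indices))
  }
  if (length(tested) == 0L) {
    flags <- matrix(numeric(0), 0L, length(samples),
                    dimnames = list(NULL, samples))
    tested_df <- data.frame(ligand = character(0), receptor = character(0),
                            pair_id = character(0), n_flagged = integer(0))
  } else {
    flags <- do.call(rbind, flag_rows)
    colnames(flags) <- samples
    tested_df <- do.call(rbind, tested)
  }
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(ligand = character(0), receptor = character(0),
               reason = character(0))
  message(sprintf("dysregulation: %d pair(s) tested, %d skipped, %d flag(s) set",
                  nrow(tested_df), nrow(skipped_df), sum(flags)))
  structure(list(pairs = tested_df, sample_ids = samples, flags = flags,
                 skipped = skipped_df, alpha = alpha,
                 max_outlier_fraction = max_outlier_fraction,
                 squared = squared, log_transform = log_transform),
            class = "dysregulation_profile")
}

#' @export
print.dysregulation_profile <- function(x, ...) {
  cat(sprintf("dysregulation profile: %d pair(s) x %d sample(s), %d skipped\n",
              nrow(x$pairs), length(x$sample_ids), nrow(x$skipped)))
  cat(sprintf("  flags set: %d (alpha = %g, max outlier fraction = %g)\n",
              sum(x$flags), x$alpha, x$max_outlier_fraction))
  invisible(x)
}

#' Write a dysregulation profile
#'
#' Writes the binary pairs x samples flag matrix as a tab-separated table
#' (first columns `ligand`, `receptor`) and, optionally, the skipped-pair
#' report.
#'
#' @param profile A `dysregulation_profile`.
#' @param path Output path for the flag matrix.
#' @param skipped_path Optional output path for the skipped-pair report.
#' @export
write_dysregulation_profile <- function(profile, path, skipped_path = NULL) {
  stopifnot(inherits(profile, "dysregulation_profile"))
  out <- cbind(profile$pairs[, c("ligand", "receptor")],
               as.data.frame(profile$flags, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(skipped_path)) {
    utils::write.table(profile$skipped, skipped_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
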