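# Count normalization (FPKM / TPM / RPM), stage contrasts with categorical
# fold bins, expression correlation, and qPCR comparative-Ct ratios.

#' Construct a count matrix container
#'
#' Bundles an integer count matrix with its feature and sample annotations.
#' Samples are named `<stage>_<replicate>`; `library_size` defaults to the
#' column sums and must be at least the column sum of assigned counts.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param features `data.frame` with columns `id`, `biotype`, `length`
#'   (bp), rows matching `rownames(counts)`.
#' @param samples `data.frame` with columns `sample`, `stage`, `replicate`,
#'   rows matching `colnames(counts)`.
#' @param library_size Optional named vector of per-sample library sizes.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, features, samples, library_size = NULL) {
  stopifnot(is.matrix(counts), nrow(features) == nrow(counts),
            nrow(samples) == ncol(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(library_size)) library_size <- colSums(counts)
  if (any(library_size < colSums(counts) - 1e-8)) {
    stop("library_size must be >= the column sums of assigned counts",
         call. = FALSE)
  }
  rownames(counts) <- features$id
  colnames(counts) <- samples$sample
  structure(list(counts = counts, features = features, samples = samples,
                 library_size = setNames(as.numeric(library_size),
                                         samples$sample)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$features$biotype), collapse = ", ")))
  invisible(x)
}

#' Subset a count matrix by biotype
#'
#' @param cm A `count_matrix`.
#' @param biotypes Character vector of biotypes to keep.
#' @param recompute_library Recompute library sizes from the retained rows
#'   (default `FALSE`: the original per-sample totals are kept, which is the
#'   convention for per-million normalization of a biotype slice).
#' @return A `count_matrix` restricted to the matching features.
#' @export
subset_biotype <- function(cm, biotypes, recompute_library = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- cm$features$biotype %in% biotypes
  lib <- if (recompute_library) NULL else cm$library_size
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$features[keep, , drop = FALSE],
               cm$samples, lib)
}

#' Normalize a count matrix
#'
#' Implements the three per-million conventions used for the different RNA
#' biotypes: FPKM = c * 1e9 / (N * L) for length-normalized mRNA/lncRNA
#' expression, TPM = (c/L) / sum(c/L) * 1e6 (columns sum to one million),
#' and RPM = j * 1e6 / N for circRNA back-splice junction reads, where c is
#' the count, j the junction count, L the feature length in bp and N the
#' per-sample library size.
#'
#' @param cm A `count_matrix`.
#' @param method One of `"FPKM"`, `"TPM"`, `"RPM"`.
#' @return A numeric matrix of normalized values with a `method` attribute.
#' @export
normalize_counts <- function(cm, method = c("FPKM", "TPM", "RPM")) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  counts <- cm$counts
  N <- cm$library_size
  if (any(N <= 0)) stop("zero library size", call. = FALSE)
  L <- cm$features$length
  out <- switch(method,
    FPKM = {
      if (any(L < 1)) stop("feature lengths must be >= 1 bp for FPKM", call. = FALSE)
      sweep(counts * 1e9 / L, 2, N, "/")
    },
    TPM = {
      if (any(L < 1)) stop("feature lengths must be >= 1 bp for TPM", call. = FALSE)
      rate <- counts / L
      denom <- colSums(rate)
      if (any(denom == 0)) stop("zero total rate in at least one sample (TPM undefined)",
                                call. = FALSE)
      sweep(rate, 2, denom, "/") * 1e6
    },
    RPM = sweep(counts * 1e6, 2, N, "/")
  )
  attr(out, "method") <- method
  out
}

#' Per-stage mean expression
#'
#' @param normalized Normalized matrix (features x samples).
#' @param samples Sample table with `sample` and `stage` columns.
#' @param stage_order Optional stage ordering for the output columns.
#' @return Matrix features x stages of replicate means.
#' @export
stage_means <- function(normalized, samples, stage_order = NULL) {
  stopifnot(all(colnames(normalized) == samples$sample))
  stages <- if (is.null(stage_order)) unique(samples$stage) else stage_order
  out <- vapply(stages, function(s) {
    rowMeans(normalized[, samples$stage == s, drop = FALSE])
  }, numeric(nrow(normalized)))
  rownames(out) <- rownames(normalized)
  out
}

#' Fold-change bin from a log2 fold change
#'
#' The categorical bins used to color regulatory networks: bin A for linear
#' fold in (1, 2], B in (2, 5], C in (5, 10], D above 10 (upper bounds
#' inclusive), applied to the linear fold magnitude `2^|log2fc|`; `none`
#' when the fold is exactly 1.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Character vector over `{"A","B","C","D","none"}`.
#' @export
fold_bin <- function(log2fc) {
  fold <- 2^abs(log2fc)
  out <- rep("none", length(log2fc))
  out[fold > 1 & fold <= 2] <- "A"
  out[fold > 2 & fold <= 5] <- "B"
  out[fold > 5 & fold <= 10] <- "C"
  out[fold > 10] <- "D"
  out
}

#' Stage contrast with log2 fold changes and fold bins
#'
#' log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)) with stage
#' means taken over replicates; the contrast label is `"a/b"`. Direction is
#' the sign of log2fc and the fold bin follows [fold_bin()].
#'
#' @param normalized Normalized matrix (features x samples).
#' @param samples Sample table with `sample` and `stage` columns.
#' @param stage_a,stage_b Stage labels (numerator and denominator).
#' @param pseudocount Stabilizing pseudocount added to both means
#'   (default 1).
#' @return `data.frame` with columns `feature`, `contrast`, `log2fc`,
#'   `direction`, `fold_bin`.
#' @export
contrast_stages <- function(normalized, samples, stage_a, stage_b,
                            pseudocount = 1) {
  for (s in c(stage_a, stage_b)) {
    if (!s %in% samples$stage) {
      stop(sprintf("unknown stage label '%s'", s), call. = FALSE)
    }
  }
  ma <- rowMeans(normalized[, samples$stage == stage_a, drop = FALSE])
  mb <- rowMeans(normalized[, samples$stage == stage_b, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  data.frame(
    feature = rownames(normalized),
    contrast = paste0(stage_a, "/", stage_b),
    log2fc = lfc,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
    fold_bin = fold_bin(lfc),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Pearson correlation of two expression profiles
#'
#' Standard product-moment correlation over per-stage means. Profiles with
#' zero variance have an undefined correlation and return `NA` with a
#' warning; downstream filters treat `NA` as non-correlated.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Relative expression by the comparative Ct method
#'
#' 2^(-ddCt) with ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator); the reference gene (e.g. 18S
#' rRNA) normalizes loading and the calibrator sample sets the unit.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample of
#'   interest for the target and reference gene.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator sample.
#' @return Relative expression ratio (1 when sample equals calibrator).
#' @export
ddct_ratio <- function(ct_target_sample, ct_ref_sample,
                       ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
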