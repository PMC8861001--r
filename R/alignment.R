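# Homology screening: exact Smith-Waterman local alignment with affine gaps
# (BLOSUM62, gap open 11 / extend 1 -- the classic BLASTP defaults) and
# Karlin-Altschul E-values applied to the local score.

#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman local alignment under affine gap costs (a gap of
#' length L costs `gap_open + L * gap_extend`). Identity is computed over the
#' aligned columns with gap columns counted in the denominator. When no
#' positive-scoring segment exists the score is 0 and the spans are empty.
#'
#' @param query,subject Protein sequences (strings over the 20-letter
#'   amino-acid alphabet).
#' @param substitution_matrix Substitution matrix (default BLOSUM62 as
#'   shipped with Biostrings).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1).
#' @return A list of class `alignment_result` with elements `score`,
#'   `identity`, `aligned_length`, `query_span`, `subject_span` (1-based
#'   inclusive `c(start, end)`, `integer(0)` when empty) and the two aligned
#'   strings.
#' @examples
#' smith_waterman("MKSLR", "MKSLR")$identity
#' @export
smith_waterman <- function(query, subject, substitution_matrix = NULL,
                           gap_open = 11, gap_extend = 1) {
  query <- check_protein_sequence(query, "query")
  subject <- check_protein_sequence(subject, "subject")
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()

  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(aln)
  if (s <= 0) {
    out <- list(score = 0, identity = NA_real_, aligned_length = 0L,
                query_span = integer(0), subject_span = integer(0),
                query_aligned = "", subject_aligned = "")
    class(out) <- "alignment_result"
    return(out)
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pa, "", fixed = TRUE)[[1]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1]]
  ncol_aln <- length(pc)
  ident <- sum(pc == sc & pc != "-") / ncol_aln

  qr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  out <- list(
    score = s,
    identity = ident,
    aligned_length = ncol_aln,
    query_span = c(Biostrings::start(qr), Biostrings::end(qr)),
    subject_span = c(Biostrings::start(sr), Biostrings::end(sr)),
    query_aligned = pa,
    subject_aligned = sa
  )
  class(out) <- "alignment_result"
  out
}

#' Karlin-Altschul E-value
#'
#' E = K * m * n * exp(-lambda * S) for a local alignment score S against a
#' search space of effective lengths m (query) and n (database). The default
#' parameters are the classic ungapped BLOSUM62 values (lambda = 0.3176,
#' K = 0.134), applied here to the Smith-Waterman score as a documented
#' approximation of a BLASTP-style significance estimate.
#'
#' @param score Alignment score (may be a vector).
#' @param m,n Effective query and database lengths (positive).
#' @param lambda,K Karlin-Altschul parameters (positive).
#' @return E-value(s), strictly decreasing in `score`.
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  check_scalar_number(lambda, "lambda")
  check_scalar_number(K, "K")
  if (lambda <= 0) stop_config("lambda", "must be > 0")
  if (K <= 0) stop_config("K", "must be > 0")
  check_scalar_number(m, "m", min = 1)
  check_scalar_number(n, "n", min = 1)
  K * m * n * exp(-lambda * score)
}

#' Screen query proteins against a homology reference set
#'
#' For each query, the best-scoring local alignment against the reference
#' set is computed; queries are retained when that hit reaches both
#' thresholds: aligned-column identity >= `identity_min` (inclusive) and
#' E-value < `evalue_max` (strict). The E-value search space is the query
#' length times the summed reference length.
#'
#' @param queries,references `data.frame`s with columns `id` and `sequence`
#'   (or named character vectors).
#' @param identity_min Minimum identity over aligned columns (default 0.80,
#'   inclusive).
#' @param evalue_max E-value cutoff (default 1e-5, exclusive).
#' @param lambda,K Karlin-Altschul parameters passed to [karlin_evalue()].
#' @return `data.frame` with one row per query: `id`, `best_ref`, `score`,
#'   `identity`, `evalue`, `retained`. The retained subset carries the
#'   passing hit; the full table supports auditing the screen.
#' @export
screen_candidates <- function(queries, references, identity_min = 0.80,
                              evalue_max = 1e-5, lambda = 0.3176, K = 0.134) {
  queries <- as_seq_frame(queries, "queries")
  references <- as_seq_frame(references, "references")
  if (nrow(references) == 0L) {
    stop_config("references", "must contain at least one sequence")
  }
  check_scalar_number(identity_min, "identity_min", min = 0, max = 1)
  check_scalar_number(evalue_max, "evalue_max", min = 0)
  n_db <- sum(nchar(references$sequence))
  subst <- blosum62()

  rows <- lapply(seq_len(nrow(queries)), function(i) {
    best <- NULL
    best_ref <- NA_character_
    for (j in seq_len(nrow(references))) {
      a <- smith_waterman(queries$sequence[i], references$sequence[j],
                          substitution_matrix = subst)
      if (is.null(best) || a$score > best$score) {
        best <- a
        best_ref <- references$id[j]
      }
    }
    ev <- karlin_evalue(best$score, m = nchar(queries$sequence[i]), n = n_db,
                        lambda = lambda, K = K)
    data.frame(id = queries$id[i], best_ref = best_ref, score = best$score,
               identity = best$identity, evalue = ev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$retained <- !is.na(out$identity) &
    out$identity >= identity_min & out$evalue < evalue_max
  out
}

#' @noRd
as_seq_frame <- function(x, what) {
  if (is.character(x)) {
    if (is.null(names(x))) {
      stop(sprintf("%s must be a named character vector or a data.frame", what),
           call. = FALSE)
    }
    return(data.frame(id = names(x), sequence = unname(x),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  x[, c("id", "sequence"), drop = FALSE]
}
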