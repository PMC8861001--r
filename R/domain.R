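# SBP-domain scanning with an ungapped position-specific score matrix, and
# splice-isoform deduplication. A full-length domain hit is the family
# membership criterion: candidates whose best hit is truncated by a sequence
# end are rejected.

#' SBP-domain position-specific score matrix
#'
#' Builds an ungapped log-odds profile of fixed width from a consensus
#' sequence: column j of the profile is the BLOSUM62 substitution row of the
#' consensus residue at position j. The bundled consensus is a synthetic
#' SBP-like domain (76 aa) shipped under `extdata`; any consensus string can
#' be supplied instead.
#'
#' @param consensus Optional consensus string; when `NULL` the bundled
#'   synthetic SBP consensus is used.
#' @return A list of class `domain_profile` with elements `matrix` (width x
#'   20 score matrix, rows = profile columns, columns = residues),
#'   `consensus` and `width`.
#' @export
sbp_profile <- function(consensus = NULL) {
  if (is.null(consensus)) {
    path <- system.file("extdata", "sbp_domain_consensus_synthetic.txt",
                        package = "splnet", mustWork = TRUE)
    lines <- readLines(path)
    consensus <- lines[!grepl("^#", lines) & nzchar(lines)][1L]
  }
  consensus <- check_protein_sequence(consensus, "profile consensus")
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  b62 <- blosum62()[AA_ALPHABET, AA_ALPHABET]
  mat <- b62[chars, , drop = FALSE]
  rownames(mat) <- NULL
  out <- list(matrix = mat, consensus = consensus, width = length(chars))
  class(out) <- "domain_profile"
  out
}

#' Scan a protein for the best domain hit
#'
#' Slides the profile along the protein and scores every ungapped window:
#' all full-width windows, plus partial windows at the two sequence ends
#' (domain truncated by the N- or C-terminus, at least `min_partial`
#' columns). The best-scoring window is returned; `full_length` is `TRUE`
#' iff it covers all profile columns without truncation by a sequence end.
#' Proteins shorter than the profile width can never yield a full-length
#' hit.
#'
#' @param protein Amino-acid sequence.
#' @param profile A `domain_profile` from [sbp_profile()].
#' @param score_min Minimum score for a hit to be reported (default 0, the
#'   natural cutoff for a log-odds profile).
#' @param min_partial Minimum number of profile columns for a truncated
#'   terminal window (default 10).
#' @return A list of class `domain_hit` with `start`, `end` (1-based
#'   inclusive on the protein), `profile_score` and `full_length`, or `NULL`
#'   if no window reaches `score_min`.
#' @export
scan_domain <- function(protein, profile, score_min = 0, min_partial = 10L) {
  protein <- check_protein_sequence(protein, "protein")
  stopifnot(inherits(profile, "domain_profile"))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(chars)
  W <- profile$width
  pm <- profile$matrix
  idx <- match(chars, AA_ALPHABET)

  best <- NULL
  consider <- function(start, end, score, full) {
    if (is.null(best) || score > best$profile_score ||
        (score == best$profile_score && start < best$start)) {
      best <<- list(start = start, end = end, profile_score = score,
                    full_length = full)
    }
  }

  if (L >= W) {
    for (s in seq_len(L - W + 1L)) {
      sc <- sum(pm[cbind(seq_len(W), idx[s:(s + W - 1L)])])
      consider(s, s + W - 1L, sc, TRUE)
    }
  }
  # Domain cut off by the N-terminus: protein prefix matches a profile suffix.
  kmax <- min(L, W - 1L)
  if (kmax >= min_partial) {
    for (k in min_partial:kmax) {
      sc <- sum(pm[cbind((W - k + 1L):W, idx[seq_len(k)])])
      consider(1L, k, sc, FALSE)
    }
    # Domain cut off by the C-terminus: protein suffix matches a profile prefix.
    for (k in min_partial:kmax) {
      sc <- sum(pm[cbind(seq_len(k), idx[(L - k + 1L):L])])
      consider(L - k + 1L, L, sc, FALSE)
    }
  }

  if (is.null(best) || best$profile_score < score_min) return(NULL)
  class(best) <- "domain_hit"
  best
}

#' Deduplicate splice isoforms to one canonical record per locus
#'
#' Alternative-splicing products of the same locus are redundant for
#' family-level analyses; the longest isoform is kept, with ties broken by
#' the lexicographically smallest identifier.
#'
#' @param candidates `data.frame` with columns `id`, `locus` and either
#'   `sequence` or `length`.
#' @return A list with `canonical` (one row per locus) and `discarded`
#'   (the removed rows with a `reason` column).
#' @export
deduplicate_isoforms <- function(candidates) {
  stopifnot(is.data.frame(candidates), all(c("id", "locus") %in% names(candidates)))
  if (any(is.na(candidates$locus) | !nzchar(candidates$locus))) {
    stop("every candidate must carry a locus id", call. = FALSE)
  }
  len <- if ("length" %in% names(candidates)) {
    candidates$length
  } else if ("sequence" %in% names(candidates)) {
    nchar(candidates$sequence)
  } else {
    stop("candidates need a 'sequence' or 'length' column", call. = FALSE)
  }
  ord <- order(candidates$locus, -len, candidates$id)
  sorted <- candidates[ord, , drop = FALSE]
  keep <- !duplicated(sorted$locus)
  canonical <- sorted[keep, , drop = FALSE]
  discarded <- sorted[!keep, , drop = FALSE]
  if (nrow(discarded) > 0L) {
    discarded$reason <- sprintf(
      "redundant splice isoform of locus %s (canonical: %s)",
      discarded$locus,
      canonical$id[match(discarded$locus, canonical$locus)]
    )
  } else {
    discarded$reason <- character(0)
  }
  rownames(canonical) <- NULL
  rownames(discarded) <- NULL
  list(canonical = canonical, discarded = discarded)
}

#' Identify SPL family members in a protein set
#'
#' Chains the three family-identification gates: homology screen against a
#' reference set ([screen_candidates()]), full-length SBP-domain scan
#' ([scan_domain()]), and splice-isoform deduplication
#' ([deduplicate_isoforms()]).
#'
#' @param proteins `data.frame` with columns `id`, `locus`, `sequence`.
#' @param references Reference SPL protein set (`data.frame` with `id`,
#'   `sequence`).
#' @param profile Domain profile (default [sbp_profile()]).
#' @param identity_min,evalue_max Screen thresholds (defaults 0.80 and 1e-5).
#' @param score_min Domain-scan score cutoff (default 0).
#' @return A list with `screen` (full screen table), `domain` (per-candidate
#'   hit table), `canonical` (final SPL set, one per locus) and `discarded`
#'   (redundant isoforms).
#' @export
identify_spl <- function(proteins, references, profile = sbp_profile(),
                         identity_min = 0.80, evalue_max = 1e-5,
                         score_min = 0) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "locus", "sequence") %in% names(proteins)))
  screen <- screen_candidates(proteins, references,
                              identity_min = identity_min,
                              evalue_max = evalue_max)
  passed <- proteins[proteins$id %in% screen$id[screen$retained], , drop = FALSE]

  hits <- lapply(seq_len(nrow(passed)), function(i) {
    h <- scan_domain(passed$sequence[i], profile, score_min = score_min)
    data.frame(
      id = passed$id[i],
      domain_start = if (is.null(h)) NA_integer_ else h$start,
      domain_end = if (is.null(h)) NA_integer_ else h$end,
      profile_score = if (is.null(h)) NA_real_ else h$profile_score,
      full_length = if (is.null(h)) FALSE else h$full_length,
      stringsAsFactors = FALSE
    )
  })
  domain <- do.call(rbind, hits)
  if (is.null(domain)) {
    domain <- data.frame(id = character(0), domain_start = integer(0),
                         domain_end = integer(0), profile_score = numeric(0),
                         full_length = logical(0))
  }

  with_domain <- passed[passed$id %in% domain$id[domain$full_length], , drop = FALSE]
  dedup <- deduplicate_isoforms(with_domain)
  canonical <- merge(dedup$canonical, domain, by = "id", sort = TRUE)
  list(screen = screen, domain = domain, canonical = canonical,
       discarded = dedup$discarded)
}

#' Extract the aligned domain windows of identified SPL proteins
#'
#' Because every full-length hit covers the same profile columns, the
#' extracted windows are mutually aligned by construction and can feed the
#' phylogeny stage directly.
#'
#' @param canonical The `canonical` table from [identify_spl()] (needs
#'   `id`, `sequence`, `domain_start`, `domain_end`).
#' @return Named character vector of equal-length domain sequences.
#' @export
domain_alignment <- function(canonical) {
  stopifnot(all(c("id", "sequence", "domain_start", "domain_end") %in%
                  names(canonical)))
  out <- substr(canonical$sequence, canonical$domain_start, canonical$domain_end)
  names(out) <- canonical$id
  out
}
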