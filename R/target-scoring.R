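# miR156 target-site prediction by penalty-scored duplex alignment, with
# back-splice junction handling for circRNAs.

#' Penalty scheme for miRNA target scoring
#'
#' The scoring convention for plant miRNA target prediction used throughout
#' the package: each mismatch costs 1, each G:U wobble 0.5, each gap 2, and
#' penalties are doubled when the miRNA position (1-based from the 5' end)
#' falls in the seed range 2-13. Sites are called at a total penalty at or
#' below `cutoff` with at most `max_gaps` gaps. All values are configurable;
#' these defaults are this package's bundled convention.
#'
#' @param mismatch,gu_wobble,gap Per-event penalties (non-negative).
#' @param seed_multiplier Multiplier applied inside the seed range.
#' @param seed_start,seed_end Seed range in miRNA coordinates.
#' @param cutoff Maximum total penalty for a reported site.
#' @param max_gaps Maximum number of gaps in the duplex.
#' @return A list of class `penalty_scheme`.
#' @export
penalty_scheme <- function(mismatch = 1, gu_wobble = 0.5, gap = 2,
                           seed_multiplier = 2, seed_start = 2L,
                           seed_end = 13L, cutoff = 3, max_gaps = 1L) {
  for (f in c("mismatch", "gu_wobble", "gap", "seed_multiplier", "cutoff")) {
    check_scalar_number(get(f), f, min = 0)
  }
  if (seed_start < 1L || seed_end < seed_start) {
    stop_config("seed_range", "must satisfy 1 <= seed_start <= seed_end")
  }
  if (max_gaps < 0L) stop_config("max_gaps", "must be >= 0")
  structure(list(mismatch = mismatch, gu_wobble = gu_wobble, gap = gap,
                 seed_multiplier = seed_multiplier,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 cutoff = cutoff, max_gaps = as.integer(max_gaps)),
            class = "penalty_scheme")
}

#' Penalty score of one miRNA/target-window duplex
#'
#' Minimum total penalty over alignments of the miRNA (5'->3') against the
#' reverse-complement sense of the window with at most `max_gaps` gaps,
#' found by dynamic programming. The window length must lie within
#' `max_gaps` of the miRNA length. The returned duplex shows the miRNA
#' 5'->3' over the target site 3'->5', so paired bases sit in the same
#' column.
#'
#' @param mirna miRNA sequence, 5'->3' (T and U are equivalent).
#' @param window Target subsequence (sense strand, 5'->3').
#' @param scheme A [penalty_scheme()].
#' @return List with `score`, `mirna_aligned`, `target_aligned`.
#' @examples
#' s <- penalty_scheme()
#' duplex_penalty("ACGUACGUACGUACGUACGUA",
#'                revcomp_rna("ACGUACGUACGUACGUACGUA"), s)$score  # 0
#' @export
duplex_penalty <- function(mirna, window, scheme = penalty_scheme()) {
  stopifnot(inherits(scheme, "penalty_scheme"))
  mi <- encode_nt(mirna)
  wi <- encode_nt(window)
  m <- length(mi)
  if (length(wi) < m - scheme$max_gaps || length(wi) > m + scheme$max_gaps) {
    stop(sprintf(
      "window length %d outside [%d, %d] for a %d-nt miRNA with <= %d gaps",
      length(wi), m - scheme$max_gaps, m + scheme$max_gaps, m,
      scheme$max_gaps), call. = FALSE)
  }
  duplex_dp_cpp(mi, wi, scheme$mismatch, scheme$gu_wobble, scheme$gap,
                scheme$seed_multiplier, scheme$seed_start, scheme$seed_end,
                scheme$max_gaps, TRUE)
}

#' Reverse complement (DNA alphabet, U treated as T)
#'
#' @param seq Nucleotide sequence.
#' @return Reverse complement as a DNA string.
#' @export
revcomp_rna <- function(seq) {
  revcomp(seq)
}

#' Find miRNA target sites on a transcript
#'
#' Scores every window whose length is within `max_gaps` of the miRNA
#' length and reports all sites with penalty at or below the scheme cutoff.
#' Overlapping calls for the same miRNA are resolved to the lowest-score
#' site, ties going to the leftmost start.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcript Target transcript sequence (sense strand).
#' @param scheme A [penalty_scheme()].
#' @param mirna_id,target_id Identifiers copied to the output.
#' @param keep_overlaps Keep all passing windows without overlap resolution
#'   (used for exhaustive auditing; default `FALSE`).
#' @return `data.frame` with columns `mirna_id`, `target_id`, `start`,
#'   `end` (1-based inclusive), `score`, `spans_junction` (always `FALSE`
#'   here), sorted by `start`.
#' @export
find_sites <- function(mirna, transcript, scheme = penalty_scheme(),
                       mirna_id = "miRNA", target_id = "target",
                       keep_overlaps = FALSE) {
  stopifnot(inherits(scheme, "penalty_scheme"))
  mi <- encode_nt(mirna)
  ti <- encode_nt(transcript)
  if (length(ti) < length(mi) - scheme$max_gaps) {
    stop("transcript shorter than the minimum site length", call. = FALSE)
  }
  hits <- duplex_scan_cpp(mi, ti, scheme$mismatch, scheme$gu_wobble,
                          scheme$gap, scheme$seed_multiplier,
                          scheme$seed_start, scheme$seed_end,
                          scheme$max_gaps, scheme$cutoff)
  hits <- as.data.frame(hits)
  if (nrow(hits) > 0L && !keep_overlaps) {
    hits <- resolve_overlaps(hits)
  }
  out <- data.frame(
    mirna_id = rep(mirna_id, nrow(hits)),
    target_id = rep(target_id, nrow(hits)),
    start = hits$start, end = hits$end, score = hits$score,
    spans_junction = rep(FALSE, nrow(hits)),
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

# Greedy resolution: best (lowest score, then leftmost) site wins; any
# window overlapping an accepted site is dropped.
#' @noRd
resolve_overlaps <- function(hits) {
  ord <- order(hits$score, hits$start, hits$end)
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(0)
  ks <- integer(0); ke <- integer(0)
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    s <- hits$start[k]; e <- hits$end[k]
    if (!any(s <= ke & e >= ks)) {
      keep[k] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Back-splice junction pseudo-sequence of a circRNA
#'
#' The junction context of a circRNA in linear representation: the last
#' `flank` bases followed by the first `flank` bases, plus a map from
#' pseudo-coordinates back to circular coordinates. Sites found on this
#' pseudo-sequence span the back-splice junction.
#'
#' @param sequence circRNA sequence in linear representation (the circle
#'   closes between the last and first base).
#' @param flank Number of bases taken from each side of the junction
#'   (default: miRNA length - 1 = 20).
#' @return List with `sequence` (the pseudo-sequence) and `map` (integer
#'   vector: `map[p]` is the circular coordinate of pseudo-position `p`).
#' @export
circ_junction_sequence <- function(sequence, flank = 20L) {
  seq <- as_dna(sequence)
  L <- nchar(seq)
  if (flank >= L) {
    stop(sprintf("flank (%d) must be smaller than the circle length (%d)",
                 flank, L), call. = FALSE)
  }
  pseudo <- paste0(substr(seq, L - flank + 1L, L), substr(seq, 1L, flank))
  map <- c((L - flank + 1L):L, 1L:flank)
  list(sequence = pseudo, map = map)
}

#' Predict the miRNA targetome over a transcript set
#'
#' Runs [find_sites()] for every (miRNA, transcript) pair. circRNAs are
#' scanned both on their linear sequence and on the back-splice junction
#' pseudo-sequence; junction hits are mapped back to circular coordinates,
#' flagged `spans_junction`, and deduplicated against linear hits by mapped
#' start coordinate.
#'
#' @param mirnas `data.frame` with columns `id`, `sequence`.
#' @param transcripts `data.frame` with columns `id`, `biotype`,
#'   `sequence` (circRNAs are rows with `biotype == "circRNA"`).
#' @param scheme A [penalty_scheme()].
#' @return MRE table: `data.frame` with columns `mirna_id`, `target_id`,
#'   `biotype`, `start`, `end`, `score`, `spans_junction`.
#' @export
predict_targetome <- function(mirnas, transcripts, scheme = penalty_scheme()) {
  stopifnot(is.data.frame(mirnas), is.data.frame(transcripts))
  out <- vector("list", nrow(mirnas) * nrow(transcripts) * 2L)
  k <- 0L
  for (i in seq_len(nrow(mirnas))) {
    mir_len <- nchar(mirnas$sequence[i])
    for (j in seq_len(nrow(transcripts))) {
      sites <- find_sites(mirnas$sequence[i], transcripts$sequence[j], scheme,
                          mirna_id = mirnas$id[i],
                          target_id = transcripts$id[j])
      if (nrow(sites) > 0L) {
        sites$biotype <- transcripts$biotype[j]
        k <- k + 1L
        out[[k]] <- sites
      }
      if (identical(transcripts$biotype[j], "circRNA")) {
        flank <- min(mir_len - 1L + scheme$max_gaps,
                     nchar(transcripts$sequence[j]) - 1L)
        pj <- circ_junction_sequence(transcripts$sequence[j], flank)
        jsites <- find_sites(mirnas$sequence[i], pj$sequence, scheme,
                             mirna_id = mirnas$id[i],
                             target_id = transcripts$id[j])
        if (nrow(jsites) > 0L) {
          # keep only hits that truly cross the junction (the rest are
          # rediscoveries of linear-sequence sites)
          crosses <- jsites$start <= flank & jsites$end > flank
          jsites <- jsites[crosses, , drop = FALSE]
        }
        if (nrow(jsites) > 0L) {
          jsites$spans_junction <- TRUE
          mapped_start <- pj$map[jsites$start]
          mapped_end <- pj$map[jsites$end]
          jsites$start <- mapped_start
          jsites$end <- mapped_end
          jsites$biotype <- "circRNA"
          k <- k + 1L
          out[[k]] <- jsites
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      biotype = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      spans_junction = logical(0)))
  }
  tab <- do.call(rbind, out[seq_len(k)])
  tab <- tab[, c("mirna_id", "target_id", "biotype", "start", "end",
                 "score", "spans_junction")]
  # one site per (miRNA, target, mapped start)
  key <- paste(tab$mirna_id, tab$target_id, tab$start)
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
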