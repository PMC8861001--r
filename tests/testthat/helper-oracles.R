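# Independent reference implementations used as oracles. These deliberately
# take different algorithmic routes than the package code:
#  - local alignment: enumeration of global (Gotoh) scores over all
#    substring start pairs, versus the package's Smith-Waterman;
#  - duplex penalty: explicit enumeration of single-gap placements, versus
#    the package's dynamic program over gap-count states;
#  - domain scan: direct per-window sums.

b62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Best local alignment score as the maximum over all substring start pairs
# of a global affine-gap DP read off at every end cell. A gap of length L
# costs open + L * ext. Returns max(0, best).
oracle_local_score <- function(s1, s2, subst, open = 11, ext = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n1 <- length(a)
  n2 <- length(b)
  best <- 0
  NEG <- -1e9
  for (i1 in seq_len(n1)) {
    for (j1 in seq_len(n2)) {
      la <- n1 - i1 + 1L
      lb <- n2 - j1 + 1L
      M <- matrix(NEG, la + 1L, lb + 1L)
      E <- matrix(NEG, la + 1L, lb + 1L)  # gap in s1 (consumes s2)
      F <- matrix(NEG, la + 1L, lb + 1L)  # gap in s2 (consumes s1)
      M[1, 1] <- 0
      for (j in seq_len(lb)) E[1, j + 1L] <- -open - ext * j
      for (i in seq_len(la)) F[i + 1L, 1] <- -open - ext * i
      for (i in seq_len(la)) {
        for (j in seq_len(lb)) {
          sc <- subst[a[i1 + i - 1L], b[j1 + j - 1L]]
          M[i + 1L, j + 1L] <- max(M[i, j], E[i, j], F[i, j]) + sc
          E[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                   E[i + 1L, j] - ext)
          F[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                   F[i, j + 1L] - ext)
          best <- max(best, M[i + 1L, j + 1L])
        }
      }
    }
  }
  best
}

# Pair penalty in duplex scoring; b is the target base read in sense
# orientation (not complemented).
oracle_pair_pen <- function(a, b, scheme) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, 0, ifelse(gu, scheme$gu_wobble, scheme$mismatch))
}

oracle_seed_wt <- function(pos, m, scheme) {
  pos <- pmin(pos, m)
  ifelse(pos >= scheme$seed_start & pos <= scheme$seed_end,
         scheme$seed_multiplier, 1)
}

# Minimum duplex penalty by enumerating all placements of at most one gap
# (the package default max_gaps = 1).
oracle_duplex_penalty <- function(mirna, window, scheme) {
  stopifnot(scheme$max_gaps == 1L)
  a <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  w <- rev(strsplit(chartr("Uu", "Tt", toupper(window)), "")[[1]])
  m <- length(a)
  n <- length(w)
  wt <- oracle_seed_wt(seq_len(m), m, scheme)
  if (n == m) {
    return(sum(oracle_pair_pen(a, w, scheme) * wt))
  }
  if (n == m - 1L) {
    # one miRNA base g unpaired
    best <- Inf
    for (g in seq_len(m)) {
      keep <- setdiff(seq_len(m), g)
      pen <- sum(oracle_pair_pen(a[keep], w, scheme) * wt[keep]) +
        scheme$gap * wt[g]
      best <- min(best, pen)
    }
    return(best)
  }
  if (n == m + 1L) {
    # one target base g bulged; gap weighted by the next miRNA position
    best <- Inf
    for (g in seq_len(n)) {
      keep <- setdiff(seq_len(n), g)
      pen <- sum(oracle_pair_pen(a, w[keep], scheme) * wt) +
        scheme$gap * oracle_seed_wt(min(g, m), m, scheme)
      best <- min(best, pen)
    }
    return(best)
  }
  stop("window length outside single-gap bounds")
}

# Exhaustive site enumeration over every admissible window of a transcript.
oracle_all_windows <- function(mirna, transcript, scheme) {
  tr <- chartr("Uu", "Tt", toupper(transcript))
  m <- nchar(mirna)
  L <- nchar(tr)
  out <- list()
  for (len in (m - scheme$max_gaps):(m + scheme$max_gaps)) {
    if (len < 1L || len > L) next
    for (s in seq_len(L - len + 1L)) {
      sc <- oracle_duplex_penalty(mirna, substr(tr, s, s + len - 1L), scheme)
      out[[length(out) + 1L]] <- data.frame(start = s, end = s + len - 1L,
                                            score = sc)
    }
  }
  do.call(rbind, out)
}

# Best full-width window sum for a domain profile.
oracle_domain_best <- function(protein, profile) {
  chars <- strsplit(protein, "")[[1]]
  W <- profile$width
  L <- length(chars)
  if (L < W) return(NULL)
  scores <- vapply(seq_len(L - W + 1L), function(s) {
    sum(profile$matrix[cbind(seq_len(W), match(chars[s:(s + W - 1L)],
                                               colnames(profile$matrix)))])
  }, numeric(1))
  list(start = which.max(scores), score = max(scores))
}

random_protein <- function(n) {
  paste(sample(splnet:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# support (in %) of the bipartition separating `side` from the rest
support_of_split <- function(tree, side) {
  ntip <- length(tree$tip.label)
  vals <- numeric(0)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    if (setequal(tips, side) || setequal(tips, setdiff(tree$tip.label, side))) {
      vals <- c(vals, suppressWarnings(as.numeric(tree$node.label[node - ntip])))
    }
  }
  if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
}
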