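# Protein physicochemical profiling: molecular weight, theoretical pI,
# GRAVY, instability index, charged-residue counts.

# Kyte-Doolittle hydropathy values.
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Average (not monoisotopic) masses of the free amino acids, in Daltons.
# Residue mass = free mass - one water; a protein adds one water back.
AA_AVERAGE_MASS <- c(
  A =  89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G =  75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)

WATER_MASS <- 18.0153

# Bjellqvist-style pKa values (the set behind the ExPASy Compute pI tool,
# without the position-specific refinements for terminal D/E/C).
PKA_SIDECHAIN_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
PKA_SIDECHAIN_POS <- c(H = 5.98, K = 10.00, R = 12.00)
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70)
PKA_NTERM_DEFAULT <- 7.50
PKA_CTERM <- 3.55

#' @noRd
diwv_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "diwv_guruprasad.tsv", package = "splnet",
                          mustWork = TRUE)
      tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
      cache <<- as.matrix(tab)
    }
    cache
  }
})

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge over the ionizable side chains
#' (Asp, Glu, Cys, Tyr, His, Lys, Arg) plus the two termini. The charge is a
#' strictly decreasing function of pH, which guarantees a unique isoelectric
#' point.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param ph pH value (may be a vector).
#' @return Net charge (same length as `ph`).
#' @export
protein_charge <- function(sequence, ph) {
  sequence <- check_protein_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  nterm_pka <- PKA_NTERM[chars[1L]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT

  pos_pka <- c(unname(nterm_pka),
               rep(PKA_SIDECHAIN_POS, counts[names(PKA_SIDECHAIN_POS)]))
  neg_pka <- c(PKA_CTERM,
               rep(PKA_SIDECHAIN_NEG, counts[names(PKA_SIDECHAIN_NEG)]))

  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' Bisection on the net-charge curve over pH 0-14; the curve is strictly
#' decreasing so the root is unique. Iterates until the absolute net charge
#' at the midpoint falls below `tol`.
#'
#' @param sequence Amino-acid sequence.
#' @param tol Convergence tolerance on |net charge| (default 1e-6).
#' @return pH at which the net charge is (numerically) zero.
#' @export
isoelectric_point <- function(sequence, tol = 1e-6) {
  lo <- 0
  hi <- 14
  mid <- 7
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- protein_charge(sequence, mid)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physicochemical profile of a protein
#'
#' Computes the ProtParam-style summary used to characterize SPL family
#' members: length, average molecular weight (sum of residue masses plus one
#' water), theoretical pI (bisection on the Henderson-Hasselbalch charge
#' curve), GRAVY (mean Kyte-Doolittle hydropathy), the Guruprasad instability
#' index II = (10/L) * sum over adjacent dipeptides of their instability
#' weight, counts of negatively (Asp+Glu) and positively (Arg+Lys) charged
#' residues, and the derived classes: `unstable` iff II > 40, `acidic` iff
#' pI < 7 (otherwise `alkalescent`).
#'
#' @param sequence Amino-acid sequence (length >= 2 for the instability
#'   index; for a single residue the index is `NA` and the stability class
#'   is `NA`).
#' @return A one-row `data.frame` with columns `length_aa`, `mw_da`, `pi`,
#'   `n_negative`, `n_positive`, `gravy`, `instability_index`,
#'   `stability_class`, `acid_base_class`.
#' @examples
#' physchem_profile("MKSLRWGAL")
#' @export
physchem_profile <- function(sequence) {
  sequence <- check_protein_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)

  mw <- sum(AA_AVERAGE_MASS[chars] - WATER_MASS) + WATER_MASS
  gravy <- mean(KYTE_DOOLITTLE[chars])
  pi_val <- isoelectric_point(sequence)

  if (n >= 2L) {
    dw <- diwv_table()
    ii <- 10 / n * sum(dw[cbind(chars[-n], chars[-1L])])
    stability <- if (ii > 40) "unstable" else "stable"
  } else {
    ii <- NA_real_
    stability <- NA_character_
  }

  data.frame(
    length_aa = n,
    mw_da = mw,
    pi = pi_val,
    n_negative = sum(chars %in% c("D", "E")),
    n_positive = sum(chars %in% c("R", "K")),
    gravy = gravy,
    instability_index = ii,
    stability_class = stability,
    acid_base_class = if (pi_val < 7) "acidic" else "alkalescent",
    stringsAsFactors = FALSE
  )
}

#' Physicochemical table for a protein set
#'
#' Applies [physchem_profile()] to each sequence and binds the results with
#' the protein identifiers, mirroring the per-protein property table reported
#' for gene-family surveys.
#'
#' @param proteins `data.frame` with columns `id` and `sequence`.
#' @return `data.frame` with one row per protein.
#' @export
physchem_table <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    cbind(data.frame(id = proteins$id[i], stringsAsFactors = FALSE),
          physchem_profile(proteins$sequence[i]))
  })
  do.call(rbind, rows)
}
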