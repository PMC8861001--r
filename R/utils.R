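# Shared validation and sequence helpers.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NT_ALPHABET <- c("A", "C", "G", "T", "U")

#' @noRd
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

#' @noRd
check_scalar_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(field, "must be a single non-missing number")
  }
  if (x < min || x > max) {
    stop_config(field, sprintf("must be in [%s, %s]", min, max))
  }
  invisible(x)
}

#' @noRd
check_protein_sequence <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

#' @noRd
check_nt_sequence <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% NT_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

# Canonical DNA representation: U is stored as T throughout the package;
# target scoring treats the two as equivalent.
#' @noRd
as_dna <- function(seq) {
  chartr("Uu", "Tt", toupper(seq))
}

#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_dna(seq))))
}

# Integer encoding used by the C++ duplex scorer: A=0, C=1, G=2, T/U=3.
#' @noRd
encode_nt <- function(seq) {
  chars <- strsplit(as_dna(seq), "", fixed = TRUE)[[1]]
  m <- match(chars, c("A", "C", "G", "T")) - 1L
  if (anyNA(m)) {
    stop(sprintf("invalid nucleotide '%s' in sequence", chars[which(is.na(m))[1L]]),
         call. = FALSE)
  }
  m
}

#' @noRd
random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' @noRd
md5_of_files <- function(paths) {
  sums <- tools::md5sum(paths)
  setNames(unname(sums), basename(paths))
}
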