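## Nucleotide string utilities shared by all modules.
##
## The internal alphabet is DNA: {A, C, G, T}. RNA input is accepted
## everywhere and normalised U -> T at the boundary; `as_rna()` renders a
## sequence back in the RNA spelling.

#' Normalise a nucleotide string to the internal DNA alphabet
#'
#' Uppercases, converts U to T and validates that only A, C, G, T remain.
#' IUPAC ambiguity codes (including N) are rejected: the downstream
#' statistics have no defined behaviour for them.
#'
#' @param x Character vector of nucleotide strings (DNA or RNA spelling).
#' @param what Label used in error messages (e.g. a FASTA record id).
#' @return Character vector over `{A,C,G,T}`.
#' @examples
#' normalize_nt("augGAUC")
#' @export
normalize_nt <- function(x, what = "sequence") {
  if (!is.character(x)) stop("`x` must be a character vector", call. = FALSE)
  out <- chartr("u", "t", tolower(x))
  out <- toupper(out)
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    offending <- gsub("[ACGT]", "", out[bad][1L])
    stop(sprintf(
      "%s %s contains non-ACGT/U character(s): '%s'",
      what, if (is.null(names(x))) which(bad)[1L] else names(x)[bad][1L],
      substr(offending, 1L, 5L)
    ), call. = FALSE)
  }
  out
}

#' Render a DNA-spelled sequence as RNA
#'
#' @param x Character vector over `{A,C,G,T}`.
#' @return The same sequences with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' All rotations of a circular sequence
#'
#' @param x A single nucleotide string.
#' @return Character vector of `nchar(x)` rotations; element `i` starts at
#'   position `i` of `x`.
#' @export
rotations <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  n <- nchar(x)
  if (n == 0L) return(character(0))
  doubled <- paste0(x, x)
  substring(doubled, seq_len(n), seq_len(n) + n - 1L)
}

#' Canonical form of a circular sequence
#'
#' The canonical representative of a rotation-equivalence class is the
#' lexicographically minimal rotation. Canonicalisation is idempotent.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of canonical rotations.
#' @examples
#' canonical_rotation("GAC")  # "ACG"
#' @export
canonical_rotation <- function(x) {
  vapply(x, function(s) min(rotations(s)), character(1), USE.NAMES = FALSE)
}

#' Reverse complement (DNA alphabet)
#'
#' @param x Character vector over `{A,C,G,T}`.
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  vapply(chartr("ACGT", "TGCA", toupper(x)), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a string into single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
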