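## Conserved tRNA-loop motifs and assembly of the AL ring.
##
## The three loop motifs of archaeal tRNA-Gly(GCC) -- TGGTA (D-loop),
## CTGCCA (anticodon loop) and TTCAA (T-psi loop) -- are searched as exact
## matches; the 19-nt loop consensus prefixed with the start codon ATG
## yields the 22-nt AL ring.

#' The 19-nt tRNA-Gly loop consensus (DNA spelling)
#' @return Character scalar `"AATGGTACTGCCATTCAAG"`.
#' @export
al_consensus19 <- function() "AATGGTACTGCCATTCAAG"

#' The AL sequence
#'
#' @param form `"ring"` for the 22-nt linear spelling starting at the ATG
#'   (`ATGAATGGTACTGCCATTCAAG`), `"canonical"` for the lexicographically
#'   minimal rotation.
#' @return Character scalar.
#' @export
al_sequence <- function(form = c("ring", "canonical")) {
  form <- match.arg(form)
  s <- paste0("ATG", al_consensus19())
  if (form == "canonical") canonical_rotation(s) else s
}

#' Find exact motif occurrences
#'
#' All occurrences of each motif in each sequence, overlaps allowed.
#'
#' @param seq Named character vector of sequences (DNA or RNA spelling).
#' @param motifs Character vector of motifs over `{A,C,G,T}`.
#' @return A data.frame with columns `sequence_id`, `motif`, `start`, `end`
#'   (0-based, half-open).
#' @examples
#' find_motifs(c(x = "TTGGTAA"), "TGGTA")
#' @export
find_motifs <- function(seq, motifs) {
  stopifnot(length(motifs) >= 1L)
  motifs <- normalize_nt(motifs, "motif")
  seq <- normalize_nt(seq, "record")
  ids <- if (!is.null(names(seq))) names(seq) else as.character(seq_along(seq))
  rows <- list()
  for (i in seq_along(seq)) {
    subject <- Biostrings::DNAString(seq[[i]])
    for (m in motifs) {
      hits <- Biostrings::matchPattern(m, subject)
      if (length(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = ids[i], motif = m,
          start = Biostrings::start(hits) - 1L,
          end = Biostrings::end(hits)
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column-majority consensus of pre-aligned sequences
#'
#' Per-column most frequent symbol over equal-length strings (gap `-`
#' permitted). Ties break by the fixed order A < C < G < T < `-`; columns
#' whose winner is the gap are dropped.
#'
#' @param aligned Character vector of equal-length strings.
#' @return The consensus string.
#' @examples
#' majority_consensus(c("ACG", "ACT", "ACG"))  # "ACG"
#' @export
majority_consensus <- function(aligned) {
  stopifnot(length(aligned) >= 1L)
  aligned <- toupper(chartr("Uu", "Tt", aligned))
  n <- nchar(aligned[1L])
  if (any(nchar(aligned) != n)) stop("aligned strings must have equal length", call. = FALSE)
  bad <- grepl("[^ACGT-]", aligned)
  if (any(bad)) stop("alignment contains non-ACGT/- characters", call. = FALSE)
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  order_sym <- c("A", "C", "G", "T", "-")
  cons <- apply(mat, 2L, function(col) {
    tab <- base::table(factor(col, levels = order_sym))
    names(tab)[which.max(tab)]  # which.max takes the first maximum: tie order
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Assemble the AL ring from a 19-nt consensus
#'
#' Prepends the start codon ATG to the 19-nt loop consensus, giving the
#' 22-nt ring (DNA spelling, returned in its given reading frame starting
#' at the ATG; set `canonical = TRUE` for the minimal rotation).
#'
#' @param consensus19 A 19-nt string; defaults to [al_consensus19()].
#' @param canonical Return the canonical (lexicographically minimal)
#'   rotation instead of the ATG-first spelling.
#' @return The 22-nt ring.
#' @examples
#' assemble_al()  # "ATGAATGGTACTGCCATTCAAG"
#' @export
assemble_al <- function(consensus19 = al_consensus19(), canonical = FALSE) {
  consensus19 <- normalize_nt(consensus19, "consensus")
  if (nchar(consensus19) != 19L) {
    stop("the loop consensus must have length 19", call. = FALSE)
  }
  ring <- paste0("ATG", consensus19)
  if (canonical) canonical_rotation(ring) else ring
}

#' Packaged tRNA-Gly(GCC) sequences
#'
#' Loads the small FASTA of tRNA-Gly(GCC) primary sequences from twelve
#' species (Archaea, animals, plants) shipped with the package, used to
#' demonstrate the conserved loop motifs.
#'
#' @return Named character vector of DNA sequences.
#' @export
trna_gly_sequences <- function() {
  read_fasta(system.file("extdata", "trna_gly_gcc.fasta", package = "alring",
                         mustWork = TRUE))
}
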