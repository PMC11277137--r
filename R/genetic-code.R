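## Synonymy tables: the partition of codons into amino-acid classes.
##
## A synonymy table maps every word of a fixed length over an alphabet to a
## class label. The standard table is the genetic code (translation table 1,
## from Biostrings::GENETIC_CODE): 64 codons, 20 amino-acid classes plus a
## separate STOP class. Toy tables over small alphabets support brute-force
## oracle testing of the ring enumerator.

#' Synonymy table of the standard genetic code
#'
#' Builds the codon -> amino-acid class mapping used by the ring enumerator
#' and hairpin logic. Codons are DNA-spelled 3-mers; the STOP class
#' (`TAA`, `TAG`, `TGA`) is kept separate from the 20 amino-acid classes
#' and does not count towards coverage.
#'
#' @return An object of class `synonymy_table`: a list with
#'   `classes` (named character vector, word -> label), `labels`
#'   (the required, i.e. non-STOP, class labels), `alphabet`, `word_len`,
#'   `start_codon` and `stop_set`.
#' @examples
#' tab <- synonymy_table()
#' class_of("GGT", tab)
#' @export
synonymy_table <- function() {
  gc1 <- Biostrings::GENETIC_CODE
  classes <- setNames(ifelse(gc1 == "*", "STOP", unname(gc1)), names(gc1))
  structure(
    list(
      classes = classes,
      labels = sort(unique(classes[classes != "STOP"])),
      alphabet = c("A", "C", "G", "T"),
      word_len = 3L,
      start_codon = "ATG",
      stop_set = c("TAA", "TAG", "TGA")
    ),
    class = "synonymy_table"
  )
}

#' Toy synonymy table with singleton classes
#'
#' Maps every word of `word_len` over `alphabet` to its own class. Used to
#' cross-check the enumerator against brute force at sizes where exhaustive
#' enumeration is feasible.
#'
#' @param alphabet Character vector of at least two distinct symbols
#'   (one symbol is allowed for degenerate cases).
#' @param word_len Word length (>= 1).
#' @return A `synonymy_table` whose classes are the words themselves and
#'   whose `stop_set` is empty.
#' @examples
#' toy_table(c("A", "C"), 2)
#' @export
toy_table <- function(alphabet, word_len) {
  stopifnot(length(alphabet) >= 1L, word_len >= 1L,
            !anyDuplicated(alphabet))
  alphabet <- as.character(alphabet)
  words <- Reduce(
    function(acc, i) as.vector(outer(acc, alphabet, paste0)),
    seq_len(word_len - 1L),
    init = alphabet
  )
  words <- sort(words)
  structure(
    list(
      classes = setNames(words, words),
      labels = words,
      alphabet = sort(alphabet),
      word_len = as.integer(word_len),
      start_codon = NA_character_,
      stop_set = character(0)
    ),
    class = "synonymy_table"
  )
}

#' Synonymy class of a codon
#'
#' @param codon A single word (DNA or RNA spelling; U is normalised to T
#'   for the standard table).
#' @param table A [synonymy_table()]; defaults to the standard genetic code.
#' @return The class label (an amino-acid one-letter code or `"STOP"` for
#'   the standard table).
#' @examples
#' class_of("ATG")           # "M"
#' class_of("UGA")           # "STOP"
#' @export
class_of <- function(codon, table = synonymy_table()) {
  stopifnot(inherits(table, "synonymy_table"))
  if (identical(table$alphabet, c("A", "C", "G", "T"))) {
    codon <- normalize_nt(codon, what = "codon")
  }
  if (any(nchar(codon) != table$word_len)) {
    stop(sprintf("codon must have length %d", table$word_len), call. = FALSE)
  }
  unknown <- !(codon %in% names(table$classes))
  if (any(unknown)) {
    stop(sprintf("unknown word '%s' for this table", codon[unknown][1L]),
         call. = FALSE)
  }
  unname(table$classes[codon])
}

#' @export
print.synonymy_table <- function(x, ...) {
  cat(sprintf(
    "Synonymy table: %d words of length %d over {%s}, %d required classes%s\n",
    length(x$classes), x$word_len, paste(x$alphabet, collapse = ","),
    length(x$labels),
    if (length(x$stop_set)) sprintf(" + STOP {%s}", paste(x$stop_set, collapse = ",")) else ""
  ))
  invisible(x)
}
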