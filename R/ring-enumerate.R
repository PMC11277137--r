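## Enumeration of minimal coverage rings.
##
## A ring of length L read by overlap exposes one codon per circular start
## offset. The enumerator searches for rings whose codons cover every
## amino-acid synonymy class, using a pruned depth-first construction
## (compiled kernel): a partial ring is abandoned as soon as the number of
## "wasted" codons (STOP or already-covered class) exceeds L minus the
## number of required classes.

#' Circular codon reading of a ring
#'
#' Reads the word starting at every circular offset: codon `i` is
#' `ring[i], ring[i+1 mod L], ring[i+2 mod L]` (word length taken from
#' `table`).
#'
#' @param ring A single nucleotide string (the linear spelling of the ring).
#' @param table A [synonymy_table()] (sets the word length; default codons).
#' @return Character vector of `nchar(ring)` words.
#' @examples
#' circular_codons("ACG")   # "ACG" "CGA" "GAC"
#' @export
circular_codons <- function(ring, table = synonymy_table()) {
  stopifnot(is.character(ring), length(ring) == 1L)
  w <- table$word_len
  if (nchar(ring) < w) stop("ring shorter than the word length", call. = FALSE)
  if (identical(table$alphabet, c("A", "C", "G", "T"))) {
    ring <- normalize_nt(ring, what = "ring")
  }
  L <- nchar(ring)
  ext <- paste0(ring, substr(ring, 1L, w - 1L))
  substring(ext, seq_len(L), seq_len(L) + w - 1L)
}

#' Does a ring cover every amino-acid class?
#'
#' TRUE iff the circular codon list (all offsets) hits every required class
#' of the table. For the standard genetic code the STOP class is not
#' required: presence of a stop codon is a separate property (see
#' [start_stop_filter()]).
#'
#' @inheritParams circular_codons
#' @return Logical scalar.
#' @examples
#' covers_all_amino_acids("ATGAATGGTACTGCCATTCAAG")  # TRUE: the AL ring
#' @export
covers_all_amino_acids <- function(ring, table = synonymy_table()) {
  cods <- circular_codons(ring, table)
  hit <- unique(unname(table$classes[cods]))
  all(table$labels %in% hit)
}

#' Enumerate coverage rings of a given length
#'
#' Finds all circular sequences of length `L` whose overlapping codons cover
#' every required synonymy class, deduplicated up to rotation (canonical =
#' lexicographically minimal rotation). The search is a pruned depth-first
#' construction, not an exhaustive alphabet^L scan; a pure-R brute force is
#' available for cross-checks at toy sizes (see the test suite).
#'
#' Two reading conventions are supported. `"translation"` (default) models
#' continuous circular translation: successive codons advance by the word
#' length, so every offset is visited exactly once only when `L` is coprime
#' with the word length. For `L` divisible by 3 (standard code) a single
#' reading visits only `L/3` codon slots -- too few to cover 20 classes for
#' any `L <= 24` -- so the census reports zero solutions. `"offsets"` reads
#' a word at every circular offset regardless of coprimality (the semantics
#' of [circular_codons()]), which is the convention used by the toy-table
#' oracle tests.
#'
#' @param L Ring length in nucleotides (3..24 for the standard code).
#' @param table A [synonymy_table()].
#' @param collect Keep the canonical solutions as a character vector
#'   (default TRUE). With the standard code at L = 22 this stores ~1.9e5
#'   rings; counting alone is cheaper for audits.
#' @param reading `"translation"` or `"offsets"` (see Details).
#' @return An object of class `ring_enumeration`: list with `rings`
#'   (character vector or NULL), and `census` -- a list with `L`,
#'   `n_solutions` (canonical count), `n_raw` (marked-start count, audit),
#'   and for the standard genetic code the repeat/stop census of
#'   [ring_census()].
#' @examples
#' enumerate_rings(4, toy_table(c("A", "C"), 2), reading = "offsets")
#' @export
enumerate_rings <- function(L, table = synonymy_table(), collect = TRUE,
                            reading = c("translation", "offsets")) {
  stopifnot(inherits(table, "synonymy_table"))
  reading <- match.arg(reading)
  L <- as.integer(L)
  w <- table$word_len
  if (L < 3L) stop("ring length must be at least 3", call. = FALSE)
  standard <- identical(table$alphabet, c("A", "C", "G", "T")) && w == 3L
  if (standard && L > 24L) {
    stop("enumeration is bounded at L = 24 for the standard code", call. = FALSE)
  }
  n_req <- length(table$labels)

  g <- .gcd(L, w)
  if (reading == "translation" && g != 1L) {
    slots <- L %/% g
    if (slots >= n_req) {
      stop(sprintf(
        "L = %d is not coprime with the word length %d: continuous reading does not visit every offset",
        L, w), call. = FALSE)
    }
    # A single continuous reading exposes only L/g codon slots, fewer than
    # the required classes: coverage is structurally impossible.
    return(.ring_enumeration(character(0), L, 0, 0, table, collect))
  }

  m <- length(table$alphabet)
  words_sorted <- sort(names(table$classes))
  lab_ids <- setNames(seq_along(table$labels) - 1L, table$labels)
  cls <- ifelse(table$classes[words_sorted] %in% table$labels,
                lab_ids[table$classes[words_sorted]], -1L)
  res <- .ring_search_cpp(L, m, w, as.integer(cls), n_req,
                          paste(sort(table$alphabet), collapse = ""),
                          collect)
  .ring_enumeration(res$solutions, L, res$n_canonical, res$n_raw, table,
                    collect)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

.ring_enumeration <- function(rings, L, n_canonical, n_raw, table, collect) {
  census <- list(L = L, n_solutions = n_canonical, n_raw = n_raw)
  standard <- identical(table$alphabet, c("A", "C", "G", "T")) &&
    table$word_len == 3L
  if (collect && standard && length(rings)) {
    census <- c(census, ring_census(rings, table))
  }
  structure(
    list(rings = if (collect) rings else NULL, census = census),
    class = "ring_enumeration"
  )
}

#' Repeat and start/stop census of a set of rings
#'
#' For each ring, examines the multiset of circular codons and tallies:
#' rings with exactly one doubled synonymy class (all other amino-acid
#' classes hit exactly once) whose doubled class lies in the AUN codon box
#' (Ile `ATA/ATC/ATT` or Met `ATG`); the histogram of the doubled codon
#' pair; and rings containing both the start codon `ATG` and the stop
#' codon `TGA`.
#'
#' @param rings Character vector of rings (equal length, ACGT).
#' @param table The standard [synonymy_table()].
#' @return List with `n_single_repeat`, `frac_AUG` (fraction of
#'   single-repeat rings whose doubled pair is `ATG/ATG`),
#'   `repeat_histogram` (named counts of doubled codon pairs),
#'   `doubled_class_histogram` and `n_start_stop`.
#' @export
ring_census <- function(rings, table = synonymy_table()) {
  stopifnot(length(rings) > 0L)
  L <- nchar(rings[1L])
  stopifnot(all(nchar(rings) == L))
  ext <- paste0(rings, substr(rings, 1L, 2L))
  n <- length(rings)
  codons <- matrix("", n, L)
  for (j in seq_len(L)) codons[, j] <- substring(ext, j, j + 2L)
  cls <- matrix(unname(table$classes[codons]), n, L)

  counts <- vapply(table$labels, function(lb) rowSums(cls == lb),
                   numeric(n))
  if (n == 1L) counts <- matrix(counts, 1L)  # vapply drops to vector
  n2 <- rowSums(counts == 2)
  n3 <- rowSums(counts >= 3)
  single <- n2 == 1L & n3 == 0L

  doubled_class <- rep(NA_character_, n)
  doubled_pair <- rep(NA_character_, n)
  idx <- which(single)
  if (length(idx)) {
    doubled_class[idx] <- table$labels[max.col(counts[idx, , drop = FALSE] == 2,
                                               ties.method = "first")]
    doubled_pair[idx] <- vapply(idx, function(i) {
      paste(sort(codons[i, cls[i, ] == doubled_class[i]]), collapse = "/")
    }, character(1))
  }
  aun <- c("ATA", "ATC", "ATG", "ATT")
  aun_classes <- unique(unname(table$classes[aun]))  # Ile, Met
  single_aun <- single & doubled_class %in% aun_classes

  has_start <- rowSums(codons == "ATG") > 0
  has_tga <- rowSums(codons == "TGA") > 0

  list(
    n_single_repeat = sum(single_aun),
    frac_AUG = if (any(single_aun)) {
      mean(doubled_pair[single_aun] == "ATG/ATG")
    } else NA_real_,
    repeat_histogram = base::table(doubled_pair[single_aun]),
    doubled_class_histogram = base::table(doubled_class[single]),
    n_start_stop = sum(has_start & has_tga)
  )
}

#' Keep rings with a single repeated AUN codon (or codon class)
#'
#' With `by = "class"` (default) a ring is kept when exactly one synonymy
#' class is doubled among its circular codons -- all other amino-acid
#' classes appearing exactly once -- and that class lies in the AUN codon
#' box (`ATA`, `ATC`, `ATG`, `ATT`, i.e. Ile or Met). With `by = "codon"`
#' the stricter literal rule is applied: exactly one codon *value* occurs
#' exactly twice, all others once, and that codon is in the AUN box.
#'
#' @param rings Character vector of rings.
#' @param table The standard [synonymy_table()].
#' @param by `"class"` or `"codon"` (see Details).
#' @return List with `rings` (the kept subset) and `histogram` (named
#'   counts of the repeated codon or codon pair).
#' @examples
#' al <- assemble_al()
#' single_repeat_filter(al)$histogram
#' @export
single_repeat_filter <- function(rings, table = synonymy_table(),
                                 by = c("class", "codon")) {
  by <- match.arg(by)
  if (!length(rings)) return(list(rings = character(0), histogram = base::table(character(0))))
  aun <- c("ATA", "ATC", "ATG", "ATT")
  if (by == "class") {
    cen <- .per_ring_repeat(rings, table)
    keep <- cen$single & cen$doubled_class %in%
      unique(unname(table$classes[aun]))
    list(rings = rings[keep], histogram = base::table(cen$doubled_pair[keep]))
  } else {
    info <- lapply(rings, function(r) {
      tab <- base::table(circular_codons(r, table))
      dup <- names(tab)[tab == 2L]
      ok <- length(dup) == 1L && all(tab <= 2L) && dup %in% aun
      list(ok = ok, dup = if (ok) dup else NA_character_)
    })
    keep <- vapply(info, `[[`, logical(1), "ok")
    list(rings = rings[keep],
         histogram = base::table(vapply(info[keep], `[[`, character(1), "dup")))
  }
}

## per-ring doubled-class bookkeeping shared with ring_census
.per_ring_repeat <- function(rings, table) {
  L <- nchar(rings[1L])
  ext <- paste0(rings, substr(rings, 1L, 2L))
  n <- length(rings)
  codons <- matrix("", n, L)
  for (j in seq_len(L)) codons[, j] <- substring(ext, j, j + 2L)
  cls <- matrix(unname(table$classes[codons]), n, L)
  counts <- vapply(table$labels, function(lb) rowSums(cls == lb), numeric(n))
  if (n == 1L) counts <- matrix(counts, 1L)
  single <- rowSums(counts == 2) == 1L & rowSums(counts >= 3) == 0L
  doubled_class <- rep(NA_character_, n)
  doubled_pair <- rep(NA_character_, n)
  idx <- which(single)
  if (length(idx)) {
    doubled_class[idx] <- table$labels[max.col(counts[idx, , drop = FALSE] == 2,
                                               ties.method = "first")]
    doubled_pair[idx] <- vapply(idx, function(i) {
      paste(sort(codons[i, cls[i, ] == doubled_class[i]]), collapse = "/")
    }, character(1))
  }
  list(single = single, doubled_class = doubled_class,
       doubled_pair = doubled_pair)
}

#' Keep rings containing both the start codon ATG and the stop codon TGA
#'
#' @param rings Character vector of rings.
#' @param table The standard [synonymy_table()].
#' @return The subset of `rings` whose circular codons include both `ATG`
#'   and `TGA`.
#' @export
start_stop_filter <- function(rings, table = synonymy_table()) {
  if (!length(rings)) return(character(0))
  keep <- vapply(rings, function(r) {
    cods <- circular_codons(r, table)
    ("ATG" %in% cods) && ("TGA" %in% cods)
  }, logical(1), USE.NAMES = FALSE)
  rings[keep]
}

#' @export
print.ring_enumeration <- function(x, ...) {
  cen <- x$census
  cat(sprintf("Ring enumeration at L = %d\n", cen$L))
  cat(sprintf("  solutions (up to rotation): %s\n",
              format(cen$n_solutions, big.mark = ",")))
  cat(sprintf("  raw marked-start strings:   %s\n",
              format(cen$n_raw, big.mark = ",")))
  if (!is.null(cen$n_single_repeat)) {
    cat(sprintf("  single AUN-class repeat:    %s (AUG doubled: %.1f%%)\n",
                format(cen$n_single_repeat, big.mark = ","),
                100 * cen$frac_AUG))
    cat(sprintf("  containing ATG and TGA:     %s\n",
                format(cen$n_start_stop, big.mark = ",")))
  }
  invisible(x)
}
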