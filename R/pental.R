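## The PpAL pentamer-proximity statistic.
##
## A pentamer set of k distinct 5-mers matches a uniform-random window with
## probability p = k/4^5 = k/1024. For a sequence of length N the expected
## number of matching window starts is n_e = N * p, its dispersion is
## modelled as Poisson (sigma_e = sqrt(n_e)), and the proximity score is
## p_AL = (n_o - n_e) / sigma_e in standard-deviation units, reported
## doubled as Pp_AL = 2 * p_AL.

#' Construct a pentamer set
#'
#' @param members Character vector of distinct 5-mers (DNA or RNA
#'   spelling).
#' @param name Label for the set.
#' @return An object of class `pentamer_set` with fields `name`, `members`
#'   and `p` (= k/1024 exactly).
#' @examples
#' pentamer_set(c("AAAAA", "ACGTA"), "demo")
#' @export
pentamer_set <- function(members, name = "custom") {
  members <- normalize_nt(members, "pentamer")
  if (length(members) < 1L) stop("a pentamer set needs at least one member", call. = FALSE)
  if (any(nchar(members) != 5L)) stop("all members must be 5-mers", call. = FALSE)
  if (anyDuplicated(members)) stop("pentamer set members must be distinct", call. = FALSE)
  structure(
    list(name = name, members = members, p = length(members) / 1024),
    class = "pentamer_set"
  )
}

#' Built-in AL pentamer sets
#'
#' `al_pentamers("al9")` is the nine-pentamer head set of the AL hairpin
#' (ATTCA, TTCAA, TCAAG, CAAGA, AAGAT, AGATG, GATGA, ATGAA, TGAAT);
#' `al_pentamers("al5")` is the five-pentamer variant
#' (AGATG, GATGA, GTGGC, TGGCC, GGCCT).
#'
#' @param name `"al9"` or `"al5"`.
#' @return A [pentamer_set()].
#' @export
al_pentamers <- function(name = c("al9", "al5")) {
  name <- match.arg(name)
  members <- switch(name,
    al9 = c("ATTCA", "TTCAA", "TCAAG", "CAAGA", "AAGAT",
            "AGATG", "GATGA", "ATGAA", "TGAAT"),
    al5 = c("AGATG", "GATGA", "GTGGC", "TGGCC", "GGCCT")
  )
  pentamer_set(members, name)
}

#' @export
print.pentamer_set <- function(x, ...) {
  cat(sprintf("Pentamer set '%s': %d members, p = %d/1024\n",
              x$name, length(x$members), length(x$members)))
  cat(" ", paste(x$members, collapse = " "), "\n")
  invisible(x)
}

#' Count pentamer-set matches in a sequence
#'
#' Number of window start positions whose 5-mer belongs to the set.
#' Overlapping matches all count. Linear topology scans `N - 4` starts;
#' circular topology scans all `N` starts with wraparound.
#'
#' @param seq A nucleotide string (DNA or RNA spelling), or a character
#'   vector of them (one count per element).
#' @param pset A [pentamer_set()]; default the nine-pentamer AL head set.
#' @param topology `"linear"` or `"circular"`.
#' @return Integer vector of match counts.
#' @examples
#' count_matches("ATGAATGGTACTGCCATTCAAG", topology = "circular")  # 9
#' @export
count_matches <- function(seq, pset = al_pentamers("al9"),
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(inherits(pset, "pentamer_set"))
  seq <- normalize_nt(seq, "record")
  if (topology == "linear" && any(nchar(seq) < 5L)) {
    stop("linear scoring needs at least 5 nucleotides", call. = FALSE)
  }
  if (any(nchar(seq) < 1L)) stop("empty sequence", call. = FALSE)
  scan <- if (topology == "circular") {
    # extend by 4 wraparound nucleotides (rings shorter than 5 nt must be
    # repeated several times)
    ifelse(nchar(seq) >= 5L,
           paste0(seq, substr(seq, 1L, 4L)),
           substr(strrep(seq, 5L), 1L, nchar(seq) + 4L))
  } else {
    seq
  }
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(pset$members))
  hits <- Biostrings::vcountPDict(dict, Biostrings::DNAStringSet(scan))
  as.integer(colSums(hits))
}

#' PpAL score from an observed count
#'
#' Implements the proximity arithmetic: `n_e = N * k/1024`,
#' `sigma_e = sqrt(n_e)` (Poisson dispersion), `p_al = (n_o - n_e)/sigma_e`
#' and `Pp_al = 2 * p_al`. Note that `N` is the sequence length, not the
#' window count.
#'
#' @param n_o Observed match count (>= 0).
#' @param N Sequence length in nucleotides (>= 1).
#' @param pset A [pentamer_set()] (only its size matters here).
#' @return An object of class `ppal_result`: list with `n_o`, `N`, `n_e`,
#'   `sigma_e`, `p_al`, `Pp_al` at full precision (see
#'   [format.ppal_result()] for display rounding).
#' @examples
#' ppal_score(13, 552)  # Pp_al approximately 7.4
#' @export
ppal_score <- function(n_o, N, pset = al_pentamers("al9")) {
  stopifnot(inherits(pset, "pentamer_set"))
  if (N < 1L) stop("degenerate input: N must be positive", call. = FALSE)
  if (n_o < 0L) stop("n_o must be nonnegative", call. = FALSE)
  n_e <- N * pset$p
  sigma_e <- sqrt(n_e)
  p_al <- (n_o - n_e) / sigma_e
  structure(
    list(n_o = as.integer(n_o), N = as.integer(N), n_e = n_e,
         sigma_e = sigma_e, p_al = p_al, Pp_al = 2 * p_al,
         pset = pset$name),
    class = "ppal_result"
  )
}

#' Score a sequence against a pentamer set
#'
#' Composition of [count_matches()] and [ppal_score()]; the sequence length
#' `N` (not the window count) feeds the expectation.
#'
#' @inheritParams count_matches
#' @return A `ppal_result`.
#' @export
score_sequence <- function(seq, pset = al_pentamers("al9"),
                           topology = c("linear", "circular")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("degenerate input: empty sequence", call. = FALSE)
  n_o <- count_matches(seq, pset, topology)
  ppal_score(n_o, nchar(seq), pset)
}

#' Upper-tail probability of the standard Gaussian
#'
#' The probability that a standard normal exceeds `z`; at the conventional
#' 4-sigma significance threshold this is about 3.17e-5, below 5e-5.
#'
#' @param z Threshold in standard-deviation units (>= 0).
#' @return Upper-tail probability.
#' @examples
#' tail_probability(4)
#' @export
tail_probability <- function(z) {
  stopifnot(all(z >= 0))
  pnorm(z, lower.tail = FALSE)
}

#' Grouped gradient table of mean PpAL scores
#'
#' Averages `Pp_al` per molecule across species and orders molecules by
#' ascending mean, reproducing the gradient layout (vital functions and
#' ancient lineages scoring high).
#'
#' @param results A data.frame with columns `molecule`, `species` and
#'   `Pp_al` (one row per molecule x species), or a list of
#'   `(molecule, species, ppal_result)` triples.
#' @return A data.frame with columns `molecule`, `n`, `mean_Pp_al`,
#'   sorted ascending by `mean_Pp_al`.
#' @export
gradient_report <- function(results) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(molecule = r[[1L]], species = r[[2L]],
                 Pp_al = if (inherits(r[[3L]], "ppal_result")) r[[3L]]$Pp_al else r[[3L]])
    }))
  }
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(molecule = character(0), n = integer(0),
                      mean_Pp_al = numeric(0)))
  }
  stopifnot(all(c("molecule", "Pp_al") %in% names(df)))
  agg <- aggregate(Pp_al ~ molecule, data = df,
                   FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(molecule = agg$molecule,
                    n = as.integer(agg$Pp_al[, "n"]),
                    mean_Pp_al = agg$Pp_al[, "mean"])
  out <- out[order(out$mean_Pp_al), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
format.ppal_result <- function(x, ...) {
  sprintf("n_o=%d N=%d n_e=%s sigma=%s p_al=%s Pp_al=%s",
          x$n_o, x$N, signif(x$n_e, 2), signif(x$sigma_e, 2),
          round(x$p_al, 1), round(x$Pp_al, 1))
}

#' @export
print.ppal_result <- function(x, ...) {
  cat("PpAL score (", x$pset, "): ", format(x), "\n", sep = "")
  invisible(x)
}
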