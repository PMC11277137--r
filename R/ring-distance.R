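## Distances between circular sequences and medoid (barycenter) selection.
##
## All metrics minimise over rotations of the second argument, which makes
## them rotation-invariant in both arguments and symmetric.

#' Circular Hamming distance
#'
#' Minimum Hamming distance between `a` and any rotation of `b`.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Integer in `[0, nchar(a)]`.
#' @examples
#' circular_hamming("ACGT", "CGTA")  # 0: pure rotation
#' @export
circular_hamming <- function(a, b) {
  a <- normalize_nt(a, "sequence"); b <- normalize_nt(b, "sequence")
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  av <- .chars(a)
  min(vapply(rotations(b), function(r) sum(av != .chars(r)), numeric(1)))
}

#' Circular edit (Levenshtein) distance
#'
#' Minimum unit-cost Levenshtein distance between `a` and any rotation of
#' `b`. Lengths may differ.
#'
#' @param a,b Nucleotide strings.
#' @return Integer edit distance.
#' @examples
#' circular_edit("AAAA", "AAA")  # 1
#' @export
circular_edit <- function(a, b) {
  a <- normalize_nt(a); b <- normalize_nt(b)
  if (nchar(b) == 0L) return(nchar(a))
  min(utils::adist(a, rotations(b)))
}

#' Circular permutation (Cayley swap) distance
#'
#' If `a` and `b` have the same letter multiset, the minimum number of
#' pairwise position swaps turning the best rotation of `b` into `a`;
#' otherwise `NA` (undefined, not an error). For a fixed rotation the swap
#' count equals the number of mismatched positions minus the maximum number
#' of edge-disjoint cycles packing the (balanced) mismatch multigraph on
#' the alphabet; the packing is solved exactly by a small recursive search.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Integer, or `NA_integer_` when `a` and `b` are not anagrams.
#' @examples
#' permutation_distance("AACG", "AAGC")  # 1
#' @export
permutation_distance <- function(a, b) {
  a <- normalize_nt(a); b <- normalize_nt(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  av <- .chars(a)
  if (!identical(sort(av), sort(.chars(b)))) return(NA_integer_)
  best <- Inf
  for (r in rotations(b)) {
    rv <- .chars(r)
    mis <- av != rv
    if (!any(mis)) return(0L)
    letters <- sort(unique(c(av, rv)))
    k <- length(letters)
    cnt <- matrix(0L, k, k, dimnames = list(letters, letters))
    for (i in which(mis)) cnt[rv[i], av[i]] <- cnt[rv[i], av[i]] + 1L
    swaps <- sum(mis) - .max_cycle_packing(cnt)
    if (swaps < best) best <- swaps
  }
  as.integer(best)
}

## Maximum number of edge-disjoint directed cycles decomposing a balanced
## multigraph given as a count matrix. Exact recursive search over simple
## cycles through the first remaining edge (non-simple cycles never help:
## splitting them yields more cycles).
.max_cycle_packing <- function(cnt) {
  nz <- which(cnt > 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0L)
  from <- nz[1L, 1L]; to <- nz[1L, 2L]
  best <- 0L
  extend <- function(path) {
    # path: vertex sequence from `from`, currently ending at tail(path,1)
    last <- path[length(path)]
    if (last == from) {
      cand <- 1L + .max_cycle_packing(cnt)
      if (cand > best) best <<- cand
      return(invisible())
    }
    for (nxt in seq_len(ncol(cnt))) {
      if (cnt[last, nxt] > 0L && !(nxt %in% path[-1L])) {
        cnt[last, nxt] <<- cnt[last, nxt] - 1L
        extend(c(path, nxt))
        cnt[last, nxt] <<- cnt[last, nxt] + 1L
      }
    }
  }
  cnt[from, to] <- cnt[from, to] - 1L
  extend(c(from, to))
  best
}

#' Pairwise distance matrix over a set of rings
#'
#' @param rings Character vector of rings (named or not; names become
#'   labels).
#' @param metric One of `"circular_hamming"`, `"circular_edit"`,
#'   `"permutation"`.
#' @return A symmetric numeric matrix with zero diagonal and
#'   `metric` attribute.
#' @export
ring_distance_matrix <- function(rings,
                                 metric = c("circular_hamming",
                                            "circular_edit",
                                            "permutation")) {
  metric <- match.arg(metric)
  fun <- switch(metric,
                circular_hamming = circular_hamming,
                circular_edit = circular_edit,
                permutation = permutation_distance)
  n <- length(rings)
  labels <- if (!is.null(names(rings))) names(rings) else as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- fun(rings[[i]], rings[[j]])
      }
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Barycenter (medoid) of a set of rings
#'
#' Returns the member minimising the mean distance to the other members.
#' Ties are broken by the lexicographically smallest canonical rotation;
#' whether the minimiser was unique is reported.
#'
#' @param rings Character vector of rings (length >= 1).
#' @param metric Metric name, as in [ring_distance_matrix()].
#' @return List with `ring` (the medoid, as given), `mean_distance`,
#'   `unique` (logical: was the minimum attained once?) and `index`.
#' @export
barycenter <- function(rings, metric = "circular_hamming") {
  if (length(rings) == 0L) stop("empty ring set", call. = FALSE)
  if (length(rings) == 1L) {
    return(list(ring = rings[[1L]], mean_distance = 0, unique = TRUE,
                index = 1L))
  }
  d <- ring_distance_matrix(rings, metric)
  if (anyNA(d)) stop("metric undefined on some pair (non-anagram rings?)",
                     call. = FALSE)
  means <- rowSums(d) / (length(rings) - 1L)
  hits <- which(means == min(means))
  pick <- hits[order(canonical_rotation(unlist(rings[hits])))][1L]
  list(ring = rings[[pick]], mean_distance = means[[pick]],
       unique = length(hits) == 1L, index = pick)
}
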