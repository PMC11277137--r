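## Ring <-> hairpin duality: fold a sequence into a stem-loop by greedy
## outward-in pairing and derive the "head" pentamers around the loop.
##
## Pairing is structural, not thermodynamic: Watson-Crick pairs plus the
## G.T (G.U) wobble by default. For circular input the fold searches all
## rotations (cut points) and small 5'/3' overhangs, keeping the longest
## stem; on a ring an overhang simply bulges at the closing side of the
## stem.

.complementary <- function(x, y, wobble = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
        (x == "C" & y == "G") | (x == "G" & y == "C")
  if (!wobble) return(wc)
  wc | (x == "G" & y == "T") | (x == "T" & y == "G")
}

## greedy outward-in pairing of chars v between indices lo..hi (1-based),
## stopping at the first non-complementary pair or when the enclosed loop
## would drop below min_loop
.greedy_stem <- function(v, lo, hi, min_loop, wobble) {
  pairs <- 0L
  while (hi - lo - 1L >= min_loop && .complementary(v[lo], v[hi], wobble)) {
    pairs <- pairs + 1L
    lo <- lo + 1L
    hi <- hi - 1L
  }
  list(pairs = pairs, loop = c(lo, hi))  # loop spans positions lo..hi
}

#' Fold a sequence into a stem-loop hairpin
#'
#' Pairs position `i` with position `n - 1 - i` (0-based) outward-in,
#' stopping at the first non-complementary pair or when the loop would
#' shrink below `min_loop`. With `circular = TRUE` the input is treated as
#' a ring: every rotation and every pair of 5'/3' overhangs up to
#' `max_overhang` is tried and the fold with the most pairs is kept (ties:
#' fewer overhang nucleotides, then smaller rotation index).
#'
#' @param seq Nucleotide string (DNA or RNA spelling).
#' @param min_loop Minimum unpaired loop length (>= 3).
#' @param wobble Allow G.T (G.U) wobble pairs (default TRUE).
#' @param circular Treat `seq` as a ring and search rotations.
#' @param max_overhang Maximum unpaired overhang per side (circular mode).
#' @return An object of class `hairpin_fold`: list with `seq` (input
#'   spelling), `rotation` (0-based cut offset; 0 for linear), `overhang`
#'   (5', 3'), `pairs` (two-column matrix of 0-based paired positions in
#'   the rotated spelling), `score` (number of pairs), `loop` (0-based
#'   half-open interval in the rotated spelling), `loop_ring` (0-based
#'   positions of the loop in the *input* spelling) and `circular`.
#' @examples
#' fold_hairpin("GGGAAACCC")$score  # 3
#' @export
fold_hairpin <- function(seq, min_loop = 3L, wobble = TRUE,
                         circular = FALSE, max_overhang = 2L) {
  seq <- normalize_nt(seq, "sequence")
  stopifnot(length(seq) == 1L, min_loop >= 3L)
  n <- nchar(seq)
  if (n < min_loop + 2L) stop("sequence too short to fold", call. = FALSE)
  rots <- if (circular) 0:(n - 1L) else 0L
  over <- if (circular) 0:max_overhang else 0L
  best <- NULL
  for (r in rots) {
    s <- if (r == 0L) seq else paste0(substr(seq, r + 1L, n), substr(seq, 1L, r))
    v <- .chars(s)
    for (a in over) for (b in over) {
      if (n - a - b < min_loop + 2L) next
      st <- .greedy_stem(v, a + 1L, n - b, min_loop, wobble)
      key <- c(st$pairs, -(a + b), -r)
      if (is.null(best) || .lex_gt(key, best$key)) {
        best <- list(key = key, r = r, a = a, b = b, st = st, s = s)
      }
    }
  }
  st <- best$st
  npair <- st$pairs
  pairs <- if (npair > 0L) {
    cbind(best$a + seq_len(npair) - 1L, n - best$b - seq_len(npair))
  } else {
    matrix(integer(0), 0L, 2L)
  }
  loop0 <- st$loop[1L] - 1L      # 0-based start of loop in rotated spelling
  loop1 <- st$loop[2L]           # half-open end
  list(
    seq = seq, rotation = best$r, overhang = c(best$a, best$b),
    pairs = pairs, score = npair,
    loop = c(loop0, loop1),
    loop_ring = (best$r + loop0:(loop1 - 1L)) %% n,
    circular = circular
  ) |> structure(class = "hairpin_fold")
}

.lex_gt <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] > y[i]) return(TRUE)
    if (x[i] < y[i]) return(FALSE)
  }
  FALSE
}

#' Head pentamers of a hairpin fold
#'
#' All 5-nt windows overlapping the loop interval, plus `flank` adjacent
#' windows on each side. For a circular fold the windows are read on the
#' ring (wraparound); for a linear fold they are clamped to the sequence.
#' For the AL ring with the default parameters this reproduces the
#' nine-pentamer head set exactly.
#'
#' @param fold A `hairpin_fold` from [fold_hairpin()].
#' @param flank Number of adjacent windows added on each side (default 1).
#' @return A [pentamer_set()] named `"head"`.
#' @examples
#' head_pentamers(fold_hairpin(al_sequence(), circular = TRUE))
#' @export
head_pentamers <- function(fold, flank = 1L) {
  stopifnot(inherits(fold, "hairpin_fold"))
  n <- nchar(fold$seq)
  if (length(fold$loop_ring) == 0L) {
    stop("undefined head: the fold has no loop", call. = FALSE)
  }
  loop <- fold$loop  # in rotated spelling, 0-based half-open
  # window starts overlapping [loop0, loop1): w in [loop0-4, loop1-1]
  starts <- (loop[1L] - 4L - flank):(loop[2L] - 1L + flank)
  if (fold$circular) {
    starts <- (fold$rotation + starts) %% n  # back to input spelling
    ext <- paste0(fold$seq, substr(fold$seq, 1L, 4L))
    windows <- substring(ext, starts + 1L, starts + 5L)
  } else {
    starts <- starts[starts >= 0L & starts + 5L <= n]
    windows <- substring(fold$seq, starts + 1L, starts + 5L)
  }
  pentamer_set(unique(windows), "head")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  n <- nchar(x$seq)
  s <- if (x$rotation == 0L) x$seq else
    paste0(substr(x$seq, x$rotation + 1L, n), substr(x$seq, 1L, x$rotation))
  db <- rep(".", n)
  if (x$score > 0L) {
    db[x$pairs[, 1L] + 1L] <- "("
    db[x$pairs[, 2L] + 1L] <- ")"
  }
  cat(s, "\n", paste(db, collapse = ""), "\n", sep = "")
  cat(sprintf("stem: %d pairs; loop: [%d, %d) of the %s spelling%s\n",
              x$score, x$loop[1L], x$loop[2L],
              if (x$rotation) sprintf("rotation-%d", x$rotation) else "input",
              if (x$circular) " (circular fold)" else ""))
  invisible(x)
}
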