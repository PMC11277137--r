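# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (Biostrings dictionaries, the compiled DFS, adist) so the
# tests compare two independent routes.

# window-scan pentamer counting by direct substring comparison
bf_count <- function(seq, members, topology = "linear") {
  if (topology == "circular") seq <- paste0(seq, substr(seq, 1, 4))
  n <- nchar(seq)
  if (n < 5) return(0L)
  hits <- 0L
  for (i in seq_len(n - 4L)) {
    if (substr(seq, i, i + 4L) %in% members) hits <- hits + 1L
  }
  hits
}

# exhaustive enumeration of coverage rings over all |alphabet|^L strings,
# deduplicated to canonical rotations
bf_enumerate <- function(L, table) {
  ab <- table$alphabet
  w <- table$word_len
  grids <- do.call(expand.grid, c(rep(list(ab), L), stringsAsFactors = FALSE))
  strings <- do.call(paste0, grids)
  covered <- vapply(strings, function(s) {
    ext <- paste0(s, substr(s, 1, w - 1L))
    words <- substring(ext, seq_len(L), seq_len(L) + w - 1L)
    all(table$labels %in% unname(table$classes[words]))
  }, logical(1), USE.NAMES = FALSE)
  sort(unique(canonical_rotation(strings[covered])))
}

# textbook Levenshtein dynamic programme
bf_lev <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (av[i] != bv[j]))
  }
  d[n + 1L, m + 1L]
}

# minimum number of position swaps turning b into a, by breadth-first
# search over strings (tiny inputs only)
bf_swaps <- function(a, b) {
  if (a == b) return(0L)
  frontier <- b
  seen <- b
  depth <- 0L
  repeat {
    depth <- depth + 1L
    nxt <- character(0)
    for (s in frontier) {
      v <- strsplit(s, "")[[1]]
      n <- length(v)
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        u <- v; tmp <- u[i]; u[i] <- u[j]; u[j] <- tmp
        cand <- paste(u, collapse = "")
        if (cand == a) return(depth)
        if (!(cand %in% seen)) { seen <- c(seen, cand); nxt <- c(nxt, cand) }
      }
    }
    frontier <- nxt
    if (!length(frontier) || depth > 8L) return(NA_integer_)
  }
}

bf_circular_swaps <- function(a, b) {
  min(vapply(rotations(b), function(r) bf_swaps(a, r), integer(1)))
}

# half-up rounding (the convention of the printed tables; R's round() is
# half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
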