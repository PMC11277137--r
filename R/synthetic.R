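## Synthetic sequences with the statistical structure the PpAL analysis
## assumes: an i.i.d. uniform null, and a planted-enrichment model in which
## pentamer-set members are written over a uniform background at a
## controlled excess rate.

## run fn with a private RNG stream seeded by `seed`, restoring the
## caller's stream afterwards
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a synthetic nucleotide sequence
#'
#' `mode = "null"` draws i.i.d. uniform nucleotides. `mode = "planted"`
#' overwrites a Poisson((lambda - 1) * N * p) number of pentamer-set
#' members at uniformly chosen non-overlapping offsets of a uniform
#' background, so the expected total match rate is about lambda times the
#' null rate. Planting positions that would overlap an earlier insertion
#' are redrawn (bounded retries); the realised insertion count is recorded.
#'
#' @param N Sequence length (>= 5).
#' @param mode `"null"` or `"planted"`.
#' @param lambda Enrichment multiplier (>= 1; planted mode).
#' @param pset A [pentamer_set()] (planted mode).
#' @param seed Integer seed; the same `(arguments, seed)` reproduce the
#'   identical sequence.
#' @return A character scalar with attribute `planted` (realised insertion
#'   count, planted mode only).
#' @examples
#' generate_sequence(30, seed = 1)
#' @export
generate_sequence <- function(N, mode = c("null", "planted"), lambda = 1,
                              pset = al_pentamers("al9"), seed) {
  mode <- match.arg(mode)
  stopifnot(N >= 5L, lambda >= 1)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  .with_seed(seed, function() {
    v <- sample(c("A", "C", "G", "T"), N, replace = TRUE)
    planted <- 0L
    if (mode == "planted" && lambda > 1) {
      k <- rpois(1L, (lambda - 1) * N * pset$p)
      occupied <- rep(FALSE, N)
      tries <- 0L
      while (planted < k && tries < 100L * max(k, 1L)) {
        tries <- tries + 1L
        at <- sample.int(N - 4L, 1L)
        if (any(occupied[at:(at + 4L)])) next
        member <- pset$members[sample.int(length(pset$members), 1L)]
        v[at:(at + 4L)] <- .chars(member)
        occupied[at:(at + 4L)] <- TRUE
        planted <- planted + 1L
      }
    }
    out <- paste(v, collapse = "")
    if (mode == "planted") attr(out, "planted") <- planted
    out
  })
}

#' Generate a cohort of random rings
#'
#' Draws `n` uniform-random rings of length `L`, canonicalises them
#' (lexicographically minimal rotation) and removes duplicates.
#'
#' @param n Number of rings to draw (>= 1).
#' @param L Ring length (>= 3).
#' @param seed Integer seed.
#' @return Character vector of canonical rings (possibly fewer than `n`
#'   after deduplication).
#' @export
generate_ring_cohort <- function(n, L, seed) {
  stopifnot(n >= 1L, L >= 3L)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  .with_seed(seed, function() {
    raw <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    unique(canonical_rotation(raw))
  })
}
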