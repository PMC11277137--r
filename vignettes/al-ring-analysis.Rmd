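---
title: "Minimal RNA rings and the PpAL proximity statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal RNA rings and the PpAL proximity statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alring)
```

## The scientific setting

One family of origin-of-life hypotheses posits a small circular RNA — here
called AL, for *Archetypal Loop* — as a candidate primordial molecule: a ring
short enough to be prebiotically plausible, yet exposing, through overlapping
reading, at least one codon for every amino acid, so that it could have acted
as a generic adaptor ("marriage agency") between amino acids and nucleic
acids. The AL sequence itself is assembled from the conserved loop motifs of
archaeal tRNA-Gly(GCC): prepending the start codon AUG to the 19-nt loop
consensus `AAUGGUACUGCCAUUCAAG` yields the 22-nt ring
`AUGAAUGGUACUGCCAUUCAAG`. If such a molecule seeded early genomes, modern
sequences with vital functions should still be enriched for short fragments
of it. The package implements the full computational chain behind that
argument:

1. **Combinatorics** — enumerate all rings of a given length whose
   overlapping codons cover the twenty amino-acid synonymy classes, and
   characterise them (repeated codons, start/stop content).
2. **Geometry** — circular distance measures and medoid ("barycenter")
   selection among candidate rings.
3. **Structure** — the ring ↔ hairpin duality and the derivation of the
   "head" pentamers from the hairpin loop.
4. **Statistics** — the PpAL score: how strongly a given sequence is
   enriched for those head pentamers relative to a uniform null.
5. **Simulation** — null and planted-enrichment sequence generators so the
   calibration and power of the statistic are testable without any external
   data.

All internal computation uses the DNA alphabet `{A,C,G,T}`; RNA input is
normalised `U → T` at the boundary (`normalize_nt()`), and `as_rna()`
renders results back in RNA spelling. IUPAC ambiguity codes are rejected
rather than skipped, because the statistic has no defined behaviour for
them.

## Ring enumeration

A ring of length $L$ read "by overlap" exposes the codon starting at every
circular offset. When $L$ is coprime with 3 — as for $L = 22$ — continuous
circular translation visits every offset exactly once over three
revolutions, so the ring carries exactly $L$ codons. The enumeration
constraint is *coverage*: at least one codon from each of the 20 amino-acid
synonymy classes of the standard genetic code. The STOP class is **not**
required; whether a ring also contains a stop codon is tracked separately.

`enumerate_rings()` performs a depth-first construction over the $4^L$
candidate strings with an aggressive but exact prune. Since each of the $L$
codons either covers a new class or is "wasted" (STOP, or a class already
covered), any completed solution has exactly $L - 20$ wasted codons; a
partial assignment is abandoned the moment its waste exceeds $L - 20$. At
$L = 22$ the waste budget is 2, which cuts the search from $4^{22} \approx
1.8 \times 10^{13}$ leaves to about $2 \times 10^{10}$ visited nodes — a
compiled kernel finishes in roughly one to two minutes on a single CPU.
Solutions are deduplicated up to rotation by keeping only lexicographically
minimal rotations; the raw marked-start count is reported alongside for
audit (`census$n_raw`). A periodicity argument shows the two conventions
differ by exactly the factor $L$ at $L = 22$: a period $d \mid 22$, $d <
22$, would cap the number of distinct codons at $d \le 11 < 20$, so all
solutions are aperiodic.

Key census results, recomputed by `enumerate_rings(22)` (and asserted in
the test suite):

* **191,664** coverage rings up to rotation (4,216,608 marked-start
  strings).
* **29,520** of them have exactly one *doubled synonymy class* — every
  other amino-acid class hit exactly once — and that class always lies in
  the AUN codon box (Ile `AUA/AUC/AUU` or Met `AUG`). These are precisely
  the solutions that also contain a stop codon: with a waste budget of 2,
  one waste pays for the stop and the other for the doubled class.
* The doubled codon is AUG (N = G) for 15,408 of the 29,520, i.e. **52%**.
* 15,120 solutions contain both the start codon AUG and the stop codon
  UGA (`start_stop_filter()`).

`single_repeat_filter()` defaults to the doubled-class reading
(`by = "class"`), which the census above uses; a stricter literal variant
(`by = "codon"`: one codon *value* repeated exactly twice) is kept for
audit and gives 49,752 rings.

### Reading conventions and lengths below 22

For lengths not coprime with 3 a single continuous overlap reading visits
only $L/3$ codon slots, far too few to cover 20 classes for any $L \le 24$,
so the default (`reading = "translation"`) reports zero solutions at
$L = 21$ on structural grounds. With $L = 19$ there are fewer codons than
classes, and the $L = 20$ search returns empty: **no solution exists below
length 22**, the minimality property that motivates the choice of 22.
`reading = "offsets"` reads a word at every circular offset regardless of
coprimality; it is the convention of `circular_codons()` and of the
brute-force oracle tests on toy synonymy tables (`toy_table()`), where
exhaustive enumeration over all $|\Sigma|^L$ strings is feasible and must
agree with the pruned search exactly.

### A note on the published total

The downstream census numbers (29,520; 52%) reproduce published values for
this enumeration exactly under the canonical rotation convention, while a
widely quoted total of 1,761,011 solutions at $L = 22$ matches neither the
canonical count (191,664) nor the raw marked-start count (4,216,608), nor
any relaxation we examined (linear reading, anticodon or complement
coverage — all of which additionally break the minimal-length-22 property).
The package therefore reports both of its counting conventions and leaves
the discrepancy visible rather than calibrating to it.

## Distances and the barycenter

Three rotation-invariant metrics are provided, each minimising over
rotations of the second argument: `circular_hamming()` (equal lengths),
`circular_edit()` (unit-cost Levenshtein, lengths may differ; satisfies the
triangle inequality) and `permutation_distance()` (anagram inputs only:
the minimum number of position swaps, computed exactly as mismatches minus
the maximum cycle packing of the mismatch multigraph; non-anagram pairs
yield `NA`). The swap-count formula is exact because a balanced multigraph
decomposes into directed cycles and a cycle of length $k$ costs $k - 1$
swaps; the packing is maximised by a small recursive search, which is
cheap at ring lengths $\le 22$.

`barycenter()` returns the *medoid* — the member of the set minimising mean
distance to the others — since the distinguished ring is described as lying
within the candidate set itself. Ties break deterministically toward the
lexicographically smallest canonical rotation, and uniqueness of the
minimiser is reported.

## The hairpin and its head pentamers

The ring and a stem-loop hairpin are two conformations of the same
sequence. `fold_hairpin()` models the hairpin structurally (not
thermodynamically): positions are paired outward-in, greedily, stopping at
the first non-complementary pair or when the enclosed loop would drop below
`min_loop` (default 3 nt, the sterically minimal RNA loop). Complementarity
is Watson-Crick plus the G·T (G·U) wobble; `wobble = FALSE` restricts to
Watson-Crick. Because the wobble pair is strand-asymmetric (the reverse
complement of G·T is A·C, which does not pair), fold scores are invariant
under reverse complement only under the pure Watson-Crick rule set — the
property tests check exactly that.

With `circular = TRUE` the fold searches all rotations (cut points) and
small 5'/3' overhangs (`max_overhang`, default 2) and keeps the longest
stem, breaking ties toward fewer overhang nucleotides and then the smaller
rotation. For the AL ring the optimum is unique and maximal: a 9-bp stem
(one wobble pair), one bulged C, and a 3-nt loop sitting at ring positions
{20, 21, 0} — the junction where AUG was prepended to the loop consensus.

```{r}
fold <- fold_hairpin(al_sequence(), circular = TRUE)
fold
```

`head_pentamers()` collects every 5-nt window overlapping the loop
interval plus `flank` (default 1) adjacent windows per side — nine windows
for a 3-nt loop on a ring. For AL this reproduces the canonical
nine-pentamer head set used by the statistic; that conformance pins the
parameterisation (`min_loop = 3`, wobble on, `max_overhang = 2`,
`flank = 1`):

```{r}
sort(head_pentamers(fold)$members)
```

## The PpAL statistic

For a pentamer set of $k$ distinct 5-mers, a window of a uniform i.i.d.
sequence matches with probability $p = k/4^5 = k/1024$. Scoring a sequence
of length $N$ with observed match count $n_o$:

$$ n_e = N\,p, \qquad \sigma_e = \sqrt{n_e}, \qquad
   p_{AL} = \frac{n_o - n_e}{\sigma_e}, \qquad Pp_{AL} = 2\,p_{AL}. $$

Two conventions are deliberate and verified against the reference table
shipped with the package (`ppal_reference()`): the expectation uses the
sequence length $N$, not the window count $N - 4$; and the dispersion is
the Poisson form $\sqrt{n_e}$ rather than the binomial
$\sqrt{Np(1-p)}$ — both choices match the published per-row arithmetic to
its printed precision. Overlapping matches all count, only the given
strand is scanned, and distinct set members cannot match at the same
start, so no double-counting rule is needed. At the conventional 4-sigma
threshold the Gaussian upper tail is `tail_probability(4)` ≈ 3.2e-5,
below the 5e-5 bound quoted for the method.

```{r}
ppal_score(13, 552)          # a ribosomal-protein mRNA row
score_sequence(al_sequence(), topology = "circular")  # AL against itself
```

`gradient_report()` averages $Pp_{AL}$ per molecule across species and
sorts ascending, reproducing the published gradient: means rise from
ribosomal protein L18 (8.3) through helicase (18.15) to tRNA-Gly (84.4)
and AL itself (100). Display rounding follows the reference table
(1 decimal for sigma-unit quantities, two significant figures for
expectations); `write_report()` renders machine-readable TSV without sigma
suffixes.

One reference row is special: AL's self-score row prints $p_{AL} = 50\sigma$
and $Pp_{AL} = 100$ where the arithmetic gives $49.57\sigma$ — the printed
value rounds the sigma count to an integer before doubling. The tests
assert that rounding identity for that row and the ±0.15 one-decimal band
for all others. The reference rows' observed counts $n_o$ are inputs, not
recomputed: for the mRNA/rRNA rows they derive from external database
sequences, and the tRNA rows use a counting convention (counts up to $N$
on a 22-nt scale) that is not reconstructible from the sequences alone.

## The synthetic-data generator

`generate_sequence()` emulates exactly the statistical structure the score
assumes:

* **null** — i.i.d. uniform nucleotides, the distribution under which
  $p = k/1024$ holds per window;
* **planted** — a uniform background in which
  $\mathrm{Poisson}\big((\lambda-1)\,N\,p\big)$ set members are written at
  uniformly drawn non-overlapping offsets, so the expected match rate is
  about $\lambda$ times the null rate. Overlapping placements are redrawn
  (bounded retries) and the realised insertion count is recorded in the
  `planted` attribute.

Each call is bit-for-bit reproducible from its `(arguments, seed)` pair and
leaves the caller's RNG state untouched. The generator makes no attempt at
realistic codon usage, GC content, or phylogenetic correlation — so a
passing calibration says the *statistic* behaves as advertised under its
own null, not that real genomes are uniform; on real sequences,
composition bias alone can move $p_{AL}$.

The simulation tests use problem sizes chosen to keep the whole suite
within a few minutes while retaining power: null calibration with 400
replicates at $N = 2000$ (mean $n_o$ within 3 Monte-Carlo standard errors
of $Np$), power monotonicity across $\lambda \in \{1, 2, 5, 10\}$ with 60
replicates each, and a type-I check at $N = 10^4$ with 600 replicates
against the loose $5\times10^{-4}$ bound (the analytic 4-sigma tail is
asserted separately, not simulated).

## Numerical and design choices

* **Canonical form** of a ring is its lexicographically minimal rotation;
  canonicalisation is idempotent and is the deduplication key everywhere.
* **Degenerate inputs** fail fast with informative errors: empty sequences
  and $N = 0$ scores, rings shorter than the word length, non-anagram
  pairs for the permutation metric (`NA`, not an error), folds without a
  loop for `head_pentamers()`.
* **Tie-breaks** are always deterministic: alphabet order `A < C < G < T <
  '-'` in `majority_consensus()` columns; smallest canonical form for
  medoid ties; fewest overhangs then smallest rotation for equal-score
  folds.
* **Reflection is not identified** with rotation: rings are read 5'→3',
  and the reverse complement is a different molecule.
* The enumeration census and the proximity arithmetic are exact
  (integer/floating deterministic); only the generator-based checks are
  Monte Carlo.

## Limitations

* Enumeration is bounded at $L = 24$ for the standard code; the waste
  budget (and hence the search) grows combinatorially with $L - 20$.
* The hairpin model is structural; it does not compute free energies and
  will not resolve competing folds that differ only thermodynamically.
* The motif machinery is exact-match only (no PWMs or IUPAC degeneracy),
  matching how the conserved tRNA-loop motifs are described.
* Scoring genome-scale sequences works but is not an optimised scanner;
  `count_matches()` accepts vectors of sequences for batch use.
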