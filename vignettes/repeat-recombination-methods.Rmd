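---
title: "Methods: repeat-mediated recombination analysis on circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated recombination analysis on circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circrecomb)
```

## The model

A circular genome of length $n$ is stored linearly with an implicit
origin; every coordinate is taken modulo $n$, internally 0-based
half-open, and printed 1-based inclusive. Two molecules are the same
physical circle iff their *canonical forms* — the lexicographically
minimal string over all rotations of the sequence and of its reverse
complement — are identical. Canonicalization is the workhorse
equivalence throughout: it is what lets recombination products be
de-duplicated without tracking rotations or strand conventions.

Dispersed repeats are modelled as *families*: sets of intervals whose
sequences are identical up to reverse complement (at the default
`min_identity = 1`). A pair of copies is **DR** if the copies share a
strand once copy `a` is fixed as `+`, **IR** otherwise. Homologous
recombination between a pair is modelled at repeat-copy granularity:
because exact copies are interchangeable, every crossover position
inside the repeat yields the same product, so only three event types
exist —

* **inversion** (IR pair, one circle): the arc strictly between the two
  copies is reverse-complemented; both copies survive; an involution up
  to rotation.
* **fission** (DR pair, one circle): the circle splits into
  subcircle 1 = copy 1 + arc to copy 2, and subcircle 2 = copy 2 +
  remaining arc; lengths are conserved and each subcircle keeps one
  full copy.
* **fusion** (two circles, one copy each): the inverse of fission.

`enumerate_forms()` closes these events breadth-first from the master
circle `MC1` up to `max_events` (default 2, which covers the four major
forms a large IR plus a large DR generate: `MC1`, `MC2`, `MC1^2`,
`MC2^2`). Event orderings that commute collapse because states are
keyed by the multiset of canonical forms. Whether the doubly-rearranged
forms are "really" two subcircles or re-fused master circles in vivo is
not observable from junctions alone; this package represents them as
fission products (the two-circle multipartite model), and fusion events
fold them back when enumeration continues.

Read support for a pair is measured on four junction references built
from `flank_len` (default 3,000 bp) of oriented context around each
copy: `ref_a = U_a R D_a`, `ref_b = U_b R D_b` reproduce the genome;
`alt_ab = U_a R D_b`, `alt_ba = U_b R D_a` are the recombinant
configurations. For the minus-strand copy of an IR pair the context is
reverse-complemented first, so all four present the repeat in the same
orientation. A read counts only if its primary alignment covers at
least `min_flank_overlap` (default 1,800 bp) of the upstream *and* the
downstream flank. The default bar is deliberately larger than the
longest repeat that covers a nested repeat in the target genome
(1,467 bp): a read that only touches repeat-shared sequence can then
never be assigned, which the suite checks with adversarial
repeat-only reads. Rates are pooled (`ref_a`+`ref_b` vs
`alt_ab`+`alt_ba`; the per-label counts are kept internally) and
printed as 2-decimal percentages.

## Alignment engine

Junction classification, coverage filtering and duplex detection share
one native aligner: exact $k$-mer anchors ($k = 15$, read sampled every
`stride = 5` bases plus the final position) hashed against the
reference set, grouped by diagonal (`ref_pos − read_pos`) into bands of
`bandwidth = 100` bp (three adjacent bands are pooled, absorbing indel
drift at the error rates the simulator produces), scored by the number
of distinct anchored read positions. The best-scoring band over all
references and strands is the primary alignment; its span is refined by
maximal exact extension of both ends, so error-free reads get exact
boundaries. Ties break deterministically: higher score, then reference
order (`ref_a < ref_b < alt_ab < alt_ba`), then `+` strand. The engine
is a contract, not a reimplementation of a production mapper: it is
required to choose the right reference and estimate spans for reads
within ~5% divergence, which the suite verifies directly (100% accuracy
on error-free dual-flank reads; ≥99% primary-reference agreement at 1%
substitutions). Circular references are doubled internally so one
collinear chain can cross the origin without ever double-counting a
read (one read, one label).

Total query coverage (the ≥70% organelle-extraction rule) pools the
union of anchored read positions over all diagonals, references and
strands of a compartment — the moral equivalent of summing primary plus
supplementary alignment spans — so a half-mitochondrial chimera scores
about 0.5 and is excluded. Duplex-like artifacts (two halves of a read
reverse complements of each other) are detected by aligning the halves
separately: the read is removed when the halves land on the same
reference region on opposite strands with reciprocal overlap ≥ 0.8.
That threshold is not dictated by the upstream protocol; 0.8 is strict
enough to keep ordinary reads (<1% false positives in the planted
audit) and loose enough that boundary jitter of anchor spans never
rescues a true artifact. Because a repeat copy (or the doubled
reference) makes half placements ambiguous, the second half is chosen
among near-best candidates (≥0.8 of the top score) as the one most
consistent with a fold-back, with spans compared modulo the circle
length.

Full-length accounting applies the documented ordered test: a read is
explained by the master circle when one collinear chain covers ≥ 95% of
its bases ("aligned linearly" operationalized as one band: single
strand, monotone coordinates — reads needing a strand switch or two
chains fail); only the failures are tested against the alternative
form's circles, so a read satisfying both counts for the master circle.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_repeat_len` | 50 | bp | smallest dispersed repeat reported; below ~20 bp seeds are unreliable and the finder refuses |
| `min_identity` | 1.0 | fraction | exact repeats are the substrates of clean homologous recombination; 0.99 enables mismatch-tolerant extension (substitutions only) |
| `flank_len` | 3,000 | bp | junction context per side |
| `min_flank_overlap` | 1,800 | bp | dual-flank bar; must exceed the longest nested-covering repeat |
| `full_length_threshold` | 0.95 | fraction | collinear coverage for "fully and linearly" aligned |
| `organelle_query_coverage` | 0.70 | fraction | mitochondrial read retention |
| `k`, `stride`, `bandwidth` | 15, 5, 100 | bp | anchor density vs speed; band width absorbs indel drift |
| duplex reciprocal overlap | 0.8 | fraction | exposed flag (see above) |

## The simulator, and what passing tests do not show

`make_genome()` plants repeat families into i.i.d. background (uniform
base composition by default; a GC knob exists because GC only matters
for seed-collision rates). Planted boundaries are *hardened*: the
background base adjacent to each free copy is reassigned whenever two
copies of a family would share an oriented neighbor base, so the
planted length is exactly the maximal repeat length and the truth
catalog is recovered verbatim rather than ±a few lucky bases. The
`preset_genome()` preset is a 100-kb circle with an 8,986-bp IR
pair, a 1,467-bp DR pair carrying a 188-bp repeat nested at positions
1,173–1,360 plus a free inverted third copy, and 564/317/161-bp minor
pairs — the geometry the analysis is designed around, at about half the
length of a real mitogenome to keep test runtimes proportionate.

`simulate_reads()` draws, per read: a form from the mixture, a circle
within the form proportional to length, a uniform start, a
truncated-lognormal length (HiFi-like default: mean 15 kb, σ_log 0.35,
truncated to 1–50 kb and to the circle length; an ONT-like setting
raises the mean and error rates), a uniform strand, and i.i.d.
per-base substitutions/insertions/deletions (≤ 0.1 each). Everything is
deterministic given the seed, to the byte in FASTQ output.

What this emulates is the *statistical* structure the analysis assumes:
junction-spanning read counts are binomial in the mixture proportion,
which is why closed-loop tests demand recovery within three binomial
standard deviations of the assigned-read count (scenarios at
alternative proportions 0.5, 0.78 and 0.98 with 2,000 simulated reads
each). What it does not emulate: realistic HiFi/ONT error profiles
(homopolymer indels, quality-correlated errors), chimeras beyond
duplex fold-backs, biased genomic coverage, or diverged repeat copies.
Passing tests therefore demonstrate correctness of the accounting and
classification machinery, not robustness to every artifact of real
sequencing runs — for real data the aligner contract can be satisfied
by an external long-read mapper upstream, feeding alignments into
`classify_read()`.

## Numerical and degenerate-input choices

* **Rounding**: percentages round half away from zero to 2 decimals
  (`round_half_up()`); base `round()`'s half-even rule disagrees with
  published support tables on ties.
* **Canonicalization**: least rotation by iterative candidate
  refinement on byte values (locale-free); ties across the full period
  mean the survivors are identical rotations, and the
  forward/reverse-complement winner is chosen by byte comparison.
* **Repeat finder**: seeds are exact `min(min_len, 64)`-mers (20-mers
  in relaxed mode); `N` never seeds or extends (treated as a universal
  mismatch); hits whose copies overlap on the circle (tandem
  arrangements) are out of scope and dropped; equal-length families
  order by first copy position; copies may wrap the origin and are
  reported with `end > n`.
* **Inversion arc**: the arc strictly between the copies in
  rotation-to-copy-1 frame is inverted and the product is rotated back,
  so both copies keep their coordinates; inverting the complementary
  arc yields the same canonical form (tested), which is why the
  convention is safe.
* **Enumeration naming**: repeat-1 inversions toggle `MC1`/`MC2`;
  other events append `^k`, with copy letters only for ≥3-copy
  families. After an event, copies are re-located by exact search, so
  for ≥3-copy families the letters attached to a *subsequent* event
  reflect position order in the current circle rather than provenance
  of the original letters — a documented approximation; de-duplication
  by canonical form is unaffected.
* **Shadowed pairs** (both copies nested in copies of one larger
  family) are skipped by the pipeline with a logged notice: their
  junction evidence is indistinguishable from the outer family's.
* **Empty support**: a pair with no assigned reads emits counts 0 and
  blank rates rather than dividing by zero.

## Problem sizes in the test suite

Brute-force oracles bound the sizes: the maximal-repeat oracle scans
all $n$ diagonals and anti-diagonals of the full self-comparison, so
oracle-equivalence tests run on 0.9–1.6-kb circles (several layouts ×
seeds, planted and repeat-free); recombination round-trips use 500
random toy circles of a few hundred bp; closed-loop mixture recovery
uses the 100-kb preset with 2,000 reads per scenario; the end-to-end
pipeline test uses 120 reads. These sizes are the package's choices for
a suite that a maintainer can run routinely; every algorithmic path
they exercise is size-independent.

## Known limitations

* Relaxed identity (< 1) extends through substitutions only; diverged
  repeats with indels are fused or truncated conservatively.
* The native aligner is not base-accurate under indel noise — spans
  come from anchors plus exact extension — so flank-overlap decisions
  near the exact 1,800-bp boundary can flip for high-indel reads; the
  published-style thresholds leave hundreds of bp of slack for typical
  junction-spanning reads.
* Stoichiometric population dynamics, linear/concatemer in-vivo
  structures and repeat masking are out of scope.
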