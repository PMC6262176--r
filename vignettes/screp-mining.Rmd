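---
title: "Mining secreted cysteine-rich repeat proteins by self-alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining secreted cysteine-rich repeat proteins by self-alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screpmine)
library(dplyr)
```

## The problem

Secreted cysteine-rich repeat proteins (SCREPs) carry two or more
disulfide-rich domains in tandem on one polypeptide. The few that have been
characterized pharmacologically — double-knot spider toxins acting on TRPV1,
double-ICK inhibitors of ASIC1a, tandem Kunitz protease inhibitors — share a
bivalent mode of action: two homologous domains engaging a (often
symmetric) target simultaneously, with large gains in avidity and
selectivity. Finding more of them in sequence databases is a pure
primary-sequence problem: for most candidates there is no structure, often
not even a useful annotation. `screpmine` implements a complete desk-scale
toolkit for that search: tandem-repeat detection by self-alignment,
candidate refinement, domain-architecture classification, and homology
screening against reference toxin sets.

## The detection model

The detector asks a simple question of every mature sequence: *does some
prefix of the protein align well to the remaining suffix?* A division site
is slid along the sequence in increments of $n$ residues (default
$n = 10$). At each site $k$ the prefix $s[1..k]$ and suffix $s[k+1..L]$ are
locally aligned under BLOSUM62 with affine gap penalties (open 11, extend
1), i.e. a gap of length $g$ costs $11 + g$. A tandem duplication produces
a sharp maximum in this split-score profile at the true domain boundary: at
that split the two repeat copies face each other and the local alignment
recovers (up to divergence) the unit self-score. The call rule is:

* **strong** — some split scores strictly above 30 (raw score);
* **weak** — the best split score is positive but at most 30;
* **none** — no positive-scoring split, or the sequence failed the
  prefilter.

Only strong calls proceed downstream.

Before scanning, candidates are prefiltered on simple features of the
*mature* sequence (the signal region, when annotated, is removed first;
signal prediction itself is out of scope and cleavage sites are consumed as
two-column annotations): length between 20 and 500 residues inclusive — the
lower bound excludes short low-complexity repeats, the upper bound excludes
large multi-pass receptors — and at least 4 cysteines, the minimum for one
disulfide per domain in a two-domain protein. Selenocysteine (`U`) is never
counted as cysteine.

Several details of this scheme were genuinely open and are fixed here as
package policy:

* The >30 threshold applies to the **raw** Smith–Waterman score, not the
  bit score: BLOSUM62 raw scores are what the split comparison produces,
  and 30 raw is the scale on which the strong/weak split was defined. A
  best score of exactly 30 is weak (the strong rule is strict).
* Both segments must be at least $n$ residues long, so 1–9-residue stubs
  are never aligned; for a length-$L$ sequence the admissible sites are the
  multiples of $n$ up to $L - n$.
* A strong score at *any* single split suffices; no multi-split support is
  required. Scores are not length-normalized.
* Ties in the profile resolve to the smallest split position, making output
  deterministic.

### Exact alignment rather than heuristic search

All alignments are computed exactly (Smith–Waterman / Needleman–Wunsch with
affine gaps, via Biostrings' C implementation) rather than by a seeded
heuristic search, and no composition-based score adjustment or edge-effect
length correction is applied. Exact scores are never below heuristic ones
and are bit-reproducible, which makes every threshold decision exact and
every rerun identical. The flip side matters for nulls: on
composition-biased sequences — and everything this package looks at is
deliberately cysteine-rich, with C–C scoring +9 — exact unadjusted optima
run higher than composition-adjusted heuristic scores, so chance
self-alignments clear a raw-score-30 bar noticeably more often than they
would under a heuristic, composition-adjusted scorer. The shuffled-decoy
null computed by the acceptance script quantifies this directly; it is the
operating characteristic of the exact scorer, not a detection failure (at
divergence up to 0.4 the true-positive margin is several-fold above the
threshold).

## Alignment statistics

Homology screening converts raw scores to Karlin–Altschul bit scores and
E-values:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-S'}$$

with the published gapped BLOSUM62-11/1 constants $\lambda = 0.267$,
$K = 0.041$, query length $m$ and search space $n$ equal to the total
residue count of the reference set. A hit passes the screen when
$E \le 10^{-6}$ **and** bit score $> 35$; the two thresholds are applied
jointly (the stricter reading), each independently configurable.

## Refinement

Three refinement operations clean the raw strong-hit set:

* **Cysteine-density profiling.** Density is $100 \cdot \#C / L$ on the
  mature sequence, binned half-open at 1% width. Cysteine density is
  characteristic of a domain type, and the 2–3% band is where
  heme-coordinating and redox-active proteins concentrate.
* **Annotation-driven exclusion.** Proteins whose cysteines are catalytic
  or metal-coordinating rather than disulfide-forming (cytochrome c's
  CxxCH heme attachment, thioredoxin's active-site dithiol) self-align
  convincingly without being disulfide-rich repeats. A record is removed
  iff one of its domain annotations matches a configurable exclusion term
  (case-insensitive substring) or accession; unannotated records are always
  kept, and only annotation-matched records are ever removed — never whole
  density bins.
* **Redundancy clustering.** Greedy incremental clustering at ≥99%
  identity: sequences sorted by length descending (ties by accession) each
  join the first cluster whose representative they match, where identity is
  identical aligned columns of the global alignment divided by the shorter
  sequence's length; otherwise they found a cluster. This reproduces the
  greedy strategy of cd-hit at desk scale with exact identities and no
  k-mer prefilter — the prefilter can only split clusters, never merge
  more, so clusters here are at worst coarser. At a 99% threshold one
  substitution splits a 50-residue pair (49/50 = 0.98) but not a
  100-residue pair (99/100 = 0.99); this length sensitivity is inherent to
  the threshold, not to the implementation.

## Architectures and repeat purity

Domain annotations (InterProScan TSV, 1-based inclusive coordinates) are
ordered along the sequence and rendered as bracketed letter strings, with
letters assigned by first appearance of each distinct domain type: `[AA]`
is a pure two-domain repeat, `[ABB]` a combinatorial repeat (a repeated
type plus at least one unit of another type), `[A]` a non-repeat.
Overlapping annotations of the same type merge when the overlap exceeds
half the shorter interval; across types the earlier-listed annotation wins
under the same rule — InterProScan output routinely contains nested and
duplicated matches and some such policy is required; this one is simple and
deterministic.

**Repeat purity** is the mean pairwise sequence identity between the
repeating units, computed over the most-copied domain type (ties: the type
appearing first), with identity taken from the global alignment over its
full length including gap columns — units are pre-delimited domains, so an
end-to-end alignment, not a local one, is the right comparison. Two
identical units give 100%; purity is undefined (an error) when no type has
two units.

## The synthetic benchmark generator

Because the interesting invariants are statements about ground truth
("strong at the true split", "decoys rejected"), the package ships a
deterministic generator rather than curated fixtures. A synthetic SCREP is
built from one random unit (default 35 residues, uniform over the 19
non-cysteine residues, with cysteines pinned at six knottin-like offsets
{2, 9, 16, 21, 27, 32}); later copies substitute each non-cysteine position
independently with probability `divergence`; units are joined by
low-complexity G/S linkers (default 5 residues, the short-flexible-linker
regime of the known two-domain toxins); an optional hydrophobic-biased
signal prefix is prepended. Ground truth (unit boundaries, split positions,
architecture string, divergence) is carried on the record. Decoys cover the
three false-positive classes the refinement stage exists for: residue-level
shuffles of a SCREP (same length and composition, no tandem structure),
cytochrome-c-like CxxCH decoys in the 2–4% density band, and low-cysteine
records that must fail the prefilter.

What the generator deliberately does *not* emulate: real domain families
(units are i.i.d. random, so inter-family sequence similarity structure is
absent), realistic residue frequencies (uniform background), propeptides
between domains, fragmentary database entries, and annotation noise.
Passing the synthetic suite therefore demonstrates the machinery is
correct — boundaries found exactly, thresholds applied exactly,
determinism — not that real-database precision/recall matches any
particular figure.

## Numerical and degenerate-input policy

* All internal interval arithmetic is 0-based half-open; external formats
  (InterProScan, signal annotations) are 1-based inclusive and converted at
  the parsing boundary only.
* The empty local alignment (score 0) is legal and reported with zero-width
  ranges; `AAAA` vs `GGGG` has no positive-scoring residue pair and scores
  exactly 0.
* Length bounds 20/500 are inclusive; cysteine minimum 4 is inclusive.
* Alignment tracebacks are Biostrings' deterministic traceback; score ties
  elsewhere (best split, cluster representative, purity type) all resolve
  to the smallest position / lexicographically smallest accession.
* Sequences may contain `X/B/Z/U`; `*` is stripped on input with a warning;
  anything else is a hard parse error with a line number.

## Problem sizes

The test and acceptance workloads are sized for interactive use: 200
random-pair oracle comparisons, 20 synthetic positives per divergence
level on the grid {0, 0.1, 0.2, 0.3, 0.4}, 200 shuffled decoys for the
scan null and 50 for the homology null, and a 100-record (50 distinct)
clustering set. These sizes give binomial standard errors of a few percent
on the reported rates while keeping a full run in minutes on one core.

## Known limitations

* O(n²) clustering and all-vs-all screening are desk-scale by design;
  database-scale runs need the heuristic tools this package mirrors.
* Raw-score thresholds on exact, composition-unadjusted alignments are
  liberal on cysteine-rich nulls (see above); users wanting stricter nulls
  should raise `strong_threshold` knowingly rather than assume
  heuristic-search behavior.
* Signal regions and domains are consumed as annotations, never predicted.
* Proteolytic processing between domains is not modelled: a multi-domain
  precursor that is cleaved into single-domain products will still be
  reported as a repeat protein.
* A single scan pass detects two-segment self-similarity; higher copy
  numbers are recovered from domain annotations, not from the scan itself.
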