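---
title: "Designing oligo FISH probes for repetitive DNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing oligo FISH probes for repetitive DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfish)
```

## The problem

Satellite DNA — long tandem arrays of a repeated monomer, such as the
~171-bp alpha-satellite monomer at human centromeres — is difficult to
target with conventional single-copy FISH probe designs, which mask
repeats away before mining oligos. `repfish` takes the opposite approach:
it looks *for* the repeats, designs oligos against them so that one probe
sequence binds hundreds to thousands of sites in a compact genomic
interval, and screens every candidate genome-wide so that the predicted
binding stays confined to the intended interval.

The pipeline has four stages, each exposed as ordinary functions and
chained by `run_pipeline()`:

1. **Repeat discovery** from genome-wide k-mer counts;
2. **Candidate mining** under length/Tm/GC constraints;
3. **Ranking** by target-specific k-mer enrichment;
4. **Selection** by in-silico specificity profiling (alignment
   enumeration + duplex-probability scoring + binned off-target culling).

## Repeat discovery

The genome is counted at a fixed k (default **k = 18**, configurable),
strand-specifically and with no canonical collapsing: a k-mer and its
reverse complement are distinct keys. This choice changes every
downstream count sum, so it is worth stating clearly: all R~m~/H~m~
quantities in this package are forward-strand occurrence sums.
N-containing windows contribute nothing.

Each scaffold position then carries the genome-wide count of the k-mer
starting there. A position is *flagged* when its count strictly exceeds
the threshold `T` (default 10); a sliding window of `W` positions
(default 3000, step 1) is *repeat-positive* when the fraction of flagged
positions in it is at least the composition score `C` (default 0.5).
Overlapping positive windows merge into maximal runs.

Two deliberate choices here:

* **Composition rule.** "Sum of counts over the window" and "fraction of
  flagged positions" are both defensible window statistics; we default to
  the binarized fraction (a count either passes `T` or it does not), with
  the raw-mean rule available as `composition_mode = "mean"`. The
  binarized rule makes `C` scale-free in copy number.
* **Trimming.** A raw union of positive windows pads every array with up
  to `W·(1−C)` bp of background on each side — at the defaults, 1.5 kb of
  noise per flank. Each merged run is therefore trimmed to the span of
  flagged positions it contains before the final `k − 1` bp extension
  that covers the last k-mer's footprint. On planted-array fixtures this
  raises the Jaccard overlap with the true array from ~0.63 to >0.99.

Both `T` and `C` are monotone: raising either never grows any interval,
a property the test suite asserts against an exhaustive window-scan
oracle.

## Thermodynamics

All melting temperatures come from unified nearest-neighbor ΔH/ΔS
dinucleotide parameters (shipped as a versioned TSV in `extdata`), with
initiation terms per terminal base pair, the monovalent-salt entropy
correction `ΔS + 0.368·N·ln[Na⁺]`, and a linear formamide correction of
−0.65 °C per percent formamide. Probe mining windows on the
formamide-adjusted Tm at 50% formamide and 0.39 M Na⁺, matching a 2×SSC /
50%-formamide hybridization recipe.

Binding-site scoring uses a **two-state duplex model**: for an aligned
probe/site pair, ΔG° at the hybridization temperature (default 69.5 °C,
0.39 M Na⁺) accumulates over matched nearest-neighbor stacks; each
mismatched or gapped column breaks the stacks it touches and contributes
a destabilizing penalty equivalent to **+1.0 kcal/mol at 69.5 °C**. The
fraction duplexed `p_dups ∈ [0, 1]` solves the bimolecular mass-action
quadratic at equal strand concentrations (default 10⁻⁶ M each).

Choices worth knowing about:

* The penalty is carried as an entropic term (−2.918 cal mol⁻¹ K⁻¹ per
  bad column, which is +1.0 kcal/mol at 69.5 °C) rather than a
  temperature-independent free energy. A fixed ΔG penalty would make the
  duplex fraction of stack-free pairs *rise* with temperature; the
  entropic form keeps `p_dups` non-increasing in temperature for every
  pair, which is the physically expected stringency behavior.
* This is deliberately a two-state approximation, not a partition
  function over secondary structures. Absolute `p_dups` values are
  therefore model-specific; everything downstream (On~T~, Off~T~,
  binding proportion, bin aggregates) uses sums and orderings, which the
  two-state model preserves: perfect duplexes outrank singly mismatched
  ones, which outrank doubly mismatched ones, strictly.
* No divalent-cation correction is applied; the default model has
  magnesium at 0.

## Candidate mining and ranking

Within each target interval a greedy left-to-right scan grows a window
from `min_length` (25 nt) until its adjusted Tm reaches `min_temp`
(42 °C), emits it if all of length ≤ 50 nt, Tm ≤ 52 °C and GC within
20–80% hold, and resumes *past* the emitted probe, so candidates never
overlap. Windows containing N are skipped. Exact duplicate sequences —
ubiquitous when mining a tandem array — are removed, first occurrence
kept.

Each candidate is scored by its aggregate k-mer counts: R~m~ within the
target (direct scan of the target sequence, so boundary-straddling
occurrences do not count), H~m~ genome-wide, and the enrichment
K~b~ = R~m~/H~m~. Candidates are ordered by the Normalized Rank

$$N_r = \frac{R_m}{\max(R_m)\,c_1} + \frac{K_b}{\max(K_b)\,c_2}$$

with maxima over the target's own candidate set and user weights
`c1_val`/`c2_val` (default 1 each; no external default exists, and the
score is scale-free in R~m~ either way). Ties break deterministically by
genomic start, then sequence. Walking down the ranking, a candidate whose
*distinct* k-mer set overlaps the running union of accepted candidates'
k-mers by more than `mer_cutoff` (default 0.95) is dropped — the
running-union reading, chosen over pairwise comparison because the
filter's purpose is set-level novelty. Sets, not multisets, define the
overlap proportion; multiplicity is already captured by R~m~.

## Alignment enumeration

Candidate binding sites are enumerated natively by seed-and-extend: an
exact-match index of all genomic `seed_length`-mers (default 15) anchors
every probe seed (both strands are always searched), and each anchor is
extended by local Smith–Waterman alignment with match +2, mismatch −6,
gap open −5, gap extend −3. Hits qualify when their score reaches
`1 + 4·ln(L)` for a probe of length `L`; overlapping extensions collapse
to the best-scoring site per locus and strand; at most `max_alignments`
(default 500 000) hits return, best first. Seed sensitivity to one
mismatch is approximated by probing all one-substitution variants of each
seed whenever the index holds fewer than 10⁷ positions.

Minus-strand hits are reported in forward coordinates, with the target
row of the aligned pair reverse-complemented so both rows read in the
hybridization frame — a match column means a Watson–Crick pair. On exact
tandem fixtures the hit count equals the planted copy number, which the
suite checks against an exhaustive window-scan oracle; equivalence with
any external aligner's hit set is explicitly *not* a contract.

## Specificity profiling and selection

Every hit's `p_dups` is summed into On~T~ (hits overlapping the target by
≥ 1 bp) and Off~T~ (all others);
`binding_prop = On_T / (On_T + Off_T)`. Scores also aggregate over a
fixed genome tiling (default bin size 1 kb at fixture scale, 1 Mb
intended at genome scale); a hit straddling a bin edge belongs to the bin
containing its midpoint, so bin sums conserve On~T~ + Off~T~ exactly.

Selection walks the ranked candidates strictly in order. A candidate is
accepted iff

* `on_t ≥ min_on_target`,
* `binding_prop ≥` the configured floor (default 0.9),
* no non-target bin's aggregate exceeds `off_bin_thresh`, and
* its predicted pairwise duplex probability with every already-accepted
  probe is at most `max_pdups_binding` (evaluated by globally aligning
  the two probe sequences in the hybridization frame — an exact duplicate
  pairs perfectly and is always rejected).

The loop stops when the accepted set's aggregate On~T~ reaches
`target_sum`, when `max_probe_return` probes are accepted, or when the
stream is exhausted; the reason is recorded, and a per-candidate log
(rank, accept/reject, failing gate) makes the greedy loop auditable.
The off-bin cull is applied per probe, not to the accepted set's combined
bins: each accepted probe must individually be clean.

Two presets bundle the selection intents: `"conservative"`
(aggregate ≥ 500 predicted on-target events, strict floors) and
`"permissive"` (aggregate ≥ 25, relaxed floors). Their exact numbers are
repository defaults expressing those intents.

## Reporting

Per-bin duplex sums are emitted as bedGraph tracks, raw and min–max
normalized to integers 0–255 (half-up rounding; an all-equal track maps
to all zeros — a flat track carries no signal, so 0 is the honest
degenerate value). The imaging window for a target is the smallest
interval spanning all target-overlapping bins whose raw sum exceeds
`align_thresh`; if none qualifies that is an explicit error, not an empty
interval. The module also carries the small statistics used when
validating probe sets in situ: a two-sided Fisher exact test on 2×2
foci-count tables (`stats::fisher.test` under the hood, with zero-margin
tables returning p = 1 by convention) and half-up rounded percentages.

## The synthetic study fixture

`fixture_spec()` defaults define the study conditions used throughout
the tests and the acceptance script: a **171-bp monomer × 30 copies**
(alpha-satellite-like), per-copy substitution divergence **0.02**,
background GC 50%, and flanks sized so the single-scaffold genome is
exactly **50 kb**. Mutation is substitution-only by default so alignment
oracles stay exact; ground-truth BED intervals delimit the planted arrays
to the base. An optional decoy array with stated identity to the target
monomer exercises the off-target machinery.

What the generator does *not* emulate — and hence what passing tests do
not show about real genomes: higher-order repeat structure, indel-driven
satellite evolution, interspersed repeat families sharing k-mers with the
target, assembly gaps, and genome-scale k-mer backgrounds. The fixture
demonstrates that the machinery is correct, not that any particular
parameter set is optimal for a given genome.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full pipeline on the
50-kb fixture and module-level checks on streams of 10² – 10⁴ positions;
these sizes were chosen so the whole cycle completes in about a minute
while still exercising every stage end to end. The k-mer table and seed
index are plain in-memory hashes, appropriate for assemblies up to tens
of megabases; genome-scale deployments would swap in disk-backed
counting behind the same interfaces.

Degenerate inputs are handled explicitly: intervals shorter than
`min_length` mine nothing; a zero-binding profile is flagged invalid
rather than dividing by zero; `composition` outside [0, 1] and
non-positive `c1`/`c2` are parameter errors; empty selection is a valid
outcome with `termination_reason = "exhausted"`. All pipeline stages are
deterministic; the only randomness in the package is the fixture
generator's, fixed by its seed.

## Known limitations

* The two-state duplex model is not a secondary-structure partition
  function; absolute `p_dups` values should not be compared across
  thermodynamic models.
* Probes are mined from the forward strand only, and k-mer counting is
  strand-specific; palindromic or strand-ambiguous targets deserve a
  manual look at both strands.
* The native aligner's recall contract is stated on fixtures; highly
  diverged binding sites below the seed sensitivity (more than one
  mismatch in every seed window) can be missed.
* No probe secondary-structure or homopolymer screening is performed.
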