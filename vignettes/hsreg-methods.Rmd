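---
title: "Methods: identifying and characterizing human-specific TE-derived regulatory loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing human-specific TE-derived regulatory loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Transposable elements (TEs) are a major source of new transcription-factor
(TF) binding sites in mammalian genomes. In human embryonic stem cells
(hESC), young retrotransposon families — LTR7/HERV-H, LTR5_Hs, L1HS, L1PA2 —
carry binding events for the pluripotency regulators NANOG, POU5F1 (OCT4)
and for CTCF. A binding site is *human-specific* in the operational sense
used throughout this package: a 200-bp window centered on the ChIP-defined
binding event that maps uniquely within human assemblies but fails
chain-based liftover to every rodent and non-human primate genome in a
panel. `hsreg` implements that definition and the downstream
characterization stages as a tested pipeline, exercised end-to-end on a
synthetic multi-species genome with known ground truth.

## Lineage classification model

The unit of analysis is the fixed-width window (default 200 bp; the
midpoint of an even-length peak is the floor of the average, i.e.
left-of-center) around each binding-peak midpoint. For each species, the
window is assessed against the pairwise alignment chains with the human
genome as target:

* *coverage* of a chain = fraction of window bases inside that chain's
  aligned blocks;
* the window is **deleted** in a species (the liftOver "Deleted in new"
  outcome) when no single chain reaches `min_match` (default 0.95, the
  conventional liftOver `minMatch`);
* **maps_unique** / **maps_multi** when exactly one / more than one chain
  reaches it.

Labels follow strict nesting: *primate-specific* = deleted in mouse AND
rat; *human-specific* = primate-specific AND deleted in every non-human
primate of the panel AND mapping uniquely under same-species
alternate-assembly chains (the dual-assembly stability criterion; in
simulation the "alternate assembly" is the same genome, i.e. identity
chains). Everything else is *shared*. Sites on chromosomes absent from a
resource are reported `unassessable`, never silently dropped.

This is deliberately a simplification of liftOver's multi-fragment remap
logic: best-single-chain block coverage is deterministic, testable, and
faithful to the `minMatch` semantics at the 200-bp window scale. Re-running
the classifier on simulated fixtures recovers the planted labels exactly
(sensitivity 1, FDR 0 at default settings) because simulated chains are
exact; real aligner noise would degrade this, which is why `min_match` is a
config knob.

## The synthetic cohort: what it emulates, and what a green test establishes

The generator states one world and the tests measure it; none of its
parameters were revisited after seeing test outcomes.

* A single random ancestral chromosome (default 1 Mb) with
  branch-specific TE insertions: `human` (human only), `primate` (human
  plus all non-human primates), `rodent`, or per-species branches.
  Families have fixed per-seed random consensus sequences: L1-like 6,000 bp
  (a configurable fraction inserted truncated), LTR7-like 450 bp,
  LTR5-like 600 bp; each copy gets point substitutions at 0.5% divergence.
* Chains are **exact by construction**: every non-inserted base maps;
  lineage-specific insertions become `dt`/`dq` gaps. This isolates the
  classifier logic from aligner noise — a green recovery test establishes
  the logic is right, not that real chains are this clean.
* Binding-site windows are planted fully inside human-branch insertions
  (human-specific truth), fully inside primate-branch insertions
  (primate-specific truth) or in ancestral sequence clear of insertions
  (shared truth). Within one TE copy, site midpoints are spaced at least
  1,100 bp apart so a per-site planted signal (e.g. adjacent 5hmC within a
  1-kb window) cannot leak into a neighbouring site's window; requesting
  more sites than there are well-separated slots is a config error.
* LAD and PMD tilings hit their configured genome fractions (defaults
  42.9% and 37%, the published lamina and placental-PMD fractions) exactly
  up to integer rounding, asserted within ±0.5%.
* CpG-context 5hmC calls are planted within 50 bp of 21% and within
  500 bp of 46% of human-specific NANOG sites (the published 100-bp/1-kb
  proximity fractions), plus a planted three-letter strand-asymmetric
  symbol near 10% and uniform background calls.
* A fast/slow gene set (Ka/Ks ~ U(0.6, 1.2) vs U(0.05, 0.3)) carries a 3×
  proximity excess: per-gene proximal-site counts are Poisson with mean 2
  (slow) vs 6 (fast), placed in non-overlapping gene neighbourhoods so each
  planted site is attributable to exactly one gene.
* Per-individual presence of human-specific sites is independent Bernoulli
  at the configured rates (defaults 31.4–43.6% for five modern humans,
  1.5% per archaic individual — the published per-genome conservation
  range and the ~4% aggregate archaic presence).

Not emulated: demography, recombination, selection, aligner noise
(optional in-window substitutions exist to stress `minMatch` but default
off), realistic repeat libraries, and chromatin signal.

## Characterization stages and their conventions

**Repeat association.** A site is "within repeats" when its window
overlaps ≥1 repeat annotation by ≥1 bp — the most permissive reading of
"intersected", consistent with the near-total (99.8%) repeat association
the printed tables show. Each in-repeat site is assigned to the single
maximal-overlap repeat (ties: lower start), so family counts sum exactly to
the in-repeat count; the raw pair table is also available. Full-length L1
calls use the published length bounds 5,962–6,189 bp (configurable), with
an optional divergence ceiling for the young-copy census.

**Domain colocalization.** Domains (LADs, PMDs) are ≥100 kb while windows
are 200 bp, so "inside" is the site midpoint falling within a domain
interval — deterministic at boundaries and equivalent to ≥50%-window
overlap except at domain edges (a tested sanity property). Expected counts
under random placement are `n × fraction` (e.g. 167 × 0.429 = 71.6,
printed as 72), with a two-sided binomial p and, given a finite site
universe, an upper-tail hypergeometric p. Human-specific LADs are human
LADs that lift to mouse (best-chain coverage ≥ `min_match`) and whose
mapped span overlaps none of the four mouse LAD sets (ESC, neural
precursor, astrocyte, MEF); the overlap tolerance defaults to 0 bp — any
overlap disqualifies — and is exposed because no published value exists.
Domain length differences use a two-sided Mann–Whitney test by default
(the source analysis reports a p-value without naming the test; Welch is
available).

**Proximity placement.** The proximity threshold is the arithmetic mean of
nearest-target distances, separately per gene class. Distance is measured
from site midpoint to the gene span (0 inside), with *strict* inequality at
the threshold ("smaller than the mean value"). The summary's
sites-per-gene ratio is distinct associated sites over associated genes
(115/20 = 5.8, 214/46 = 4.7 in the published tables). The Ka/Ks
correlation is offered per-gene and rank-binned (default 4 bins): the
published r = 0.992 over 24 genes is visibly bin-based but the bin count is
unstated, so the choice is surfaced to the user. 10-kb colocalization
events are (site, feature) pairs with midpoint-to-span distance < 10,000;
enrichment is hypergeometric against the TF's full site universe.

**Deamination k-mer census.** "12- to 24-nt single-site C→T mutants of a
24-nt seed" is read as: every substring window of the seed with length in
[12, 24] containing the mutated C — the only reading that yields distinct
sequences of varying lengths from a single-site change. Matching is exact,
case-insensitive, no gaps; both strands by default with palindromic hits
deduplicated per locus; overlapping occurrences count separately. Window
lengths below 8 are allowed (the enumeration examples use length 4) but
warn, since short exact matches are statistically uninformative. The
per-position asymmetry profile splits positions at the overall median of
per-position locus totals and reports the ratio of the two group medians —
the grouping behind the published high/low position sets is not defined, so
this package states its own.

**5hmC patterns.** Proximity uses half-window distance from the midpoint,
strict (`|pos − mid| < w/2`). The "three-letter 5hmC symbol" is
operationalized as three consecutive CpG-context hmC calls whose middle
call is on the opposite strand from the flanks, within a maximum span
(default 50 bp, configurable) — the source describes the pattern only
verbally/graphically, so the geometry is parameterized and documented
rather than hard-coded.

**Individual and archaic conservation.** Presence defaults to full-length
100%-identity conservation of the window sequence; the identity threshold
is exposed. Cells with no retrievable sequence are uncallable and excluded
from denominators. A site is attributed post-split when absent from every
archaic individual; post-split and archaic-present partition the assessable
set. The published 95.7%/4.3% do not equal 794/826 (96.1%) and 32/826
(3.9%); the package reports the raw ratios.

**Creation rates.** Rates are novel-site counts divided by lineage
timelines (mouse: 350 Myr from the zebrafish split; chimpanzee: 75 Myr =
88 − 13 Myr; modern humans: 370,000 yr from the archaic split), expressed
per 100,000 years or inverted as years per new site; accelerations are
ratios of unrounded rates, then rounded to 1 dp, which reproduces every
printed ratio (49.7, 5.7, 4.2, 41.6, 5.5). One printed cell (mouse NANOG
years-per-site 131,718) is inconsistent with its own inputs
(350e6 / 2,657 = 131,727.5); the package reports the recomputed value.

## Numerical and statistical choices

* All internal coordinates are 0-based half-open; 1-based inputs
  (RepeatMasker `.out`) are converted on read. `[a,b) ∩ [b,c) = ∅` always.
* Duplicated intervals are retained (events are counted per event);
  coverage uses a merged copy.
* `hypergeom_tail` uses the log-safe upper-tail `phyper`
  parameterization; `fisher_2x2` computes the two-sided p directly by
  `dhyper` enumeration (sum of table probabilities ≤ the observed, with a
  1e-7 relative slack for ties) and applies the Haldane–Anscombe +0.5
  correction to the odds ratio only when a cell is zero, flagged.
* Pearson p-values come from the t distribution with n − 2 df;
  zero-variance inputs yield a flagged undefined r rather than an error.
* No multiple-testing correction is applied by default (raw p-values are
  reported, as in the source analysis).
* Recovery tests that check several planted rates at once (per-individual
  conservation; repeated binomial placement draws) use simultaneous
  (Bonferroni-corrected) exact binomial envelopes: a joint sequence of
  marginal 95% intervals would fail a fixed seed about a third of the time
  by construction, which tests the arithmetic of coincidence rather than
  the generator.

## Pipeline

`run_pipeline()` drives simulate → classify → {repeats, domains,
proximity, hmc, conserve} → rates from a single config (R list or JSON);
stage dependencies are enforced, every stage writes a TSV plus a manifest
with bundle-relative paths, and identical config + seed give byte-identical
bundles (hash-tested). The report recomputes every percentage from counts.

## Known limitations

* The liftability model scores the best single chain; split remaps across
  several chains (which UCSC liftOver can stitch) are counted as
  `maps_multi` or `deleted`.
* Sequence-level k-mer presence is not positional conservation; chains are
  not consulted by `cross_genome_presence`.
* The synthetic cohort's exactness means green recovery tests bound logic
  errors, not robustness to alignment noise.
* Scale: scanning is intended for fixture-scale genomes (tens of Mb), not
  whole mammalian genomes; no suffix-automaton indexing is attempted.
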