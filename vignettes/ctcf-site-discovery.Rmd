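---
title: "Discovering and classifying CTCF sites in V(D)J recombination loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and classifying CTCF sites in V(D)J recombination loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighctcf)
```

## The problem

The variable (V) region of an immunoglobulin heavy-chain (IgH) locus
spans megabases and carries dozens to hundreds of binding sites for
CTCF, the 11-zinc-finger chromatin organiser. These sites are not
generic: within the V region they share a locus-specific 14-bp
sub-consensus, they lie almost exclusively in one orientation with
respect to V-segment transcription, and they occupy three
characteristic positions — a fixed short gap downstream of a
recombination signal sequence (RSS), a window up to 8 kb upstream of a
V-segment leader exon, or intergenic space away from any gene segment.
`ighctcf` implements the computational side of that analysis as a
reusable, tested pipeline: mismatch-tolerant consensus scanning with
iterative refinement, RSS/leader-anchored classification, orientation
and CpG summaries, hot-spot detection, ChIP peak merging with
predicted-versus-observed overlap tables, and PWM scanning with exact
score p-values.

## The search model

The scanner treats a consensus motif as a fixed-width word and reports
every window, on both strands, whose Hamming distance from the word is
at most `max_mismatch` (default 2). Three modelling choices deserve
justification:

* **Hamming distance, no indels.** A "mismatch" against a fixed-width
  consensus is read as a substitution; insertions or deletions would
  change the register of the zinc-finger contacts and are not part of
  the model.
* **Windows containing N never match**, at any allowance. An ambiguous
  base cannot positively support a binding call.
* **Both strands, overlapping hits all reported.** Hits are
  deduplicated only when interval *and* strand coincide; a palindromic
  window that matches both strands is genuinely two binding
  orientations and is reported twice (a `collapse_palindromes` flag
  collapses them when a single count per interval is wanted).

Minus-strand hits are reverse-complemented into motif orientation
before any counting, so a single position frequency matrix (PFM) — and
hence a single consensus — can be derived from two-strand hits.

**Iterative refinement** (`refine_search`) scans with a seed motif,
derives the per-column majority consensus of the hits, and rescans
until the consensus reproduces itself. Majority ties are broken by the
fixed base order A < C < G < T so the procedure is deterministic; tied
columns are flagged on the returned motif. A converged trace ends with
two identical consecutive rounds, which makes "converged" directly
visible in the round table. This mirrors the two-round search used in
the field: a heterologous seed (for example the chicken β-globin FII
CTCF site, `CCGCTAGGGGGCAG`) finds a first crop of sites, whose
consensus then recruits the rest of the family.

Under a uniform background the expected number of hits is
`2 · (len − L + 1) · Σ_{i≤k} C(L,i)·3^i / 4^L`; for the default 14-mer
at two mismatches that is `862/4^14` per window, about 6.4 hits per
megabase of double-stranded random sequence. The test suite checks the
scanner against this closed form on pure background, and against a
brute-force window enumerator on random instances.

## Site classification

`classify_sites` assigns each hit exactly one class, in priority order:

1. **RSS-associated** — the hit lies 0–60 bp downstream of an RSS
   nonamer, measured in the owning segment's transcriptional
   orientation. The distance convention is the number of bases
   *strictly between* the nonamer 3′ end and the motif edge nearest
   the RSS; with that convention the canonical murine spacing is the
   3-element set {17, 18, 19} bp (about two turns of the double
   helix), and the canonical human set is {19, 48}. The 60 bp
   association window admits the 48-bp human spacing while staying far
   below the older 150-bp proximity criterion.
2. **Upstream** — a leader-exon start lies within 8 kb downstream of
   the hit (again transcription-oriented), binned proximal/mid/far at
   [0, 1.5), [1.5, 4) and [4, 8] kb to mirror the observed ~0.8 kb,
   2–3 kb and 5–6 kb subsets.
3. **Intergenic** — everything else.

For an antisense hit the "motif 5′ start" is ambiguous, so distances
use the hit interval's RSS-proximal edge; the convention is recorded
in every report. RSSs left without an associated site can be re-probed
with `rescue_scan`, a relaxed re-scan (default 4 mismatches) of the
0–60 bp window downstream of each bare nonamer — the in-locus
equivalent of the rescue that recovers sites with three or four
mismatches at a 19 bp gap near otherwise bare V-segment RSSs.

`orientation_summary` reports the majority orientation relative to
transcription; an exact 50/50 tie resolves toward
transcription-concordant and is flagged. `cpg_profile` tests
configurable adjacent position pairs (default (4,5), (6,7), (14,15),
1-based in the motif-oriented core; index L+1 is the first flanking
genomic base) for a CpG dinucleotide — the biological question being
whether methylation could regulate the site. Sites at the sequence
edge that lack the flanking base are excluded from that pair's
denominator. `find_hotspots` chains sites whose start-to-start gap is
at most `max_gap`; because observed hot spots range from three sites
in 100 bp to 50 sites in 2.1 kb there is no single natural gap, so the
default (500 bp) is always echoed in output metadata.

## Peak integration

ChIP peaks whose gap is *strictly* less than 100 bp are merged
(`merge_peaks`), reflecting the ~70 bp CTCF footprint; the boundary is
covered by a dedicated test (gap 99 merges, gap 100 does not), and the
single sorted pass is provably equal to transitive-closure merging.
`venn_overlap` reports occupancy from both perspectives — the fraction
of predicted sites overlapping a peak, and the fraction of peaks
containing a site — because one symmetric region count cannot express
both. Occupancy requires ≥1 bp of overlap by default;
`require_containment` switches to full containment.

## PWM scanning with exact p-values

`pwm_from_pfm` builds base-2 log-odds scores with a
background-weighted pseudocount (default 0.1 per column).
`score_pvalue_table` computes the *exact* null distribution of the
window score under the background model by dynamic programming:
per-cell scores are discretized onto an integer grid (default 1e4 bins
across the score range) and convolved column by column. The scanner
scores windows in the same integer domain, so p-value lookups are
exact with respect to the table; the suite checks the table against
exhaustive `4^L` enumeration for L ≤ 6 and verifies that the total
mass is 1 within 1e-9. The default reporting threshold is p ≤ 1e-4,
the conventional default of FIMO-class scanners, and any JASPAR-format
count matrix can be supplied (e.g. the 20-bp M1 CTCF core motif).

## What the synthetic generator emulates

`generate_locus` is first-class, tested code, not a fixture dump. It
lays gene-segment units on an i.i.d. background: every segment is
leader exon (50 bp), intron (80 bp), coding exon (300 bp) and a
canonical heptamer/23-spacer/nonamer RSS; proximal segments carry an
RSS-associated site at a gap drawn from {17, 18, 19}; distal segments
carry an upstream site at ~0.8/2.5/5.5 kb; intergenic sites (scattered
and as hot spots) sit in gaps buffered by 8.1 kb so they cannot fall
into any leader's upstream window. The defaults are the murine study
conditions: 144 planted sites (44 RSS-associated, 80 upstream, 20
intergenic — the ~30/70 proximal split), minority orientation 2/147,
CpG at the motif 3′ flank in half of the sites, two 3-site/100 bp hot
spots, on a 2 Mb locus (the scale of the murine V region). Segment
geometry (50/80/300 bp) is invented plumbing, recorded in the truth
table, with no biological claim attached.

Two generator modes matter for testing. With **scrubbing** on
(default), windows that accidentally match the planting motif within
two mismatches are re-randomised (never touching planted sites, their
CpG flank, or RSS elements), giving a clean field where scan → classify
must recover *exactly* the planted truth — class, distance, strand and
mismatch count, zero confusion. With scrubbing off the background is
honest, and hit counts are checked against the binomial expectation
above. `generate_peaks` covers a chosen fraction of sites with
jittered, variable-width peaks (default widths uniform on 10–2282 bp,
mean 1146 bp) plus site-free decoys. Hot-spot members are covered as
one unit — one broad peak per hot spot, as a ChIP experiment would see
— and peaks are clipped to stay ≥57 bp from non-member sites so that
sub-100 bp merging can never bridge a peak across a foreign site;
coverage is therefore exact by construction
(`round(fraction · n_sites)` sites occupied), which is what makes the
77% → 111/144 overlap test sharp rather than approximate.

What the generator does *not* emulate: real V-segment sequence
families and their phylogeny, GC-content heterogeneity and repeats
(the background is i.i.d., uniform by default), microarray intensity
noise (peaks are consumed, not called), and evolutionary divergence
between species. Passing the recovery tests therefore demonstrates
correctness of the machinery under the stated geometric conditions,
not performance on real genomic sequence.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  conventions appear only at the GFF3 boundary and in printed reports.
* All randomness flows through one seeded generator per entry point
  (`withr::with_seed`); no global RNG state is disturbed, and equal
  seeds give byte-identical loci, truth tables and JSON reports.
* Consensus ties (A < C < G < T), the orientation tie (toward
  transcription-concordant) and the hot-spot gap default are the three
  places where the field's practice under-determines the algorithm;
  each is deterministic, documented, and surfaced in outputs.
* Degenerate inputs fail loudly and early: empty hit lists cannot form
  a PFM, an empty site set cannot form an overlap table, a synthetic
  spec that cannot fit its locus errors before any sequence is
  emitted, and a refinement round with zero hits returns a flagged
  trace rather than throwing.
* Problem sizes in the shipped tests — 150–400 kb loci for recovery
  tests, twenty 3 Mb backgrounds for calibration, 2 Mb for the full
  study conditions — were chosen so each property is exercised at a
  scale where its statistics are meaningful while the whole suite
  stays comfortably interactive.

## Known limitations

Real-locus reproduction of the printed murine/human counts requires
the GenBank/mm9 sequences and annotation releases used in the original
analysis; the package deliberately ships no downloader, so those runs
are an exercise for users with the files in hand (the BED/GFF3/FASTA
readers accept them directly). Classification assumes annotations and
hits share a coordinate system; cross-chromosome hits are classified
intergenic with a warning. The PWM p-value grid introduces a
discretization error bounded by the bin width times motif length;
1e4 bins keeps it far below any threshold used in practice.
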