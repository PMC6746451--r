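# ighctcf

CTCF binding-site discovery and classification in immunoglobulin
heavy-chain (IgH) loci.

## What this package does

The V region of an IgH locus carries a family of CTCF binding sites
with three striking regularities: they share a locus-specific 14-bp
consensus distinct from the genome-wide CTCF motif, they lie almost
entirely in one orientation with respect to V-segment transcription,
and they occupy three characteristic positions relative to the gene
segments — a fixed ~18 bp gap downstream of a recombination signal
sequence (RSS) nonamer, a window within 8 kb upstream of a V-segment
leader exon, or intergenic space. `ighctcf` implements the
computational analysis of such loci:

* **Mismatch-tolerant consensus scanning** — every window `w` on both
  strands with Hamming distance `d(w, m) ≤ k` from a consensus `m`
  (default `k = 2`); expected background hits follow
  `2·(n−L+1)·Σ_{i≤k} C(L,i)·3^i / 4^L`.
* **Iterative consensus refinement** — scan with a seed, rebuild the
  per-column majority consensus from the hits, rescan until the
  consensus reproduces itself (deterministic tie-break A<C<G<T).
* **Site classification** — RSS-associated (gap to nonamer 3′ end in
  {17,18,19} bp canonical, ≤60 bp associated), upstream
  (proximal/mid/far bins over [0,8] kb to the leader start) or
  intergenic, plus a relaxed rescue scan over RSSs left bare.
* **Orientation, CpG and hot-spot summaries** — strand bias relative
  to transcription, CpG dinucleotides at configurable motif positions
  (default pairs 4/5, 6/7, 14/15), single-linkage site clusters.
* **ChIP peak integration** — strict `<100 bp` gap merging, width
  statistics, and predicted-vs-observed overlap (Venn) tables from
  both the site and the peak perspective.
* **PWM scanning with exact p-values** — base-2 log-odds matrices from
  JASPAR-format counts, exact null score distributions by dynamic
  programming over a discretized grid, FIMO-style `p ≤ 1e-4` default.
* **A ground-truthed synthetic locus generator** — V-segment units
  (leader/intron/coding plus heptamer–23-spacer–nonamer RSS) with
  planted sites of every class, controlled mismatches, orientation
  minority, CpG flanks, hot spots and noisy peaks, so every stage is
  testable without downloads.

It is aimed at computational immunologists and regulatory genomicists
who want the published analysis recipe as composable, audited
functions rather than a one-off script. All coordinates are 0-based
half-open internally; BED/GFF3/FASTA/JASPAR files are the interchange
formats.

## Worked example

Simulate a 150 kb locus with 17 planted sites and ChIP-like peaks over
77% of them, then run the full pipeline:

```r
library(ighctcf)

spec <- synthetic_locus_spec(length_bp = 150000, n_proximal_segments = 8,
                             n_distal_segments = 5, n_intergenic_sites = 4,
                             n_hotspots = 1)
sim <- generate_locus(spec, seed = 1)
pk  <- generate_peaks(sim, coverage_fraction = 0.77, seed = 2)

cfg <- pipeline_config(
  locus = sim$locus,
  annotations = list(segments = sim$segments, rss = sim$rss),
  motif = spec$motif, peaks = pk$peaks, quiet = TRUE)
run_pipeline(cfg)
```

```
== CTCF site analysis: synthetic_VH_locus (150000 bp) ==
search motif: GACCAGCAGGGGGC (max 2 mismatches, refinement converged)
  round 1: GACCAGCAGGGGGC -> 17 hits
  round 2: GACCAGCAGGGGGC -> 17 hits
sites: 17 total (113.33 per Mb)
  RSS-associated 8 (canonical 8), upstream 5, intergenic 4
orientation: 17/17 (100.0%) with transcription
CpG cpg_4_5: 1/17 (5.9%)
CpG cpg_6_7: 0/17 (0.0%)
CpG cpg_14_15: 5/17 (29.4%)
hot spots (gap <= 500 bp): 1
rescue: 5 bare RSS(s), 0 relaxed site(s) recovered
peaks: 28 merged (from 31), widths 53-2775 bp, mean 1147 bp
  occupied sites: 13/17 (76.5%); peaks with site: 11/28 (39.3%)
note: no PWM supplied; skipping PWM overlap stage
```

Reading the report: the search recovered all 17 planted sites
(8 RSS-associated, every one at a canonical 17–19 bp gap; 5 upstream;
4 intergenic, three of them forming the one planted hot spot). All
sites run with transcription, 5/17 carry a CpG across the motif
boundary (positions 14/15), and 13/17 sites (76.5%) fall under a
merged ChIP peak — the coverage fraction the peak simulation was asked
for. The five "bare" RSSs belong to distal segments, whose sites are
upstream rather than RSS-associated, and the relaxed rescue scan
correctly finds nothing near them. With `out_dir` set, the same run
writes `sites.tsv`/`sites.bed`, `hotspots.bed`, `merged_peaks.bed`,
`summary.json`, `config.json` and a plain-text report; two runs on the
same inputs produce byte-identical JSON.

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/scripts/igh-ctcf-pipeline.R`.

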