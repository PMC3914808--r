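---
title: "Methods: fusion calling, copy number, somatic filtering and ploidy in pairfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion calling, copy number, somatic filtering and ploidy in pairfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairfuse)
```

`pairfuse` packages the computational arms of a flow-sorted tumor
whole-genome study — the kind of workflow applied to
well-differentiated liposarcoma (WDLS), where tumor nuclei must be
sorted by DNA content before sequencing and the genome is dominated by
focal amplification and rearrangement of chromosome 12. This vignette
is the package's own account of the models and procedures it
implements, the parameters that matter, the design decisions taken
where the procedure was genuinely open, and what the synthetic-data
tests do and do not demonstrate.

## Read-pair geometry and the anomalous-pair model

A paired-end library is summarized by an `insert_model()`: mean outer
insert size $\mu$, standard deviation $\sigma$, read length $L$, and a
concordance multiplier $k$. Defaults are $\mu = 500$, $\sigma = 50$,
$L = 101$, $k = 3$, describing a ~500 bp size-selected, 2×101 bp
library. The realized post-alignment insert distribution of such a
library is not published for the motivating study; Normal(500, 50) is
an explicit assumption of the model object, and every threshold
derived from it is configurable.

Pairs are stored mate-canonically (`(chrom1, pos1) <= (chrom2, pos2)`
under natural chromosome order) and classified by strand configuration
and outer span $s = pos_2 - pos_1 + L$:

| strands (canonical) | same chromosome | orientation |
|---|---|---|
| `+ -` | $s \in [\mu - k\sigma,\, \mu + k\sigma]$ (inclusive) | `CONCORDANT` |
| `+ -` | span outside the window | `FACING` |
| `- +` | any | `OPPOSING` |
| `+ +` | any | `SAME_FORWARD` |
| `- -` | any | `SAME_REVERSE` |

Interchromosomal pairs are always anomalous, with orientation read off
the same strand table. The mapping between strand configurations and
the report vocabulary (`Facing`, `Opposing`, `Same direction –
forward/reverse`) is a convention of this package: the vocabulary is
standard in fusion-validation tables but rarely defined formally, and
this mapping — mates pointing toward each other, away from each other,
or the same way — reproduces it deterministically. The boundary spans
$\mu \pm k\sigma$ are concordant (inclusive) so that the rule has no
measure-zero gap. "Anomalous" has no published numeric definition in
this setting; $\mu \pm 3\sigma$ is our operationalization, and the
choice is surfaced as `concordance_k`.

## The sliding-window fusion caller

The caller approximates a sliding-window scan with fixed tiling
windows of size $w = \mathrm{round}(\mu + 3\sigma)$ (650 bp by
default) — "based on the insert size" in the sense that one anomalous
fragment's mates concentrate in one window per side. Fixed tiling was
chosen over a literally sliding window for determinism and
testability; the cost (a junction whose straddling mates split across
a window boundary produces duplicate links) is repaired downstream by
merging candidates that share a gene pair and orientation, summing
support and keeping the innermost breakpoints.

The stages, each an exported function:

1. **Germline blacklist** (`summarize_windows()`, `build_blacklist()`):
   windows where the *normal* sample shows an anomalous-mate fraction
   ≥ 0.2 or a poorly-mapped (mapq < 20) fraction ≥ 0.5, with at least
   10 mates of evidence, are ignored. The fractions and floor are
   package defaults — the motivating workflow states the rule but no
   numbers — and are exposed in `caller_params()`.
2. **Linking** (`link_windows()`): anomalous pairs with pair mapq ≥ 20
   vote for their (window, window) combination; links touching a
   blacklisted window are dropped, as are links with fewer than
   `min_support = 3` pairs. We count *pairs*, not single reads: a
   fragment is one observation of one junction.
3. **Annotation** (`annotate_fusions()`): a link becomes a candidate
   only when both windows overlap a *coding* gene body and the genes
   differ. Gene bodies (not CDS exons) implement the coding-region
   restriction because validated fusion breakpoints are routinely
   intronic. Gene assignment is by maximal overlap, exact ties broken
   lexicographically. The candidate's orientation is the modal
   orientation of its supporters (ties resolved in a fixed class
   order), and breakpoints are the innermost supporting mate edges:
   the maximal 1-based end of `+` mates, the minimal start of `-`
   mates, per side. Single-base breakpoints are reported to match
   validation-table conventions; their accuracy is bounded by $w$.
4. **Partner filter** (`partner_filter()`): a candidate passes when at
   least one of its genes has ≥ 2 distinct partners across the
   candidate set. The filter *flags* rather than deletes: validated
   single-partner fusions exist (the packaged table's UHMK1–DDR2 event
   is one), so the multi-partner rule is a prioritization applied to a
   candidate list, not a validity criterion.
5. **Hotspot scan** (`hotspot_scan()`): counts candidates with ≥ 1
   gene in a cluster of interest, e.g. the NAV3/SYT1/PAWR instability
   cluster, where 6 of the 11 events of the packaged validated table
   occur.

The published workflow's final arbiter was manual inspection (IGV) and
PCR validation; `pairfuse` substitutes the deterministic
support/blacklist/partner thresholds of `caller_params()` so the whole
chain is reproducible and testable.

## Copy-number segmentation and breakpoint concordance

No segmentation algorithm is prescribed for the motivating aCGH data
(vendor software is implied), so the package declares its own:
recursive binary segmentation. For each chromosome's ordered probe
log2 ratios, the split maximizing the pooled two-sample $t$ statistic
is accepted iff $|t|$ exceeds the $\alpha$-level critical value
(`alpha = 1e-4`) and both halves keep ≥ `min_probes = 3` probes;
recursion continues in both halves; ties break leftmost; zero-variance
steps with unequal means split with $t = \infty$. The method is
simple, fully deterministic, and checkable against an exhaustive
split-scan oracle, which the test suite does for profiles up to 200
probes. Gain/loss states use ±0.58 ≈ log2(3/2), the conventional
single-copy bound on a diploid background.

`match_breakpoints()` implements the concordance step — confirming
amplification boundaries against sequencing junctions — as greedy
nearest matching within `tolerance = 10 kb` (ties toward the smaller
coordinate), each fusion breakpoint consumed at most once, with
symmetric reporting of unmatched boundaries and breakpoints.

## Somatic SNV filtering

`filter_somatic()` retains a tumor call iff its caller posterior
probability is ≥ 0.8 (inclusive — 0.80 passes), its matched normal
shows *zero* variant-supporting reads, and the tumor shows at least
one. The zero-tolerance normal rule operationalizes
"variant present in the normal" as a read count, the strictest
reading; it makes the filter idempotent and monotone in the threshold
(both property-tested). The probability is consumed as a single
per-record column; whether an upstream caller reports joint or
per-sample posteriors is outside this package's scope.
`select_damaging()` then keeps variants flagged damaging by SIFT
and/or PolyPhen (`damaging_mode = "either"` by default, since
"predicted damaging by SIFT/PolyPhen" is ambiguous between the two);
predictor outputs are inputs here, never computed, and unknown flags
never count as damaging. Indels are accepted in input but set aside
unfiltered with a warning: in the motivating study none validated, and
their error model differs enough that filtering them with SNV rules
would be misleading.

## DNA-content ploidy estimation

A DAPI histogram from a sorted preparation is modeled as a Gaussian
mixture: a diploid G0/G1 reference peak (normal fibroblasts and
diploid stroma), an aneuploid G0/G1 peak at `dna_index` times the
reference channel, and an aneuploid G2/M peak at twice the aneuploid
G0/G1 position. `fit_dna_content()` fits 2 or 3 components by EM on
the binned counts, seeded from the largest local maxima of a
lightly-smoothed histogram (running mean, width 7; peaks below 0.5% of
the maximum or within 10 channels of a taller peak are discarded);
convergence at $|\Delta \log L| < 10^{-8}$ or 500 iterations; a 0.5
channel floor on peak standard deviations guards degeneracy. Peak
seeding replaces the initialization of commercial cell-cycle software;
S-phase, debris and aggregate modeling are deliberately out of scope
(doublet exclusion happens at acquisition), which is the main
limitation relative to such software.

`estimate_ploidy()` anchors the diploid peak at the reference hint
when given, otherwise at the lowest-mean peak carrying ≥ 10% of
events; the ploidy index is $2 \times$ (aneuploid G0/G1 mean / diploid
mean) in N units, the G2/M fraction is the G2/M peak weight over total
aneuploid weight, and a peak only counts as G2/M when it lies within
15% of twice the aneuploid G0/G1 mean (otherwise the fraction is
`NA`). Estimates are scale-invariant in the channel axis
(property-tested). Text reports round ploidy to one decimal ("2.3N");
machine outputs keep full precision.

## The synthetic-data generator

The generator exists to give every stage an input with known truth:

* `build_toy_genome()` — a small multi-chromosome reference (default
  3 × 200 kb, 30 non-overlapping genes) standing in for an assembly
  plus annotation. Coordinates are 0-based half-open internally;
  serialized reports are 1-based, matching validation-table
  conventions.
* `implant_events()` — deletions, tandem duplications, inversions,
  translocations (by join strand) and tandem amplicons (the simulated
  analogue of ring/double-minute amplification). The donor genome is a
  walk of oriented reference segments; the truth set enumerates every
  novel adjacency with its expected orientation class (deletion →
  `FACING`, duplication/amplicon → `OPPOSING`, inversion →
  `SAME_FORWARD` + `SAME_REVERSE`, translocation per join strands) and
  the copy-number consequences. Junction coordinates record the cut
  position on each side, printed as-is. The test suite verifies this
  orientation bookkeeping against a constructive oracle that
  concatenates donor segments base-by-base and reads mate directions
  literally, over all event types and all four translocation
  join-strand choices.
* `simulate_pairs()` — fragments uniform along the donor walk,
  truncated-normal inserts (resampled on violation), mates projected
  back through the segment walk. Requested pair counts are met
  exactly; fragments whose mate would cross a segment boundary are
  resampled, since split-read evidence is a non-goal. Base-level
  sequence and alignment ambiguity are *not* simulated — fusion
  calling here consumes only coordinates, strands and mapq — so the
  simulations exercise the caller's logic, not aligner behavior on
  repeats. Repeat-like regions must instead be *declared* in the
  genome: they emit mapq-0 mates and clustered germline anomalous
  pairs at configured rates (defaults 0.5 and 0.3), which is exactly
  the failure mode the germline blacklist absorbs, and makes blacklist
  behavior testable with known truth.
* `simulate_probes()` — probes every `spacing` bases,
  $\log_2(\text{copies}/2)$ plus Gaussian noise.
* `simulate_histogram()` — the mixture above, binned into ≥ 1024
  channels with exact event conservation. Defaults are the study-case
  preset: DNA index 1.15 (a 2.3N population), G2/M fraction 0.14, CV
  0.04, 50,000 events. The diploid reference channel (200) and the
  diploid event fraction (0.4 — reference fibroblasts plus diploid
  stroma in a sorted preparation) are not stated by the motivating
  study; they were chosen once as realistic and are exposed as
  arguments. When the aneuploid peak lies within $2 \times$ CV of the
  diploid peak the histogram is flagged unresolvable rather than
  rejected.
* `simulate_variant_table()` — truth somatic variants (tumor-only,
  zero normal variant reads) plus germline polymorphisms (≥ 1 normal
  variant read by construction), with configurable fractions of
  somatic records demoted below the 0.8 posterior or flagged damaging.

## Problem sizes and determinism

The shipped tests run the full caller at 30× coverage over a 600 kb,
30-gene genome with six implanted events (≈ 90,000–130,000 pairs), the
segmentation oracle on ≤ 200-probe profiles, and the ploidy recovery
over 20 seeded 50,000-event histograms — sizes chosen so the whole
suite completes in well under a minute while every recovery property
(100% junction recall with ≥ `min_support` straddlers, zero calls on
the matched normal, blacklist suppression, exact somatic truth
recovery, ploidy within ±0.05N and G2/M within ±2 points) is exercised
at the study's stated conditions. All randomness flows through
explicit integer seeds; identical seeds give byte-identical outputs,
which the suite asserts at the file level for the pipeline bundle.

What passing these tests shows is that the *procedures* are correct on
data matching their stated models. What they cannot show: performance
under real alignment artifacts (multi-mapping, soft-clips, chimeric
alignment), real aCGH wave/GC structure, caller-specific posterior
calibration, or cell-cycle features (S-phase, debris) outside the
fitted mixture. Those belong to the upstream tools this package
deliberately does not reimplement.
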