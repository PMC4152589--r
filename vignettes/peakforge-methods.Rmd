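---
title: "Methods and design of peakforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of peakforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design decisions behind
`peakforge`, in the spirit of the methods sections of mature Bioconductor
packages. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Scope and containers

`peakforge` covers the computational stages that surround read mapping and
peak calling in a ChIP-Seq analysis: filtering of mapped reads, duplicate
handling and library complexity, signal-track generation, broad-domain
fold-change filtering, pseudoreplicate/IDR reproducibility bookkeeping,
peak-to-gene assignment, binomial GO enrichment over gene regulatory
domains, and duplicate-distribution diagnostics. Aligners, peak callers
(MACS, SICER) and the IDR copula-mixture estimator itself are consumed as
inputs, not reimplemented: this package is the orchestration and the
bespoke arithmetic around them.

Data live in the Bioconductor containers a practitioner expects:
alignments and peaks as `GRanges` (with a `Seqinfo` genome table),
coverage as per-chromosome `Rle` vectors, mate pairs as two parallel
`GRanges` in a `ReadPairs` object so no filter can ever separate mates.
Internally every coordinate is the 1-based, closed `GRanges` convention;
conversion to and from the 0-based half-open BED family (bedGraph,
narrowPeak/encodePeak, SICER summaries, gene BED) happens only in the I/O
layer, and SAM's 1-based `POS` plus CIGAR reference width defines read
ranges on ingestion. All test oracles for centers, windows and domains
were written against the 0-based half-open arithmetic and converted once.

## Read filtering

*MAPQ.* Reads **below** a cutoff (default 20) are removed, so the boundary
value survives. MAPQ 0 is treated throughout as the aligner's
multi-mapping placeholder. For pairs, a pair is dropped when either end is
below the cutoff; the `keepMultiBothZero` option exempts pairs whose two
ends are both MAPQ 0, preserving repetitive-region signal for marks such
as H3K9me3. The single-end analogue (`exemptMapq0`) applies the same
exemption when the aligner's random-placement mode is in use; it is off by
default because the exemption is usually discussed for pairs only.

*Pair geometry.* Proper pairs must share a chromosome, point toward each
other (FR) and have `|TLEN|` within `[minInsert, maxInsert]`, default
`[1, 1000]` bp. The bounds are configurable because no universal filter
bound exists; 1 kb comfortably brackets standard ChIP fragment sizes.

*Multi-mapper policies.* Mapped pairs fall into three exhaustive classes
by per-end uniqueness (`both_unique`, `one_unique`, `both_multi`); the
policies keep class a, a∪b, or a∪b∪c. Class-c pairs contribute the single
placement the aligner reported — the randomization happened upstream, so
re-sampling alternative placements here would be both impossible (the SAM
carries one placement) and wrong (it would double-randomize).

*Duplicates.* The duplicate key is `(chromosome, 5' position, strand)` for
reads and the two mates' 5' positions plus orientation for pairs. The 5'
position is the alignment start on `+` and the alignment end on `-`,
without soft-clip adjustment — a deliberate simplification relative to
Picard's unclipped-position refinement, adequate because the package's
inputs are filtered, essentially ungapped alignments and its fixtures
carry no clipping. One representative survives per key: highest MAPQ
(pairs: highest mate-MAPQ sum), ties resolved by input order. The
deterministic tie rule is what makes exact oracle tests possible; it is
validated against a brute-force all-pairs comparison in the suite.

*Library complexity* is `afterDedup / totalUniqueMapped`, flagged against
the ~0.8 guideline appropriate at a depth of around ten million reads.

## Signal tracks

Single-end reads are extended from their 5' end to the library's average
fragment length (default 200 bp); pairs become one fragment from the
leftmost mate's 5' end across the observed insert, because actual mate
coordinates resolve fragment-length variability better than any library
average. Fragments — not reads — are the unit of paired-end coverage.

Coverage is exact per-base fragment depth, run-length encoded; the suite
checks it against a naive per-base array on genomes up to 100 kb, and
checks the conservation identity (track mass = total fragment length when
nothing is clipped). bedGraph output omits zero runs. Wig output is
fixedStep with span = step (default 20 bp), and each window value is the
**mean** per-base coverage of the window, the trailing partial window
averaged over its true width. A window mean (rather than start-point
sampling) preserves the conservation identity under aggregation; that
choice is the package's own, since a "coverage at a step size" is
otherwise underspecified. Normalization multiplies values by
`1e6 / librarySize`; the library size defaults to the fragment count that
built the track (post-filter, post-dedup), which is the count the track
actually represents — a pre-dedup size can be passed explicitly.
Normalizing twice is an error rather than a silent rescale.

## Peak tools

Broad-domain filtering keeps SICER islands with fold change ≥ 2. When a
summary lacks the fold-change column, it is derived from raw counts as
`(ip/ipTotal)/(ctrl/ctrlTotal)` with a pseudocount of 1 on a zero control
count; the pseudocount convention is ours, chosen to keep the statistic
finite and monotone in the IP count.

Peak-set comparison counts a peak as overlapped when it shares at least
one base with the other set (half-open: `a.start < b.end` and
`b.start < a.end`); no minimum-overlap fraction is imposed because none is
standard in this context. Top-peak selection sorts by `-log10 p`
(falling back to `-log10 FDR`, then score) descending with coordinate
tie-breaks and keeps `ceiling(f·n)` peaks at fraction `f` (default 0.1).

Peak-to-gene assignment measures the signed genomic distance from the
**peak center** (`floor((start0+end0)/2)`) to each gene's TSS and TES and
reports every gene whose nearer anchor is within 10 kb (default), the
nearest flagged; equidistant genes are all flagged, in gene-id order, so
downstream consumers see ties rather than an arbitrary winner.

## Reproducibility bookkeeping

Replicates are merged by concatenation; pseudoreplicates are a uniformly
random permutation split `ceiling(n/2)` / `floor(n/2)` under an explicit
seed (default 42), deterministic and side-effect-free on the caller's RNG.
IDR values estimated externally for shared peaks (matched by best ≥ 1 bp
overlap) are written into the dual-use encodePeak name column; peaks with
no counterpart receive 1, so consistent peaks are extractable at any
cutoff by a single comparison. The decision rule: rescue ratio
`max/min(n_true, n_merged_pseudo)` and self-consistency ratio
`max/min(n_self1, n_self2)` must both be ≤ 2. Ratios are kept unrounded
internally and presented at one decimal. The conservative list is the
true-replicate count, the optimal list the larger of true and
merged-pseudoreplicate counts.

## Binomial GO enrichment

Each gene carrying at least one ontology term receives a regulatory
domain: proximal `[TSS−U, TSS+D)` (defaults U = 5000, D = 1000 bp,
strand-mirrored) plus extensions of up to UE/DE bp that are truncated
where they would enter a neighbouring gene's proximal domain — the
basal-plus-extension rule popularized by GREAT. A gene's own proximal
domain is never reduced, so proximal ⊆ extended always holds; when a
neighbour's proximal domain already overlaps a gene's own, the extension
on that side is simply zero.

For a term whose domains cover fraction `p` of the annotatable genome
(the union of all genes' extended domains; a whole-genome denominator is
available), with `k` of `n` peak centers inside that union, the p-value
is the binomial upper tail `P[X ≥ k]`, `X ~ Binomial(n, p)`, computed
with `pbinom` and verified against exhaustive outcome enumeration for
n ≤ 12. All peaks are used as trials, including those outside every
domain — restricting `n` to in-domain peaks would change `p`'s meaning
and is noted as the alternative. Multiple testing uses
Benjamini–Hochberg FDR via `p.adjust`.

## Duplicate diagnostics

Reads are assigned to region classes by their 5' position — a point rule,
so disjoint classes partition the library exactly and group totals are
additive. The non-peak background is the complement of peaks padded by
±100 bp; reads falling in the padding belong to neither class (a buffer
around imprecise peak edges). The decile profile sorts peaks by score
descending, splits them into 10 contiguous groups (remainder to the
earlier, higher-confidence groups — deterministic and documented), and
reports each group's duplicate percentage. A strongly negative rank
correlation of duplicate rate with decile is the punctate-TF signature;
a flat profile at the background level is the broad-mark signature.

## The synthetic generator

`simulateReads()` plants non-overlapping peaks, draws background read 5'
positions uniformly over the non-peak complement at `backgroundRate`
reads/bp and peak reads at `enrichment`-fold that density, then creates
duplicates by **re-emitting** existing reads: for a class of `n` originals
and target rate `d`, `round(d·n/(1−d))` re-emissions are drawn with
replacement, so the planted duplicate fraction is exact by construction up
to rounding and the rare positional collision between independent reads.
Peak significance is the Poisson upper tail of the peak's read count
against the background expectation, so per-peak duplicate rates assigned
in descending-confidence order line up with the decile ranking. Paired
mode emits proper FR pairs with inserts ~ Normal(200, 20) truncated at
the read length. SAM records carry minimal mandatory fields, random
bases and constant qualities, since nothing downstream reads base
qualities. Identical config and seed give byte-identical files.

Default study conditions: a 2 Mb two-chromosome genome, 50 peaks of
~300 ± 50 bp, background 0.005 reads/bp, 10× enrichment, 5 % background
duplicates with peak rates graded 55 %→10 % (the TF-like profile), and a
broad-like profile of 30 domains of ~2 kb at 4× enrichment with uniform
5 % duplicates. These sizes give roughly ten thousand reads per library —
large enough for duplicate-rate recovery within two percentage points and
a stable decile trend, small enough that the entire suite runs in minutes
on one core. Parameter-recovery fixtures that assert ±2-point recovery
use 40 peaks of ~2 kb at 8× enrichment so that per-peak re-emission
rounding (~1/n per peak) and positional collisions (~density/2 of reads)
both stay well inside the tolerance.

What the generator does **not** emulate: mappability structure and true
multi-mapping (MAPQ-0 labels are assigned at random), sequencing error,
base-quality variation, soft-clipping, chromatin-driven background
autocorrelation, and replicate-to-replicate biological variability beyond
boundary jitter and score noise. Passing tests therefore demonstrate the
correctness of the arithmetic under controlled conditions, not robustness
to every artefact of real libraries.

## Numerical and degenerate-input choices

Zero read counts make complexity and the reproducibility ratios
undefined; both raise errors rather than returning NaN. A region class
with no reads reports a duplicate rate of 0 with a zero denominator
rather than NaN. Empty tracks serialize as header-only files. Fold-change
and top-peak filters are idempotent subsets. `splitPseudoreplicates`
requires n ≥ 2; `decileProfile` refuses fewer peaks than groups and
suggests lowering the group count. Ties are always broken
deterministically (coordinates, input order, or gene id), so every
reported number is reproducible bit-for-bit under a fixed seed.

## Pipeline and interfaces

`runPipeline()` executes filter → dedup → complexity → tracks →
(fold-change filter | IDR bookkeeping) → gene assignment → GO →
diagnostics from one YAML (or list) config, writing per-stage TSVs and a
JSON manifest whose every number is recomputable from the exported
functions — the report is derived, never independently computed. Stages
fail loudly with the stage name; partial outputs are retained. Execution
is serial by design; cluster scheduling is out of scope. The
`inst/scripts/peakforge.R` wrapper exposes the common operations to the
shell.

## Known limitations

Duplicate keys ignore soft-clipping and optical-duplicate structure; the
IDR estimator is external, so the quality of "shared peak" IDR values is
inherited from it; SICER islands are re-emitted 0-based half-open
regardless of the caller's original convention, which is documented
rather than configurable; and bigWig/TDF output is out of scope — the
bedGraph and Wig files load directly into IGV or convert with standard
tools.
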