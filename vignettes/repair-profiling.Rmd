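---
title: "Normalized excision-repair profiling: model and methods"
author: "excisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized excision-repair profiling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its confounder

XR-seq sequences the oligonucleotides that nucleotide excision repair
releases from damaged DNA. Each aligned read is one repair event: its span
marks where a lesion was removed, its strand is the strand the lesion was
on, and the damage dinucleotide sits at a fixed distance from the read's
3' end — positions (L−7, L−6) of a read of length L, i.e. 20–21 of a
27-mer. Primary excision products are 25–28 nt (modal 27); a second
population at 16–21 nt arises from 5'-exonucleolytic degradation of
primary products.

Read density is therefore repair activity *times* damage opportunity: UV
photoproducts form at dipyrimidines, so a TT-rich region accumulates more
lesions — and more excision reads — than a GC-rich region repaired at the
same per-lesion rate. All quantitative outputs in `excisr` divide this
opportunity out with a simulated background library and report

normalized repair = RPKM_real / RPKM_sim

per feature, where RPKM = count / ((length/1000) · (library/10^6)) and each
library is normalized by its own total. Normalized repair is 1 where the
real library looks like content-matched random sampling of the genome,
and scale-invariant: duplicating every read in both libraries changes
nothing.

## The matched background library

`simulate_matched_library()` builds the background in two steps.

1. **Target profile.** The real library is summarised per read-length
   class L as its exact count n_L and its damage-site dinucleotide
   distribution q_L (16 categories; reads with N in the damage window are
   excluded from the numerator and denominator of that class, and a class
   with no usable damage sites falls back to the pooled distribution with
   a warning).
2. **Sampling.** For each read: draw a dinucleotide d ~ q_L, then
   rejection-sample a uniform genomic window of length L — chromosome
   weighted by length, start uniform, strand equiprobable — until the
   window's damage-site dinucleotide equals d (and, by default, the window
   contains no N). Conditional on d, accepted windows are uniform over all
   windows carrying d, which is the exact sense in which the background is
   "content-matched but positionally uninformed". After `max_tries`
   proposals (default 10,000) the last window is accepted anyway and a
   fallback counter is incremented; fallbacks are reported, never silent,
   and keep the count contract exact even for pathological targets.

The simulated library therefore matches the real one in total count
(exactly), length histogram (exactly), and per-class damage-site content
(up to multinomial sampling noise; the run report records the achieved
total-variation distance). Strand is drawn uniformly so the background is
strand-symmetric and TS/NTS normalization inherits no strand bias. With a
fixed seed the output is bit-identical across runs.

The optional `per_position_mono` mode additionally matches the real
library's full positional mononucleotide profile, weighting each candidate
window by the likelihood ratio of that profile against the genome's base
composition. A rejection sampler with a per-class envelope constant is
impractical here — the envelope is a product of 16–28 per-position maxima,
putting acceptance rates near e^−16 — so the implementation enumerates all
candidate windows per length class, scores them once, and samples exactly
in proportion to the weight. The target distribution is identical; only
the mechanism differs. The mode is off by default: it is slower and, for
damage types whose sequence signal is concentrated at the lesion, adds
little beyond the damage-site match.

## Strand conventions and the TS/NTS model

The excised oligonucleotide aligns to its strand of origin. For a gene on
"+", the template (transcribed) strand is "−", so reads on the strand
*opposite* a gene's annotation are template-strand (TS) repair events and
same-strand reads are non-transcribed-strand (NTS) events. Under purely
global repair the two strands are exchangeable and log2(TS/NTS) is
centred at 0; transcription-coupled repair (TCR) — repair triggered by
RNA polymerase stalling at lesions — shifts it positive.

Per gene, `gene_ts_nts()` counts reads over the complete gene region on
each strand for both libraries, forms the four RPKMs with the gene length
and the two library totals, and reports
log2((RPKM_real_TS/RPKM_sim_TS) / (RPKM_real_NTS/RPKM_sim_NTS)). No
pseudocounts are used anywhere: a zero in any of the four counts makes the
ratio undefined, and such genes are flagged and excluded from summaries
rather than shrunk toward an arbitrary value that would distort the log2
scale. A read overlapping two genes counts in both; the data give no basis
for ambiguity resolution.

## Metagene geometry

`metagene_profile()` extends each gene by half its length on both sides
(flank_fraction = 0.5), splits the extended region — twice the gene length
— into 100 equal bins, and reverses bin order for "−" genes so bin 1 is
always 5'-most. With these defaults bins 1–25 are upstream flank, 26–75
gene body, and 76–100 downstream flank. An alternative reading of
"genes plus half-length flanks in 100 bins" appends flank bins outside the
100; the inclusive layout is used because it keeps one fixed bin/feature
geometry per gene, and the body-bin indices are exposed on the result so
either interpretation of downstream summaries is explicit.

Counts are pooled across genes per bin index (separately for TS/NTS and
real/simulated), each pooled count is RPKM-normalized with the pooled bin
length, and the ratio is taken once per bin — rather than averaging
per-gene ratios — because sparse per-gene bins make per-gene ratios
unstable and undefined-prone, while pooling preserves scale invariance.
A read that spans a bin boundary counts in both bins (counting is "any
overlap ≥ 1 bp", as with BEDTools intersect); bins with zero simulated
count are reported as undefined rather than patched. Genes whose extended
region would leave the chromosome are skipped and counted.

## Expression and chromatin states

Gene-level expression is the TPM of the gene's longest transcript
(ties break to the lexicographically smallest transcript id, so the choice
is deterministic). The expression–repair association is the Pearson
correlation between log2 TS/NTS and log10(TPM + 0.1); the log transform
reflects the log-normal spread of TPM, and the 0.1 pseudocount keeps
silent genes finite while moving expressed genes negligibly. Raw-TPM
correlation is available as a sensitivity flag.

Chromatin-state repair is strandless: per segment, real and simulated
counts are RPKM-normalized with the segment length and divided. Segments
with zero simulated count are excluded and reported. State comparisons use
two-sided Welch t-tests on segment-level values — Welch because segment
counts and variances differ freely between states — with star labels at
p ≤ 0.05/0.01/0.001/0.0001 and no multiple-testing correction, so the
stars mean exactly what they mean in the usual figure legend. P-values are
reported raw; with a handful of states the pair count is small and any
correction policy is better applied by the reader than hidden in the
table.

## The synthetic data generator

`generate_synthetic_dataset()` builds a complete test bed whose defaults
describe the study conditions the package is validated under:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 500 kb, GC 0.36 | i.i.d. bases at plant-like GC |
| genes | 200, log-normal length, median 2 kb, clipped 0.5–8 kb | non-overlapping, stranded, ≥1 kb apart |
| isoforms | 1–3 per gene, nested | longest carries the gene TPM |
| expression | log-normal TPM (meanlog log 10, sdlog 1.5) | plausibly wide dynamic range |
| library | 200,000 reads | primary:degraded = 0.8:0.2; primary weights 25–28 = .15/.25/.40/.20; degraded uniform 16–21 |
| damage spectrum | TT .261, TC .242, CT .159 | remaining mass over other dinucleotides ∝ genomic availability |
| TCR | ρ(gene) = 1 + κ·rank(TPM)/n, κ = 1 | template-strand boost, expression-ranked |
| states | open 1.5, genic 1.0, hetAT 0.5, hetGC 0.6 | repair-rate multipliers |
| bumps | amplitude 1.5, σ 200 bp | Gaussian enrichment at promoter (−500 bp), TSS, TES |

Each read arises from a lesion. The damage dinucleotide class is drawn
from the spectrum as an exact marginal, and the lesion's position within
the class is drawn with probability proportional to
state multiplier × TCR boost (on template strands inside genes) ×
positional bump. The two-stage construction is deliberate: chromatin-state
labels are assigned from realized segment GC (hetAT segments are the
lower-GC half of heterochromatic intergenic space by construction), so a
single-stage per-position weighting would let the state multipliers leak
into the realized spectrum; treating the spectrum as a marginal keeps it a
clean generator parameter that QC must recover within multinomial error
(s.e. ≈ 0.0014 per category at 100k reads). Read length is drawn from the
mixture and the read placed so the lesion sits at positions (L−7, L−6).
Lesions within one maximal read length of a chromosome end are excluded
from the candidate set — the class-neutral equivalent of rejecting and
resampling boundary-crossing reads on an i.i.d. genome.

Genes are placed with a minimum intergenic gap of 1 kb. This keeps every
chromatin segment long (≥ 1 kb, typically 2–10 kb) relative to the ~27 bp
read scale; segments much shorter than that have their per-segment signal
dominated by reads spilling across segment boundaries, which is a property
of any ≥1-bp-overlap counting scheme rather than of repair.

What the generator does *not* emulate: mappability and alignment
artifacts, replicate structure, sequencing error, local composition
heterogeneity (isochores, repeats), nucleosome-scale periodicity, and any
coupling between expression and chromatin state. Passing recovery tests
therefore demonstrates that the estimators invert the generative model
they target — not that real libraries are free of the artifacts above,
which must still be handled upstream (mapping quality filtering) or
checked in QC.

The truth record accompanying each library stores the full specification
plus realized per-gene TPM and ρ, expected state multipliers and the
16-category spectrum, so every recovery target used in the tests is
computable from the record alone.

## Numerical and degenerate-input policy

- Coordinates are 0-based half-open throughout; GFF3 is converted at the
  boundary. Chromosome names must match across inputs exactly; mismatches
  are reported and fatal, because silent zero-counting is the
  characteristic failure of interval pipelines.
- Duplicate elimination keys on (chrom, start, end, strand) — coordinate
  duplicates of single-end alignments — keeps the first record, and sorts
  the output so results are independent of input order. Deduplication is
  per library, before any merging.
- Modal read length ties break toward the smaller length, and the tie rule
  is part of the documented output.
- Reads with N in a queried window are excluded from that window's
  denominator only, not from the library.
- Frequencies are true distributions (non-negative, unit sum per slot) and
  are checked as such in the tests; empty inputs are errors, not NaNs.
- All stochastic steps take explicit seeds and restore the caller's RNG
  state; equal seeds give bit-identical outputs, including written files.
- `run_pipeline()` caches at run granularity: a rerun whose input checksums
  and parameters match the previous manifest is reported fully cached.
  Per-stage partial caching was deliberately not implemented — stages
  share in-memory inputs, and a stale-stage bug costs more than the
  seconds a partial rerun would save at these problem sizes.

## Problem sizes

The validation suite runs entirely on generated data: unit tests on
genomes of 1–100 kb with 10²–10³ reads, and the end-to-end recovery suite
at the generator defaults above (1 Mb genome, 200 genes, 200,000 reads;
100,000 for the pure QC recoveries) — sizes at which binomial and
multinomial standard errors are far inside the recovery tolerances
(15% for ratio recoveries, ±0.01 per spectrum category, ±0.05 on null
medians), so the checks test correctness rather than luck.

## Known limitations

- The background simulator matches damage-site content per length class,
  not full-read composition (unless `per_position_mono` is enabled); a
  damage type whose sequence bias extends beyond the lesion would be
  normalized only partially.
- Per-gene TS/NTS requires all four counts non-zero; very short or very
  cold genes drop out of summaries, and their absence is reported rather
  than imputed.
- Metagene pooling weights genes by their read mass; a per-gene-mean mode
  is intentionally not the default and the pooled estimator should not be
  read as "the average gene".
- The pipeline consumes aligned BED6; trimming, alignment and mapping-
  quality filtering are upstream of this package by design.
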