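# excisr

Genome-wide profiling of nucleotide excision repair from XR-seq data.

XR-seq (excision repair sequencing) captures the ~16–28 nt oligonucleotides
that nucleotide excision repair cuts out of UV-damaged DNA, so the density
of mapped reads reports repair activity along the genome. Raw densities,
however, track damage *opportunity* as much as repair: UV photoproducts
such as (6-4)PP and CPD form at dipyrimidines, so AT/GC composition
confounds the signal. `excisr` removes that confounder by simulating a
background library matched to the real one in total read count, read-length
distribution and damage-site dinucleotide content, and expressing repair as

```
normalized repair = RPKM(real reads) / RPKM(simulated reads)
```

over any genomic feature. On top of this it quantifies:

- **Excision-product QC** — read-length distributions (primary 25–28 nt
  products vs 5'-degraded 16–21 nt forms) and positional mono/dinucleotide
  frequencies, including the damage-site dinucleotide at read positions
  (L−7, L−6) — positions 20–21 of a 27-mer.
- **Transcription-coupled repair (TCR)** — strand-specific 100-bin metagene
  profiles over genes with half-length flanks, and per-gene
  log2(normalized TS / normalized NTS) ratios, where TS reads map opposite
  the gene's annotated strand (the template strand) and NTS reads map with
  it. Under purely global repair the log2 ratio is 0; TCR shifts it above 0.
- **Repair vs expression** — longest-isoform TPM assignment per gene and the
  Pearson correlation of log10(TPM + 0.1) with log2 TS/NTS.
- **Chromatin-state repair** — strandless per-segment normalized repair
  across a chromatin-state segmentation, with pairwise Welch t-tests and the
  usual star notation (ns, \*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001,
  0.0001).
- **Synthetic data** — a fully parameterised generator (genome, annotation
  with isoforms and expression, chromatin states, XR-seq-like library with
  recorded ground truth) so the whole pipeline is testable without any
  external data.

It works with the standard plain-text formats: FASTA, BED6, GFF3,
chrom.sizes, bedGraph (RPM-normalized tracks), TSV tables.

## Worked example

Everything below runs from a synthetic dataset generated in memory — a
2 × 500 kb genome, 200 genes, and a 200,000-read library with a (6-4)PP-like
damage spectrum, expression-ranked TCR and chromatin-state-dependent repair:

```r
library(excisr)

ds  <- generate_synthetic_dataset(synthetic_spec(seed = 1))
fit <- xr_repair(ds$library$reads, ds$annotation$genes,
                 genome     = ds$genome,
                 states     = ds$states,
                 expression = ds$annotation$transcripts,
                 sim_cfg    = sim_config(seed = 2))
summary(fit)
```

```
Normalized repair summary
  libraries: 195016 real / 195016 simulated reads
  log2 TS/NTS over 200 genes: median 0.542 [Q1 0.267, Q3 0.803]
  mean body-bin normalized repair: TS 1.342, NTS 0.922 (ratio 1.455)
  read lengths: mode 27 nt, 79.5% in the primary window
  top damage-site dinucleotides: TT 26.0%, TC 23.7%, CT 15.9%
  mean normalized repair by chromatin state:
genic hetAT hetGC  open 
1.181 0.540 0.644 1.526 
  expression vs log2 TS/NTS: Pearson r = 0.772, p = 8.84e-41 (n = 200)
```

Reading the output: the damage-site composition and modal read length
reproduce the generator's (6-4)PP-like spectrum; the mean gene-body TS/NTS
ratio of ~1.46 recovers the generator's mean template-strand boost (1.5);
the per-gene ratios correlate with expression because the boost is
expression-ranked; and the chromatin-state means recover the programmed
open/hetAT rate ratio of 3. `coef(fit)` returns the per-gene log2 TS/NTS
vector, `plot(fit)` draws the metagene profile (also
`which = "tsnts" | "states" | "expression"`), and `simulate(fit, nsim = 3)`
draws fresh matched background libraries.

For file-based work, `run_pipeline("config.yaml")` drives
dedup → simulate → qc → profile → tsnts → states → correlate from a YAML
config, writing TSV tables, RPM bedGraph tracks, a run log and a JSON
manifest with checksum-based stage caching.

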