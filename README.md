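# tRNAcharge

Quantifies **tRNA aminoacylation (charging) levels** from periodate-treated
small RNA sequencing libraries, for researchers measuring the functional
state of cellular tRNA pools (including organellar tRNAs, tRNA-like
t-elements and synthetic spike-in controls).

## The method

An amino acid esterified to the 3' terminal adenosine protects it from
sodium periodate; the free 3' end of an uncharged tRNA is oxidized and the
terminal nucleotide eliminated. After sequencing, each read's 3' end against
its reference classifies the molecule:

- **CCA** — intact tail (charged, or escaped the chemistry),
- **CC** — exactly one nucleotide short (deprotected and oxidized),
- **missing ≥ 2** — off-target degradation or fragmentation (excluded from
  charging estimates, reported as a damage fraction of all reads).

Per gene *g* and library, `CCA% = 100·n_CCA / (n_CCA + n_CC)`, and the
charging index normalizes treatment by control:

```
theta_hat_g = CCA%_periodate(g) / CCA%_control(g)
```

which estimates the charged fraction θ_g under ideal chemistry. Around this
core the package provides: reference loading with per-nucleotide **Sprinzl
coordinates** (canonical 1–76 numbering with 17a/20a/20b and "e" labels), a
seeded **library simulator** with the full treatment chemistry and a ground
truth manifest, an affine-gap **fit aligner** tolerant of RT 5' additions
and non-templated 3' tails (SAM export), **family summaries** (isodecoder /
isoacceptor), **misincorporation and truncation profiles** on the Sprinzl
axis, a **5' tRF caller** (offset > 7 nt, fraction > 5%, clusters ≤ 3 nt
merged to the 3'-most site), non-templated **tail spectra** for CCA-less
t-elements, and deterministic report bundles.

## Worked example

Simulate a control and a periodate library over a synthetic reference with
known charging fractions, then recover them:

```r
library(tRNAcharge)

ref <- synthetic_reference(6, seed = 7, include_t_element = TRUE,
                           include_spike_in = TRUE)
theta <- setNames(c(0.8, 0.6, 0.4, 0.7, 0.3, 0.5, 0, 0), names(ref$genes))

dir <- tempfile(); dir.create(dir)
libs <- data.frame(library_id = c("ctrl1", "per1"),
                   fastq = file.path(dir, c("ctrl1.fastq", "per1.fastq")),
                   treatment = c("control", "periodate"), replicate = 1L)
for (i in 1:2)
  simulate_library(sim_config(ref, libs$treatment[i], n_reads_per_gene = 2000,
                              seed = 1, theta = theta),
                   ref, fastq = libs$fastq[i], library_index = i)

run <- run_pipeline(ref, libs)
ci <- run$charging_index
ci$theta_true <- theta[ci$gene_id]
print(ci[, c("gene_id", "cca_pct_control", "cca_pct_periodate",
             "charging_index", "theta_true")], digits = 3)
```

```
       gene_id cca_pct_control cca_pct_periodate charging_index theta_true
1 mit-AsnGTT-3            89.5             39.53         0.4417        0.4
2 mit-GlnTTG-6            91.2             44.14         0.4838        0.5
3 nuc-AlaAGC-1            93.1             68.39         0.7346        0.8
4 nuc-AspGTC-4            92.8             62.12         0.6692        0.7
5 pla-ArgACG-2            90.6             55.20         0.6093        0.6
6 pla-CysGCA-5            88.5             30.98         0.3499        0.3
7      spike-1            86.0              1.46         0.0169        0.0
8      telem-1              NA                NA             NA        0.0
```

Reading the output: control libraries sit near (but below) 100% CCA because
handling degrades some tails even without periodate; periodate CCA%
tracks each gene's charged fraction; the never-charged spike-in collapses to
~1.5% (the residual reflects the 98% periodate efficiency); the charging
index recovers θ up to the chemistry's distortions (here within a few
percentage points). The CCA-less t-element is excluded from charging
estimates — its non-templated 3' additions appear in
`run$tail_spectra$"telem-1"` instead. `build_report(run, "report/")` writes
the full TSV bundle plus a machine-readable run manifest.

A thin command-line wrapper is installed as `exec/trnacharge`
(`trnacharge simulate ...`, `trnacharge run-all ...`) for shell pipelines;
`inst/extdata/` ships a tiny synthetic reference (FASTA + annotation TSV)
illustrating the input format.

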