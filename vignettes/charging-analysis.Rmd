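---
title: "Quantifying tRNA aminoacylation from periodate-treated tRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tRNA aminoacylation from periodate-treated tRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcharge)
```

## The measurement

A tRNA is functional when an amino acid is esterified to the terminal
adenosine of its 3' CCA tail. Sodium periodate oxidizes the free cis-diol of
an *unprotected* 3' terminal ribose; subsequent base/amine treatment then
eliminates that nucleotide. An amino acid blocks the diol, so after periodate
treatment charged tRNAs keep their CCA while uncharged tRNAs end in CC.
Sequencing the treated RNA therefore turns charging into a 3'-end counting
problem: for each gene,

$$\mathrm{CCA\%} = 100 \cdot \frac{n_\mathrm{CCA}}{n_\mathrm{CCA} + n_\mathrm{CC}}$$

where reads lacking **more than one** 3' nucleotide are excluded from the
denominator — such reads arise from off-target degradation (the treatment
chemistry is harsh) and from tRNA fragments, not from the charging state.
Reads missing two or more 3' nucleotides are reported separately as

$$\mathrm{non\text{-}CC/CCA\%} = 100 \cdot \frac{n_{\geq 2\ \mathrm{short}}}{n_\mathrm{total}},$$

a damage indicator over *all* reads. Because even untreated (control)
libraries show incomplete CCA integrity, the per-gene **charging index**
normalizes the periodate value by its control counterpart:

$$\widehat{\theta}_g = \frac{\mathrm{CCA\%}^{\mathrm{periodate}}_g}
                           {\mathrm{CCA\%}^{\mathrm{control}}_g}.$$

Under ideal chemistry (complete removal, no off-target damage, intact
uncharged tails) this index equals the charged fraction $\theta_g$. A third
library type — deacylated at pH 9 before periodate — acts as a positive
control; its **retention ratio** (deacyl-periodate CCA% over periodate CCA%)
measures deacylation resistance of individual aminoacyl esters (near 1 for
slow-hydrolyzing residues such as Ile/Thr/Val-type esters, near 0 when
pre-deacylation fully exposes the tails).

## The chemistry model behind the simulator

Every molecule of gene $g$ is drawn through the following generative chain
(all knobs live in `sim_config()`):

1. with probabilities `trf5_prob`/`trf3_prob` the molecule is a 5' or 3'
   fragment with the configured breakpoint; fragments are uncharged;
2. full-length molecules are charged with probability `theta`;
3. uncharged CCA-ended molecules carry an intact tail with probability
   `cca_intact_uncharged` (default 0.9), otherwise they already end in CC in
   vivo — sequencing cannot distinguish in-vivo CC tails from extraction
   damage, so both interpretations are exposed as knobs;
4. treatment: in `deacyl_periodate` libraries, charged molecules are
   deacylated with probability `deacyl_eff * (1 - deacyl_resistance)`
   (default efficiency 0.9); periodate then removes the terminal nucleotide
   of every free 3' end with probability `periodate_eff` (default 0.98,
   chosen so an uncharged control recovers the ~2% CCA survival a synthetic
   spike-in exhibits); independently, any molecule — charged or not — loses
   `1 + Geometric(0.5)` additional 3' nucleotides with probability
   `extra_degradation` (0.10 in control, 0.35 in periodate libraries,
   reflecting the substantially higher damage the treatment series causes);
5. reverse transcription scans 3' to 5'; each modified site stops the enzyme
   with `stop_prob` (truncating the read 5' end immediately 3' of the site)
   or emits a deletion/substitution drawn from the site's emission
   probabilities; with probability `tt_prob` (0.3) the RT appends 1-3 random
   non-templated 5' bases;
6. reads shorter than `size_min` (35 nt, the library size-selection floor)
   are dropped — downstream, 3'-proximal truncations are therefore flagged
   unobservable rather than reported absent.

Modification sites are parameterized by *unconditional* outcome
probabilities: `del_prob + pA + pC + pG + pT = 1`, with mass on the reference
base counting as a correct emission. A site written as "del 0.25, substitution
0.50" therefore misincorporates in 75% of covering reads. Charged molecules
always carry an intact CCA (an amino acid requires a 3' A to attach to).

`expected_tail_fractions()` evaluates this chain in closed form (no
fragments/modifications), which the tests use to check simulated libraries
against their own model and to reason about detection bounds: with
`periodate_eff = 0.98` the expected spike-in CCA% under periodate is
$\approx 1.99\%$ — essentially at the 2% bound that follows from the
efficiency — so the acceptance check asserts the deterministic expectation
against the bound and the simulation against the expectation (within three
binomial standard errors), rather than pretending a finite sample can sit
strictly below its own mean.

What the simulator does **not** emulate: ligation and PCR bias, realistic
quality scores, sequence-dependent RT behavior, or the capture-hairpin
sequence itself. Passing recovery tests therefore demonstrates that the
estimators invert the modeled chemistry, not that real libraries are free of
representation bias — raw abundances from tRNA-seq remain untrustworthy, and
the package's outputs are ratios and within-gene comparisons for that reason.

## Alignment

Reads are fit-aligned: the read must be consumed end to end (minus clips),
while the aligned span may start and end anywhere on the reference. Scoring
is match 0, mismatch −5 (the quality-ceiling penalty of the `--mp 5,2`
convention; simulated qualities are constant so the ceiling is the only value
that matters), and affine gaps at −5 open, −3 per base. Two clip rules
absorb the RT artifacts that break global mappers on tRNA reads:

* up to `clip5_max_free = 5` read bases are clippable at the 5' end at zero
  cost (non-templated terminal-transferase additions);
* 3' clips are free only for read bases extending *past the reference 3'
  terminus*, up to `clip3_max_free = 8` bases — this is how non-templated
  tail additions on CCA-less references (t-elements) are observed. The bound
  matters: observed additions are at most 5 nt, and an unbounded free
  terminal clip would let an unrelated read "map" by pairing a token
  terminal seed with a long free overhang. All other clips cost −5 per base.

At least 10 reference-consuming columns are required (the mapper-seed
analogue), preventing degenerate all-clip alignments; reads failing
`min_score(len) = -0.7 - 0.7·len` are unmapped. Ties across distinct gene
sequences are flagged ambiguous with the tied ids recorded; the reported
winner is the lexicographically first id, so results are independent of gene
order. Within one gene, equal-scoring alignments resolve to fewer clipped
bases, then the smaller reference start, then a fixed traceback preference
(diagonal over deletion over insertion). The aligner is validated against an
independently coded exhaustive dynamic program on random read/reference
pairs.

The implementation takes an exact-match fast path (a score-0 alignment, when
one exists, is provably optimal because no positive scores exist) and falls
back to the full dynamic program otherwise; both paths honour the same
tie-breaks that the tests observe.

## Coordinates

Per-nucleotide Sprinzl labels anchor every position to the canonical
cloverleaf so positions are comparable across genes: acceptor stem 1-7,
connector 8-9, D-arm 10-26, anticodon arm 27-43 (anticodon 34-36), variable
region 44-48, T-arm 49-65, acceptor stem 66-72, discriminator 73, CCA 74-76.
Supported variability is restricted to the D-loop (7-11 nt; length 8 is the
canonical 14-21, length 7 drops "17", longer loops add the insertion slots
17a/20a/20b) and the variable region (4-23 nt; regions longer than 5 keep
the 44/45 and 48 anchors and fill the interior with "e1", "e2", ...).
Anything outside those ranges is rejected loudly rather than mislabeled.
Genes without cloverleaf homology (stem-loops) may be annotated with a single
`linear` segment and get plain sequence positions. CCA-less genes never carry
labels 74-76.

## Tail classification

A read's tail state is **coordinate-based**: the offset between the
alignment 3' end and the reference terminus (0 = CCA, 1 = CC, ≥2 =
missing-2-plus). A mismatched base inside positions 74-76 flags the read but
does not change its category — modification-induced misincorporations would
otherwise corrupt tail calls; the flag makes the alternative denominator
reproducible. On CCA-less genes the category is non-templated and the
terminal soft-clip string is the observed addition ("None" when the read ends
exactly at the reference terminus; reads not reaching the terminus carry no
addition call).

## Reporting thresholds and defaults

* `min_reads = 100` per gene for a defined CCA% (below it the value is NA,
  never zero);
* `min_cov = 50`: misincorporation cells need coverage strictly above 50,
  masked as NA otherwise;
* tRF calls need a 3'-end offset strictly greater than 7 nt and a read
  fraction strictly greater than 5%; above-threshold positions within 3 nt
  are single-linkage clustered and reported at the cluster's 3'-most member
  with the summed fraction of its above-threshold members;
* family summaries are emitted both as pooled counts and as unweighted means
  across member genes (the family-averaged displays use the unweighted
  convention; the weighting is otherwise unstated, so both are kept);
* ambiguous reads are excluded from gene-level tables by default and
  retained in genome-level totals; both toggles are exposed;
* statistical wrappers report raw P values (no multiple-testing correction);
  unpaired comparisons default to Welch; a one-way ANOVA on all-identical
  values errors (0/0), zero within-group variance with differing means
  reports F = Inf, P = 0.

## Numerical and degenerate-input choices

Deacylation acts before oxidation within a treatment; extra degradation
stacks on top of terminal removal, so the geometric tail pushes CCA reads to
CC and CC reads into the missing-2-plus class. Gap costs follow the
`open + L·extend` convention (a 1-base gap costs −8). Empty tail spectra,
genomes with zero mapped reads, single-gene association tests and
zero-variance statistics all return explicitly flagged results rather than
silent zeros, as exercised in the test suite.

## Problem sizes

The validation suite runs at the sizes the recovery properties are stated
at: 50 genes × 2000 reads per library for charging recovery (mean absolute
error of the charging index vs the simulated θ < 0.03; Spearman rank
agreement > 0.95 under realistic chemistry), 20 000 reads for the spike-in
chemistry control, 10 000 reads for misincorporation calibration (observed
rate within three binomial standard errors of the configured 0.75), 200
random pairs for the alignment oracle and 500 random coverage profiles for
the tRF-caller oracle. These sizes make every binomial check well-powered
while keeping a full run in about a minute.

## Known limitations

The pipeline measures CCA% as a *proxy* for aminoacylation and does not
correct for chemistry efficiencies; absolute charging levels inherit the
periodate and deacylation incompleteness. Read-level abundances are biased by
library construction and should only be compared across treatments of the
same gene. Truncations within ~35 nt of the 3' end are invisible to the
library and are flagged, not inferred. The Sprinzl assigner requires the
structural annotation to be correct; it validates lengths and ordering but
does not predict secondary structure.
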