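---
title: "Methods: m6A profiling, cohort comparison and RNA-fate statistics"
author: "m6aging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A profiling, cohort comparison and RNA-fate statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aging)
```

# Overview

`m6aging` implements the computational arm of an m6A (N6-methyladenosine)
epitranscriptomic profiling study comparing two human cohorts (young and
old, n = 11 subjects each). The pipeline covers six analysis stages:

1. **Site calling** — identify m6A-methylated fragments from MeRIP-seq
   IP versus input fragment counts in sliding windows.
2. **Motif and biotype tallies, cohort overlap** — classify each site by
   its methylation motif (GGACU / GACU / ACU / GAC), tally sites per
   transcript biotype, and count sites shared between cohorts.
3. **Metagene profiling** — positional density of sites along a
   normalized 5'UTR / CDS / 3'UTR model and around the translation start
   and stop codons.
4. **Expression comparison** — per-gene log2 fold changes between
   cohorts, ECDF curves and two-sample Kolmogorov–Smirnov tests,
   stratified by methylation status and RNA-binding-protein (AUF1-like /
   HuR-like) target membership.
5. **Decay kinetics** — mRNA half-life estimation from actinomycin-D
   RT-qPCR time courses via the ΔΔCt method.
6. **miRNA differential expression** — Z-ratio statistics on microarray
   intensities with the triple call threshold (pairwise z-test p < .05,
   |Z ratio| > 1.5, FDR < 0.3).

Because no sequencing accessions exist for the original cohorts, the
package ships a first-class synthetic-data generator whose defaults
encode the study design; every stage is exercised end to end against a
machine-readable truth registry.

# Coordinate conventions and annotation model

All intervals are **0-based half-open** internally. BED input is native;
GTF (1-based closed) is converted on read. A `transcript_model` stores
exons 5'→3' in transcript orientation (for minus-strand transcripts the
genomically rightmost exon comes first) and, for coding transcripts, the
CDS as transcript-space offsets. `genomic_to_transcript()` projects the
exonic part of a genomic interval into mature-transcript coordinates;
tests verify it base-by-base against an enumeration oracle and through
BED12 round trips.

Annotation biotypes are collapsed to four classes (`protein_coding`,
`lncRNA`, `pseudogene`, `other_noncoding`); unrecognized labels fall
into the last class with a warning. Where a gene has several isoforms,
gene-level operations use the longest isoform, the common metagene
convention.

# Site calling

Counts are tallied in fixed-width sliding windows (default 50 nt, step
25 nt) over exons. For window $i$ with IP count $m_i$, input count $n_i$,
and library sizes $M, N$ (so $\rho = M/N$):

* enrichment $= \dfrac{(m_i + c)/M}{(n_i + c)/N}$ with pseudocount
  $c = 0.5$;
* the null mean is $\lambda_i = (\tilde n_i + c)\,\rho$, where
  $\tilde n_i$ is the window's input count floored at its transcript's
  mean input count. This local-background floor (in the tradition of
  genomic peak callers) prevents spurious calls on windows whose single
  input draw undershoots the local coverage;
* the one-sided tail probability $P(X \ge m_i)$ is computed from a
  negative binomial with mean $\lambda_i$ and variance
  $\lambda_i(1+\rho) + 2\phi\lambda_i^2$. The $\lambda_i(1+\rho)$ term
  propagates the sampling noise of the plug-in input estimate; the
  $2\phi\lambda_i^2$ term carries the biological overdispersion of
  fragment counts in both libraries ($\phi$ = `dispersion`, default
  0.1; $\phi = 0$ gives the Poisson-difference limit). A pure Poisson
  tail on the plug-in mean is anti-conservative under overdispersed
  counts and produced a double-digit false-site percentage in
  simulation, which motivated this variance model;
* Benjamini–Hochberg correction is applied across windows, and windows
  with $q \le 0.05$ and enrichment > 1 are kept.

Runs of overlapping or abutting significant windows merge into one
site. The site inherits the counts of its best (maximum-IP) window, the
minimum q, the union interval, and the summed IP fragments
(`n_fragments`), since fragment-level resolution is not recoverable
after merging. Merged sites never overlap one another. Because two
significant windows separated by one sub-threshold step do not merge, a
single planted site can occasionally split into two called sites;
overlap-based evaluation is unaffected.

Subjects of a cohort are pooled into one IP/input library pair: the
analysis produces one site set per cohort, not per subject.

# Motif classification

The four motif classes are nested substrings of the DRACH consensus
(GAC ⊂ GACU ⊂ GGACU; ACU ⊂ GACU), so naive counting would double-count.
Classification is longest-match priority — GGACU if present, else GACU,
else ACU, else GAC, else `none` — making the classes mutually exclusive.
Matching is case-insensitive and reads DNA `T` as `U`. Site sequences
are taken from the mature transcript over the called interval.

# Quantification

FPKM (fragments per kilobase per million mapped fragments) is
$10^9 \cdot \text{count} / (\text{length} \cdot \text{libsize})$. IP
(methylated-fragment) FPKM uses the IP library size; total-RNA FPKM uses
the input/total library — the two denominators are deliberately kept
separate. MeRIP-qPCR fold enrichment over a nonspecific control (18S
rRNA) is $(q_{IP}/q_{input}) / (q_{IP}^{ctl}/q_{input}^{ctl})$ on
relative quantities such as $2^{-\Delta Ct}$.

# Metagene profiles

Each site's midpoint is projected to transcript space and assigned to
the 5'UTR $[0, \text{cds\_start})$, CDS
$[\text{cds\_start}, \text{cds\_end})$ or 3'UTR of its coding
transcript, rescaled to a region-relative position, and binned (default
20/50/30 bins). Midpoints rather than full intervals are binned so that
100–200 nt sites are not length-weighted. Pooled bin counts are
normalized to sum to 1 (pooled rather than per-transcript
normalization). Anchored profiles additionally count midpoints within
±300 nt of the start and stop codons at nt resolution. Noncoding and
unprojectable sites are skipped and reported.

# Expression comparison

Per gene, the fold change is
$\log_2\!\big((\bar x_{old} + \varepsilon)/(\bar x_{young} +
\varepsilon)\big)$ with pseudo-FPKM $\varepsilon = 0.01$, which keeps
fold changes finite for genes unexpressed in one cohort while
perturbing expressed genes negligibly. A gene is *methylated* when it
owns at least one called site in either cohort's set. ECDF and
two-sample KS comparisons use the exact sup-distance with the
asymptotic p-value (the samples here are hundreds to thousands of genes,
where the asymptotic reference is standard; a 1,000-run null simulation
in the test suite confirms type-I calibration at α = .05). Strata are
arbitrary predicates over the fold-change records, e.g. methylated
AUF1-target versus methylated non-target genes. Per-gene between-cohort
tests are two-sided Welch t-tests. The methylation-versus-abundance
scatter reports a Spearman rank correlation, flagged degenerate when
either margin is constant.

# Decay kinetics

ΔΔCt quantification: $\Delta Ct(t) = Ct_{target}(t) - Ct_{ref}(t)$,
$\Delta\Delta Ct(t) = \Delta Ct(t) - \Delta Ct(0)$, abundance
$= 2^{-\Delta\Delta Ct}$ (amplification efficiency fixed at 2). The
abundance at $t = 0$ is exactly 1 by construction, so the half-life fit
is a zero-intercept least-squares regression of log abundance on time:
$\hat k = \sum_i t_i y_i / \sum_i t_i^2$ with $y = -\log(\text{abund})$,
and $t_{1/2} = \ln 2 / \hat k$. This model-derived 50% crossing uses
every timepoint and is noise-robust; `method = "interpolate"` provides
the literal linear-interpolation crossing for comparison. Non-positive
$\hat k$ flags `no_decay` with $t_{1/2} = \infty$; log-scale $R^2$
below 0.7 flags `poor_fit`. On noiseless exponential input the
generating half-life is recovered to machine precision for
$t_{1/2} \in [0.5, 50]$ h, and the estimator is exactly time-scale
equivariant.

**Power note.** Because ΔΔCt anchors every timepoint to the noisy
$t = 0$ measurement, that error propagates to all points of a series;
with the default grid (0/2/4/8 h) and Ct noise sd 0.1, a single
replicate estimates a 9.5 h half-life with ~25–30% relative error. A
Welch t-test on 3 replicates per condition then separates 4.9 h from
9.5 h in only about half of simulated experiments, although the
condition means rank correctly almost always; six replicates restore
≥90% power. The test suite asserts exactly these properties.

# miRNA Z-ratios

Intensities are $\log_{10}(x+1)$-transformed and z-scored per array
over detectable miRNAs (detectable = intensity above a floor, default
50 units, in at least half the subjects of either group). For miRNA
$i$, $\Delta z_i = \bar z_i^{old} - \bar z_i^{young}$ and
$Z_i = \Delta z_i / \mathrm{sd}(\{\Delta z_j\})$ — the standard
microarray Z-ratio with a single shared denominator. Significance per
miRNA is a two-sample z-test on per-subject z-scores; calls require
p < .05, |Z| > 1.5 and BH FDR < 0.3 simultaneously.

**Scope limitation.** The Z-ratio is an effect-size statistic built for
scenarios where changed features are a minority. Per-array z-scoring
forces each column to mean 0, so $\{\Delta z_j\}$ averages exactly 0
and $Z$ has mean 0 and sd 1 across miRNAs; by Chebyshev's inequality at
most $1/1.5^2 \approx 44\%$ of features can ever exceed |Z| > 1.5.
When a large majority of miRNAs shift in one direction — as in the
default scenario, where 550 of 887 are planted up — the shared
denominator absorbs the common shift and the majority class falls below
the threshold, whatever the effect size. Simulations in the test suite
document this directly: the sparse scenario (40 up / 20 down of 500) is
recovered with sensitivity 1.0, while the majority-shift scenario
recovers the down class but not the up class. Detecting a
transcriptome-wide directional shift requires an external normalization
reference (e.g. spike-ins or a wider probe set), which single-channel
z-scoring over the analyzed features cannot provide.

# The synthetic study design

`sim_config()` encodes the study conditions; generators derive
per-stage seeded streams, so one seed reproduces every byte.

* **Cohorts** — 11 subjects per group; ages ~N(30.6, 1.7²) and
  N(63.7, 2.2²) years.
* **Transcriptome** — 1,500 transcripts (80% coding), log-normal
  lengths (median 1.5 kb), 1–6 exons, laid out without overlap on 22
  chromosomes; uniform random sequence.
* **Planted sites** — 750 shared + 250 young-only + 50 old-only
  fragments of 100–200 nt (young ≈ 1,000 sites, ~75% shared, old
  fewer), 90% on coding transcripts, one motif per site drawn from a
  fixed mix (GGACU .35, GACU .30, ACU .20, GAC .15) and spliced into
  the sequence at the site center. Sites sit inside single exons, ≥100
  nt apart, placed uniformly along transcripts. Three focal
  transcripts encode the contrast of interest: *AGO2-like* (methylated
  in young only, expression reduced in old), *DROSHA-like* (methylated
  in both, unchanged), *DICER1-like* (unmethylated, reduced).
* **Counts** — negative binomial (dispersion 0.1), per-transcript
  log-normal expression (median 10 fragments per 50 nt window), IP
  enrichment 8× over the covered fraction of each window; cohorts are
  pooled library pairs.
* **Expression** — per-gene log2 fold change ~N(0, 0.4²), +0.5 for
  methylated genes, −0.4 further for methylated RBP-target genes, with
  0.3 sd subject noise around log2 baselines ~N(4, 1.5²).
* **Decay** — conditions empty-vector / METTL3-OE / METTL14-OE with
  half-lives 4.9 / 9.5 / 7.1 h, timepoints 0/2/4/8 h, 3 replicates, Ct
  noise sd 0.1.
* **miRNA array** — 887 species (including 12 let-7 family members, 7
  planted down), 550 up / 93 down at one column-sd effect on the log10
  scale, subject noise sd 0.15.

What the generator does **not** emulate: real genome sequence and motif
context beyond the planted motif, per-subject biological variability in
methylation (cohorts are pooled), positional enrichment of sites near
stop codons, batch or array spatial effects, and amplification-
efficiency variation in qPCR. Passing tests therefore demonstrate the
correctness and calibration of the statistics under the declared count
and noise models, not robustness to those unmodeled features of real
data.

# Numerical choices and degenerate inputs

* Ties in the best-window choice break by smaller q, then input order;
  `top_table` ties break lexicographically by miRNA ID, making outputs
  permutation-invariant.
* Merged-site export caps BED scores ($-10\log_{10} q$) at 1000.
* Zero-variance inputs: constant arrays are an error in z-scoring
  (normalization is undefined); constant scatter margins flag
  `degenerate`; an all-identical $\Delta z$ vector yields all-zero
  Z-ratios rather than an error.
* Empty window lists, empty gene sets and site sets with no mappable
  coding transcript return empty, flagged results, not exceptions;
  zero library sizes, missing $t=0$, non-positive abundances and
  malformed annotation records are errors.
* The pipeline manifest records the configuration and an MD5 per
  output file; identical config + seed gives identical manifests. A
  resume-from-cache mode was deliberately omitted: a full default run
  takes seconds, so stage toggles plus deterministic manifests provide
  reproducibility without cache-invalidation risk.

# Problem sizes in the test suite

Unit tests run on reduced instances (hundreds of transcripts, tens of
sites); the integration checks use the full default design (1,500
transcripts, ~92,000 windows per library, 887 miRNAs), 1,000-run KS
null calibration, 200-replicate decay recovery and 50-seed miRNA
recovery. The complete suite and the acceptance script each run in a
few minutes on one CPU.
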