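# m6aging

Tools for profiling N6-methyladenosine (m6A) RNA modification from
MeRIP-seq fragment counts and relating methylation to transcript fate in
two-cohort (young versus old) human study designs.

m6A is the most abundant internal mRNA modification; it is deposited by
the METTL3/METTL14/WTAP methyltransferase complex, removed by FTO/ALKBH5,
and read by YTHDF proteins that route transcripts toward stabilization or
decay. In aging cohorts the central questions are: where are the m6A
sites, how does overall methylation change with age, and does a
transcript's methylation status track its abundance and stability? This
package implements that full analysis chain for peripheral-blood-style
cohort designs (n = 11 per group), together with the companion wet-lab
quantifications: actinomycin-D half-life estimation by RT-qPCR and miRNA
microarray differential expression.

## What it computes

* **m6A site calling** from IP vs input window counts. For window *i*
  with IP count *m*, input count *n* and library-size ratio ρ, the null
  mean is λ = (ñ + c)·ρ (ñ = input floored at the transcript-mean input,
  c = 0.5 pseudocount) and the one-sided tail is negative binomial with
  Var = λ(1+ρ) + 2φλ², propagating both count overdispersion (φ = 0.1)
  and the plug-in noise of the input estimate; BH FDR ≤ 0.05, merged
  runs of significant windows become sites.
* **Motif classes** GGACU / GACU / ACU / GAC by longest-match priority
  (the classes are nested substrings of the DRACH consensus), plus
  biotype tallies and between-cohort site overlap.
* **Metagene profiles** over 5'UTR/CDS/3'UTR bins and ±300 nt windows
  anchored at the translation start and stop codons.
* **Cohort expression comparison**: per-gene log2((old+ε)/(young+ε))
  fold changes, ECDF curves, two-sample Kolmogorov–Smirnov tests, and
  stratified reports (methylated vs rest; methylated RBP-target vs
  non-target).
* **Half-lives**: ΔΔCt abundances (2^−ΔΔCt, abundance(0) = 1) and
  zero-intercept log-linear fits, t½ = ln2/k, with a literal
  interpolation mode for comparison.
* **miRNA Z-ratios**: per-array z-scores of log10 intensities,
  Z = Δz/sd(Δz), two-sample z-test, and the triple call threshold
  (p < .05, |Z| > 1.5, FDR < 0.3).
* **A seeded synthetic study generator** reproducing the design above
  (two cohorts of 11, ~1,000 planted 100–200 nt methylated fragments
  with ~75% shared and fewer in old, AGO2-like / DROSHA-like /
  DICER1-like focal transcripts, 4.9/9.5/7.1 h decay conditions, an
  887-miRNA array with 550 up / 93 down) with a truth registry for
  recovery testing.

## Worked example

```r
library(m6aging)

run <- run_pipeline(sim_config(seed = 1), outdir = "m6a_run")
print(run)
#> <m6a_run> stages: merip, metagene, expression, decay, mirna
#>   m6A sites: young 1096, old 855, shared 804
#>   KS methylated vs rest: p = 0
#>   half-lives (h): empty_vector = 5.17, METTL14_OE = 7.05, METTL3_OE = 11.42
#>   miRNAs: 857 detectable, 0 up, 90 down
#>   outputs: m6a_run
```

Reading the output: the young cohort carries more called m6A sites than
the old one (1096 vs 855) with a large shared fraction (804), the
planted young > old methylation decline. The Kolmogorov–Smirnov p-value
(numerically 0) says the log2 fold-change distribution of methylated
genes is shifted relative to unmethylated genes — methylated transcripts
are the more abundant stratum in the old/young contrast. The half-life
table shows the AGO2-like transcript decaying in ~5 h under the empty
vector but stabilized to ~7–11 h when either methyltransferase is
overexpressed (generating values 4.9/7.1/9.5 h; three qPCR replicates
per condition). The miRNA stage recovers the planted let-7-style
down-regulation; the up calls illustrate a documented scope limitation
of the Z-ratio when a majority of features shift together (see the
methods vignette).

Per-stage functions are exported individually (`call_m6a_sites()`,
`classify_motif()`, `overlap_sites()`, `metagene_profile()`,
`log2_fold_changes()`, `ks_compare()`, `fit_half_life()`, `z_ratio()`,
…), and `inst/scripts/run_pipeline.R` provides a shell entry point
driven by a YAML config.

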