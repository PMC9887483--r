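---
title: "Scanning exomes for codon-set enrichment: model, calibration, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning exomes for codon-set enrichment: model, calibration, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscan)
library(dplyr)
```

## The model

`codonscan` asks, for every gene of an exome, whether the gene uses a
particular set of codons more or less often than the exome as a whole
does, *after conditioning on the gene's amino-acid composition*. The
conditioning is the heart of the method: a protein that is simply rich
in isoleucine will contain many isoleucine codons of every kind, and
only its choice *among* synonymous codons carries information about
codon-level selection or decoding constraints.

The motivating application is the wobble-inosine decoding system.
Eukaryotic tRNAs for several amino acids are deaminated at the wobble
adenosine by the ADAT2/ADAT3 complex, and a species-specific set of C-
and A-ending codons can only be decoded through those inosine-modified
tRNAs. Two such sets ship as presets (`"human-adat"`, shared by human,
mouse, nematode and fruit fly, and `"yeast-adat"`); any codon set of
sense codons is accepted. The human preset retains ATC even though
cognate tRNAs for it exist, because those tRNAs are lowly expressed; the
package takes no position on tRNA expression — the codon set is purely
user input.

For each amino acid $a$ with at least one target codon, the exome-wide
background frequency is

$$f_a = T_a / N_a,$$

where $N_a$ counts every codon encoding $a$ in the exome and $T_a$ the
target codons among them. A gene with $n_a$ residues of $a$ is then
expected to carry

$$E = \sum_a n_a f_a$$

target codons, against an observed count $O$. Observed and expected are
compared in a 2×2 table with rows (protein length $L$, target-codon
count) and columns (Observed, Expected), tested with Pearson's
chi-square on marginal-derived expected cells, df = 1. The per-gene
family of p-values is corrected in a single list (never split by
direction first) with Benjamini–Hochberg (default FDR 0.01) or
Bonferroni (strict inequality $p < \alpha/m$; the BH step-up uses
$\le$), and significant genes are partitioned into enriched ($O > E$)
and depleted ($O < E$) lists.

### Assumptions

* Inputs are spliced, in-frame CDS, one record per nonredundant gene.
* The exome itself is an adequate null: the background is computed on
  exactly the post-QC, deduplicated gene set being tested. This
  self-consistency buys a useful invariant — the expectations sum to
  the observations, $\sum_g E_g = \sum_g O_g$ — which the test suite
  checks to $10^{-6}$ relative tolerance on every synthetic exome.
* Codon usage is treated as independent across positions; no
  autocorrelation or positional model is fit.

## The statistic is conservative, by construction

The 2×2 table includes the protein length in both columns, so the
marginal-derived expected cells are dominated by $L$ and the statistic
for a given discrepancy $O - E$ is much smaller than a one-sample
goodness-of-fit chi-square on $O$ alone would give. Two measured
consequences (both recomputed by `scripts/acceptance.R` and the
acceptance tests):

* On null synthetic exomes (2000 genes × 300 codons, i.i.d. codons at
  the background frequency), the p-value distribution is strongly
  super-uniform — Kolmogorov–Smirnov distance from uniform ≈ 0.35,
  median null p ≈ 0.76 — and the fraction of genes called significant
  at BH FDR 0.05 is 0 across 20 seeds.
* Power at a two-fold target-odds spike in 500-codon genes is 0 at
  exome-wide FDR 0.01; detectable effects at desk-scale simulation
  sizes require roughly four-fold odds in 1000-codon genes (where
  measured power is 0.95–1.0 with zero contamination of the
  opposite-direction list).

In other words the test controls false positives very comfortably and
ranks genes sensibly by deviation, but its p-values are not calibrated
in the frequentist sense; the genes it flags on real exomes deviate
strongly. Real exomes also have far larger between-gene codon-usage
heterogeneity (isochores, GC pressure, expression-linked bias) than the
i.i.d. generator, which is why exome scans of real species flag
thousands of genes while a null simulation flags none. The `yates`
option (off by default) applies the continuity correction, which only
lowers the statistic further; it is surfaced because 2×2 library
defaults differ and the choice should be visible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `codon_set` | — | sense codons under test; presets `human-adat`, `yeast-adat` |
| `correction` | `bh` | `bh` or `bonferroni`, one family over all tested genes |
| `fdr` / `alpha` | 0.01 | level for the chosen correction |
| `yates` | `FALSE` | continuity correction in the 2×2 test |
| `bins` | 20 | gene-body profile bins |
| `min_valid` | 0.9 | minimum fraction of unambiguous triplets for a gene to pass QC |
| `top_n` | 500 | smallest-p enriched genes exported for GO analysis |

## Numerical and edge-case choices

* **Protein length** $L$ counts sense codons only; one trailing stop is
  excluded. Counting is case-insensitive.
* **QC**: genes whose length is not a multiple of three, or that
  contain an internal stop codon, are excluded and logged — the frame
  is unknowable or the entry malformed. Triplets containing non-ACGT
  characters are skipped individually; the gene is kept while at least
  90% of its triplets are plain ACGT. Duplicated identifiers keep the
  first record (reproducible and order-stable). All exclusions appear
  in `qc_report()`, whose statuses account for every record read.
* **Untested genes**: when a gene contains no amino acid covered by the
  codon set, $E = 0$ and the chi-square is undefined; the gene is
  reported with `tested = FALSE` rather than dropped, is excluded from
  the correction family $m$, and can never be significant.
* $E$ enters the table at full precision — rounding it to an integer
  would discard information and the formula does not require integer
  cells. Background frequencies are never rounded before use.
* **Direction at equality**: a gene with $O = E$ exactly has direction
  `none` and is never listed, regardless of p.
* **Underflow**: p-values that underflow to zero are written to
  `results.tsv` as `0.0` with a `p_underflow` flag rather than clipped
  silently.
* **Provenance**: the background model carries a digest of the gene set
  it was built from, and `test_exome()` refuses a model built on a
  different set, so background and tests cannot silently mix inputs.

## Gene-body profiles

The profile maps the sense codon at 0-based index $i$ of an $L$-codon
gene to bin $\lfloor i B / L \rfloor$ ($B = 20$ by default). No
standard for the binning exists, so this equal-width relative-position
convention — the usual metagene choice — is documented rather than
claimed. Per-gene per-bin frequency uses all sense codons in the bin as
denominator, consistent with the per-gene frequency $O/L$; category
means (enriched / depleted / nonsignificant, untested genes counted as
nonsignificant) are unweighted across genes so long genes do not
dominate. On i.i.d. synthetic exomes the profile is flat to within
sampling noise, which the suite checks.

## The synthetic generator

`generate_exome()` draws each gene codon-by-codon: an amino acid from
the composition, then — for amino acids the codon set covers — a target
vs non-target synonymous codon with probability $g_a$, uniform within
each group. Spiked genes multiply the target odds $g_a/(1-g_a)$ by a
single `spike_effect` (direction-symmetric: values below 1 simulate
depletion). Defaults were fixed once as a featureless null: uniform
composition over the 20 standard residues and $g_a = 0.5$ for every
covered amino acid — with no empirical usage table to defend, the
symmetric choice maximizes per-codon information and keeps standard
errors interpretable ($\sqrt{g(1-g)/N_a}$). Genes get an ATG start and
TAA trailing stop and contain no internal stops or ambiguity, so
generator output always passes QC.

What the generator does **not** emulate: between-gene GC/composition
heterogeneity, codon autocorrelation, isoform structure, expression
weighting. Passing calibration on these exomes therefore shows the
machinery is correct under its own null, not that real-exome gene lists
are exhaustive or complete.

Validation problem sizes, chosen to make sampling error negligible
relative to the asserted bounds while keeping the whole suite quick:
oracle-equivalence checks run on ≥1000 random instances per operation;
null calibration uses 2000 genes × 300 codons over 20 seeds; power
checks use 150–1000 genes of 100–1000 codons with 10–20% spiked.
Seeds are explicit everywhere; replicate $r$ of a calibration uses
`seed + r`.

## Known limitations

* The p-values inherit the conservatism of the printed-table
  construction (above); an exact binomial/multinomial alternative would
  be better calibrated but is a different method and is out of scope.
* CCDS entries are treated as genes as-is; no isoform collapsing or ID
  conversion to gene symbols is performed.
* Only the standard genetic code ships; every function accepts a
  `code` argument as the hook for alternative tables.
* GO-term enrichment itself is external: the package exports the
  ranked gene lists (`go_export_top500.txt`) and stops there.
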