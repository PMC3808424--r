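---
title: "Quantifying CpG methylation from methyl-sensitive cut counting and integrating it with expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CpG methylation from methyl-sensitive cut counting and integrating it with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccpipe)
```

## The measurement model

Methyl-sensitive cut counting (MSCC) measures CpG methylation at CCGG
motifs, the shared recognition site of the isoschizomer pair HpaII/MspI.
Two sequencing libraries are built per sample: a *methylation-sensitive*
library in which HpaII cuts only unmethylated sites, so its tags come from
unmethylated molecules, and an *inverse methylation-insensitive* library
(MspI) whose tags come from methylated molecules. Per site and condition we
therefore observe a pair of tag counts `(U, M)`.

`msccpipe` models the pair as independent Poisson draws,

$$U \sim \mathrm{Poisson}\!\big(d_U\,(1-m)\big), \qquad
  M \sim \mathrm{Poisson}\!\big(d_M\,m\big),$$

where `m` is the methylation fraction and `d_U`, `d_M` are per-library
depth factors. The estimator is the library-size-normalized share of
methylated-library signal,

$$\hat m \;=\; \frac{M/N_M}{\,M/N_M + U/N_U\,},$$

with `N_U`, `N_M` the per-library total mapped tags. For equal effective
depths this reduces to `M / (M + U)`; with unequal depths the normalization
removes the asymmetry, which is exactly what the `depth_asymmetry` knob of
the simulator exercises. A site with `U = M = 0` in a condition carries no
information and is flagged undefined rather than evaluated.

Two properties matter in practice:

* `m_hat` is invariant to multiplying both libraries' counts and totals by
  a common constant, so sequencing a library deeper does not move the
  estimate, only its precision.
* The totals `N_U`, `N_M` act as *depth* normalizers. They are exact when
  proportional to the per-library sequencing depth — the natural reading of
  fixed-throughput totals. When no library-info table is supplied the
  pipeline falls back to the column sums of the counts table; these are
  content-weighted (the insensitive-library sum grows with genome-mean
  methylation), which compresses estimates toward 0.5 whenever the genome
  mean is far from 0.5. Supply measured library totals where available;
  the fallback is a convenience, not a recommendation.

### Spike-in calibration

Each library set carries four internal standards mixed to known
methylation fractions 0, 1/3, 2/3 and 1. `fit_calibration()` fits the
least-squares line from the raw estimates at the standards to the known
fractions; `apply_calibration()` applies it (identically to both
conditions) and clamps to `[0, 1]`. Calibration is **off by default**: in
the Poisson model with correct normalizers the raw estimator is already
consistent, and the standards then mainly serve as a QC check. With fewer
than four measured standards calibration is unavailable and raw values are
used with a warning. The test suite verifies, by simulation at depth 1000
tags per library over 200 replicates, that the 1/3 and 2/3 standards are
recovered within two percentage points.

## Filters and thresholds

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 30 | per condition, combined `U + M` must reach this (inclusive); 60/100 used for coverage-stratified summaries |
| `change_cutoff` | 0.20 | absolute change in methylation *fraction* regarded as substantial (not a relative change) |
| `p_max`, `fc_min` | 0.05, 1.5 | expression filter: `p < 0.05` and fold change `> 1.5` or `< 1/1.5`, all strict |
| `min_promoter_sites` | 2 | genes with fewer measured promoter sites are excluded as noise-prone |
| `concordance_threshold` | 90 | promoter counts as directionally consistent when ≥ 90% (or ≤ 10%) of its sites moved one way; bounds inclusive |
| `site_change_cutoff` | 0 | promoter site direction calls use any nonzero delta by default; a positive value reclassifies small changes as `none` |

The coverage rule is applied *per condition*, not to the pooled pair: both
the control and the treated measurement must individually reach the read
floor, since a change is only interpretable when both endpoints are
measured. The concordance bounds are inclusive (`<= 10`, `>= 90`): the two
candidate readings ("more than 90%" versus "no more than 10% differing")
cannot be distinguished on available data — no observed promoter percentage
falls strictly between 90 and 100 — and the inclusive rule is the one that
admits boundary promoters (exactly one of ten sites differing) rather than
discarding them.

## Annotation conventions

Coordinates are 0-based, half-open throughout; BED input passes through
natively and GTF (1-based closed) is converted on read. The promoter
window spans 1500 bp upstream to 500 bp downstream of the TSS and is
strand-aware: `[tss-1500, tss+500)` on the plus strand and the coordinate
mirror `[tss-500, tss+1500)` on the minus strand, clipped at chromosome
edges. Strand-awareness is deliberate — "upstream" is a directional,
biological notion, and genes on both strands occur in any real gene set.

Signed TSS distance is negative when the site lies upstream of the TSS in
the gene's reading direction (so for a minus-strand gene a site at a larger
coordinate is upstream). Each site is assigned to exactly one nearest
gene; equidistant ties resolve toward the gene the site is downstream of,
then lexicographically by gene id — an arbitrary but deterministic rule.
Sites on chromosomes without genes are flagged and excluded from
TSS-based strata while still counting in genome-wide totals. Overlapping
islands are treated as a union for membership. A site inside two genes'
promoter windows is assigned to the nearest TSS only in the region
summaries, keeping the strata disjoint; per-gene promoter profiles, by
contrast, count every measured site inside the gene's own window, because
there the question is about that promoter, not about partitioning the
genome.

A half-open-interval subtlety: on the plus strand, promoter membership
corresponds to signed distances in `[-1500, 500)`, while on the minus
strand the mirrored window corresponds to `(-1500, 500]`. The property
tests assert exactly these flipped bounds.

## Concordance classification

Genes passing the expression filter are merged with promoter profiles
passing the site filter. With `direction` from the fold change and
`pct_hyper` the percentage of measured promoter sites that gained
methylation:

* `concordant_up`: up-regulated, `pct_hyper <= 10` (promoter hypomethylated);
* `concordant_down`: down-regulated, `pct_hyper >= 90`;
* `discordant_up` / `discordant_down`: the reversed pairings;
* `unclassified`: promoters between the thresholds.

Zero-change sites stay in the denominator of `pct_hyper` but in neither
numerator. Replaying the packaged 59-gene example table through this
classifier yields 53 `concordant_up` and 6 `concordant_down` genes and
nothing in any other class, which the acceptance script recomputes from
scratch.

```{r example}
rep <- concordance_report(classify_gene_table(load_concordant_gene_example()))
rep$counts
head(rep$table, 3)
```

## What the simulator emulates — and what it does not

`simulate_mscc()` generates, from a single seed: a small multi-chromosome
genome; genes with collision-free TSSs; CpG islands preferentially anchored
over promoter windows (`island_promoter_overlap`, default 0.7) with CCGG
sites placed at `island_density_ratio` (default 8) times the outside
density; a bimodal baseline methylome (island sites `Beta(1.5, 15)`, mean
~0.09; open-genome sites `Beta(8, 2)`, mean 0.8) reproducing the canonical
hypomethylated-island / methylated-genome structure; a treated condition in
which a fraction of promoters (default 0.2) is shifted by `shift_size`
(default −0.4, clamped to `[0, 1]`) while all other sites get truncated
Gaussian noise (sd 0.02) — enough to produce the near-diagonal scatter of
real two-condition comparisons without washing out effects; Poisson tag
counts at `mean_site_depth` (default 50, a realistic per-site tag yield for
a gigabase-scale MSCC library); the four spike-in standards at depth 1000;
and a DE table in which truth-up genes always exceed the 1.5-fold
threshold with `p < 0.05`, so truth recovery is a property of the
methylation side, not of a noisy DE caller.

The defaults above *are* the generative conditions used by the validation
suite; tests that need a specific regime (e.g. a guaranteed five sites per
promoter, or a strong −0.5 shift at depth 100) say so explicitly. The
validation problem sizes — up to 10,000 sites, ≤ 100 genes for the
brute-force oracles, 200 replicates for spike-in recovery, and a 60-gene /
4,000-site genome for the end-to-end recovery run — were chosen as the
smallest sizes at which the binomial/Poisson error bands in the checks are
meaningfully tight.

Deliberately not modelled: read-level sequence simulation, mapping
ambiguity, bisulfite chemistry, PCR duplicates, strand-resolved CCGG
handling, fragment-length bias, and biological replicates (the assay
design compared is one library set per condition). Passing tests therefore
demonstrate that the *computation* is correct under the stated count
model, not that the count model captures every artefact of a real
sequencing run.

## Numerical and degenerate-input choices

* `delta = 0` exactly yields direction `none` — zero-change sites are
  reported separately rather than forced into a hyper/hypo tie-break.
* `U = M = 0` sites are flagged undefined and excluded downstream; no
  `0/0` arithmetic occurs.
* Shifted fractions and noisy fractions are clamped to `[0, 1]`; clamping
  at the boundary is what creates exact-zero treated fractions, and those
  in turn give exactly-zero estimates (no methylated-library signal), which
  is why hypomethylation of an already-low promoter is still called
  consistently.
* Promoter windows at a chromosome edge are clipped, relaxing the 2000 bp
  width invariant rather than rejecting the gene.
* `pct_hyper` is reported to 4 decimal places in the report table,
  matching the precision convention of the packaged example.
* All analysis stages are seed-free and deterministic; reruns on identical
  inputs are byte-identical (verified via output checksums).

## Known limitations

* No statistical test is attached to per-site methylation change or to
  stratum enrichment; the method is threshold-based by design.
* The expression filter uses raw p-values (no multiple-testing
  correction), mirroring the filtering convention the packaged example
  table was built under.
* The column-sum fallback for library totals carries the content bias
  described above.
* Fold-change histogram bin edges are a required user parameter; no
  default binning is claimed.
* One nearest gene per site: a site genuinely regulated by two promoters
  is counted once in region strata.
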