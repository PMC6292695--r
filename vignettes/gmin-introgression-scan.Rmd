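---
title: "Detecting recent introgression with G_min and a coalescent null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent introgression with G_min and a coalescent null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gminscan)
```

## The model

`gminscan` targets species pairs so recently diverged that net divergence
is comparable to within-species diversity — the regime in which most of
the genome retains ancestral polymorphism and incomplete lineage sorting
(ILS) mimics gene flow. The scan statistic is

$$G_{\min} = \frac{\min[D_{XY}]}{\bar D_{XY}},$$

the minimum over all cross-population haplotype pairs of the per-site
sequence distance in a window, divided by the mean over the same pairs.
Its virtue over raw distances is that it responds to the *genealogical
configuration* rather than the local mutation rate: under strict
allopatric divergence all cross pairs coalesce in the ancestral
population, the minimum approaches the mean, and $G_{\min}\to 1$ with
vanishing variance; a haplotype that crossed the species boundary
recently and still segregates at low-to-intermediate frequency creates
one anomalously close cross pair and drags $G_{\min}$ down. ILS alone
cannot do this, because an ancestrally retained lineage is old by
construction.

### The null and its assumptions

Significance is assessed per window by Monte Carlo simulation of a
*clean split*: two populations of equal constant size that separated
$\tau$ units of $4N$ generations ago, no migration, neutral
infinite-sites mutation, optional crossover. The assumptions that
matter:

- **Equal, constant sizes.** Asymmetry or growth changes the null
  $G_{\min}$ distribution; the scan should be run separately for
  genomic partitions with different effective sizes (X vs autosomes),
  with priors calibrated per partition.
- **Per-window θ from observed divergence.** The local mutation rate is
  nuisance; we set $\theta = D_{XY} \cdot L / (2\tau + 1)$ so that the
  null reproduces the window's observed mean cross-population distance
  in expectation ($E[\bar d] = \theta(2\tau+1)$ under the split model —
  verified against simulation in the tests). A `direct` mode
  ($\theta = D_{XY}\cdot L$) is available for sensitivity analysis; the
  expectation-matched form is the default because a null that does not
  reproduce the observed divergence tests the wrong hypothesis.
- **Recombination as a nuisance with uncertainty.** For each simulated
  replicate a crossover rate is drawn from a truncated-normal prior
  whose mean comes from a genetic map (converted from cM by
  $\rho = 4 N_{\mathrm{sim}} c$, default $N_{\mathrm{sim}} = 10^6$) and
  whose variance is the arm-level variance of the map estimates.
  Recombination tightens the null $G_{\min}$ distribution (more
  independent genealogies per window), so ignoring it is
  anti-conservative for low-recombination regions; drawing one rate per
  replicate (not per window) propagates map uncertainty into the null.

### P-values, FDR, tracts

The Monte Carlo p-value is the add-one estimator
$p = (1 + \#\{G_{\min}^{null} \le G_{\min}^{obs}\})/(1 + R)$, which is
never zero and gives valid (slightly conservative) tests; uniformity
under the self-simulated null is checked in the acceptance suite at the
scale of 500 windows × 2,000 replicates. The default threshold is
$\alpha = 0.001$ with a plug-in FDR summary
$\mathrm{FDR} = \pi_0 m \alpha / R$; $\pi_0$ uses Storey's estimator at
$\lambda = 0.5$ by default, with a fixed-value override so published
summaries computed under other $\pi_0$ conventions can be reproduced.

Significant windows are merged into tracts, bridging up to
`gap_tolerance` consecutive non-significant windows (default 1). The
bridging rule exists because a long introgressed haplotype eroded by
recombination produces *nearly* contiguous runs; "nearly" is not a
standard quantity, so the tolerance is an explicit flag rather than a
hidden heuristic. Tract-level analyses (Spearman correlations of length
against mean $G_{\min}$, minimum distance, and local crossover rate;
the segment-placement permutation test) use permutation p-values
throughout.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| window size | 10,000 | bp | small enough that one genealogy dominates, large enough for stable distances |
| retention threshold | 0.5 | fraction callable | windows with less than half their sites callable give noisy distances |
| `tau` | 0.61 | 4N generations | split time of the target species pair in the scan this design follows |
| `n1`, `n2` | 10, 20 | haplotypes | the two population samples |
| `locus_length` | 10,001 | sites | simulated lattice for infinite-sites mutation |
| `replicates` | 1e5 | — | resolves p-values to 1e-5; scans in the tests use 2e3 for speed |
| `alpha` | 0.001 | — | threshold at which the plug-in FDR is ~5% in a genome-scale scan |
| `min_overlap` | 100 | sites | a haplotype pair with fewer comparable sites gives an unstable distance |
| `gap_tolerance` | 1 | windows | bridges single eroded windows inside a tract |
| `N_sim` | 1e6 | diploids | effective size for the cM→ρ conversion |

## The synthetic-data generator

`generate_dataset()` emulates the study design the scan was built for:
10 + 20 haploid samples, `tau = 0.61`, 10-kb windows, and a target
per-site between-population divergence of 0.01, from which the
per-window θ follows by the same expectation-matching used in the null.
Introgression is modeled as mass-migration pulses — at a chosen time
each destination lineage jumps to the source population with the pulse
proportion — because pulses give an unambiguous per-window truth label
(does the realized genealogy carry a migrant lineage?), which
continuous migration does not. Callable masks draw per-window callable
fractions from Beta(8, 2) (mean 0.8, a realistic tail of windows
failing the 50% rule), and the genetic map draws per-window cM
estimates from a truncated normal.

What the generator does *not* emulate, and what passing tests therefore
do not establish about real data:

- **Windows are unlinked and internally non-recombining.** Real 10-kb
  windows recombine internally and are correlated along the
  chromosome; simulated tract structure comes only from pulse sharing
  across windows, not linkage.
- **Within-species diversity is tied to the split model.** Under a
  clean split with equal sizes, expected within-population diversity is
  $\theta/L \approx 0.0045$ per site when divergence is calibrated to
  0.01 — lower than in real data from this regime, where retained
  ancestral variation makes diversity comparable to divergence (and net
  divergence can be negative). Statistics that contrast within and
  between (D_A, F_ST) are therefore exercised in a somewhat easier
  regime than reality.
- No selection, no demographic change, no sequencing error beyond the
  callable mask.

## Numerical choices

- **Coalescent scaling.** Time in units of 4N generations, pairwise
  coalescence rate 2 within a deme, mutations Poisson with mean
  θ × branch length — so $E[S] = \theta a_1$ and
  $E[\bar d_{XY}] = \theta(2\tau+1)$, both verified against the
  implementation by simulation.
- **Infinite sites on a lattice.** Mutations land on discrete positions
  with collisions resolved by resampling, so replicate matrices are
  exchangeable with ms-format text.
- **Backends.** The internal compiled coalescent supports ρ = 0 and is
  the self-contained validation backend; ρ > 0 shells out to the
  msprime library through `python`, with a Kolmogorov–Smirnov
  backend-agreement test at ρ = 0 tying the two together. Scans are
  reproducible: per-window child seeds are derived deterministically
  from the root seed.
- **Pairwise-complete distances.** A site missing in either member of a
  pair is treated as uncallable for that pair, and each pair is
  normalized by its own comparable length; pairs below `min_overlap`
  comparable sites are dropped, and a window where every pair drops is
  NA rather than a guess.
- **Degenerate windows.** $\bar D_{XY} = 0$ makes $G_{\min}$ NA (logged
  and skipped, never coerced to 0 or 1); S = 0 makes Tajima's D NA;
  fewer than two non-singleton biallelic sites make ZnS NA.
- **Fractional χ² counts.** Frequency-weighted ABBA/BABA sums are
  fractional; the region contrast uses them as-is by default (with a
  `round` option), falling back to Fisher's exact test on rounded
  counts when an expected cell drops below 1.

## Open design decisions

Choices the method description leaves genuinely open, and what this
package does:

- **F_ST estimator.** Both a Weir–Cockerham-type variance-components
  ratio-of-sums (default) and Hudson's $1 - \pi_W/\pi_B$ are provided;
  the Slatkin depth conversion $(1+F)/(1-F)$ is estimator-agnostic.
- **Ancestral/derived partition.** A population's polymorphism counts
  as "retained ancestral" when its derived allele is also observed in
  the sister species, and "new derived" when private — the sharing
  dichotomy is the only one computable from two focal samples plus an
  outgroup.
- **ρ draws.** One draw per replicate (not per window), as uncertainty
  propagation; the per-window alternative would understate null
  variance.
- **Replicates per window.** 1e5 by default, tunable; p-values at the
  default α only need 1e3+.
- **5-kb scans.** Any window size is supported; the null is regenerated
  per scan, never recycled across window sizes.

## Problem sizes in the tests

The suite runs the calibration check at 500 windows × 2,000 replicates,
the pulse-recovery check on two 1-Mb chromosomes (200 windows) against
a pulse-free genome of the same size, brute-force equivalence on
hundreds of ≤6×6 matrices, and D-statistic power on 25 + 25 replicate
150-locus panels — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping every Monte Carlo comparison inside
its stated confidence band.

## Limitations

$G_{\min}$ is blind to introgressed haplotypes that have fixed in the
recipient (the minimum and mean then move together), is agnostic about
the direction of introgression, and loses power as introgressed
lineages age. The null's constant-size assumption makes the scan
sensitive to unmodeled bottlenecks; the plug-in FDR inherits whatever
miscalibration the null has. Phasing error in non-inbred data inflates
apparent minimum distances and is not modeled.
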