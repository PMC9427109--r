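---
title: "Methods: analysing a balanced supergene polymorphism with sgscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing a balanced supergene polymorphism with sgscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the model

`sgscan` analyses a two-arrangement supergene of the kind segregating on
white-throated sparrow chromosome 2. A standard arrangement (ZAL2) and a
rearranged arrangement (ZAL2m) are held at roughly 3:1 chromosome
frequencies by near-obligate disassortative mating between the two
plumage morphs: tan-striped birds (TS) are ZAL2/ZAL2 homokaryotypes,
white-striped birds (WS) are ZAL2/ZAL2m heterokaryotypes, and the rare
super-white class (SW) is ZAL2m/ZAL2m. Because almost every pairing is
WS x TS, the rearranged arrangement lives in a near-constant state of
heterozygosity, and crossing-over inside the rearranged span is
suppressed in heterokaryotypes. The package implements the downstream
population-genomic toolchain for such a system — fixed-difference
discovery, chromosome-of-origin phasing, coverage-corrected window
statistics, sweep and balancing-selection scans, haplogroup analysis,
and allele-specific-expression integration — together with a forward
simulator that generates every input the toolchain consumes.

# The simulator: a stated world

`sim_config()` / `simulate_population()` implement a discrete-generation
Wright-Fisher population of `N` diploids on a single contig with an
inversion span `[a, b)`:

* **Mating.** Each offspring draws a WS x TS parent pair with
  probability `fidelity` (default 0.99, matching the field observation
  that same-morph pairings are rare), otherwise a uniformly random
  fitness-weighted pair. Parent sampling is fitness-weighted within
  class, i.e. viability selection applied at parent sampling.
* **Recombination.** Crossovers arise at `rec` per bp per generation;
  inside `[a, b)` the rate is multiplied by `c_suppress` (default 0)
  when the transmitting parent is a heterokaryotype. Homokaryotypes
  (TS, and the rare SW) recombine at the full rate everywhere, which is
  exactly the leak of recombination the field attributes to rare
  rearranged homozygotes.
* **Mutation.** Finite sites on the integer grid at `mu` per bp per
  generation; position collisions are re-drawn; sites lost or globally
  fixed are pruned.
* **Selection.** An optional sweep allele multiplies fitness by `1+s`
  per copy carried *on its arrangement class*, introduced at a set
  generation and re-seeded if lost (conditioning on establishment). An
  optional balanced locus inside the inversion applies negative
  frequency-dependent selection (NFDS) among rearranged haplotypes:
  carriers of allele A on a ZAL2m haplotype get the multiplier
  `1 + s_b (0.5 - freq(A | ZAL2m))`. NFDS is a modelling choice: the
  empirical system shows balancing selection without identifying its
  mechanism, and NFDS is the simplest mechanism that holds two
  haplogroups at intermediate frequency.

## Initial conditions and rate rescaling

Desk-scale runs (default `N = 500`, 1 Mb, 2000 generations) cannot grow
either equilibrium diversity or an ancient arrangement divergence from
a monomorphic start, so the initial state encodes what forward time
cannot produce:

* **Standing variation** is seeded with expected count
  `theta L a_{2N-1}` at frequencies drawn from the neutral `1/i`
  spectrum. Starting monomorphic instead would leave a star-like
  genealogy and a strongly negative Tajima's D at sampling time; the
  spectrum start keeps the neutral calibration honest.
* **Arrangement fixed differences** are seeded inside the inversion at
  `init_fd_density = 5e-3`/bp. The real rearrangement is 2-3 My old and
  carries on the order of 1e-2 fixed SNPs per bp; 2000 generations of
  forward time would produce essentially none.
* **Rates are rescaled**, the standard forward-simulation compromise:
  `mu = 1e-7` and `rec = 2e-7` per bp per generation keep
  `theta = 4 N mu = 2e-4` and `rho = 4 N r = 4e-4` per bp at realistic
  magnitudes with `N = 500`.
* For a balanced locus, **two backbone haplogroups** are seeded at
  50/50 among rearranged haplotypes with diagnostic-site density
  `1.8e-3`/bp across the inversion, which reproduces the observed
  outlier-region diversity scale (pi ~ 1e-3, roughly tenfold the
  rearranged-class background).

Two population-genetic consequences of the stated world are worth
knowing because they shape several tests. First, *class-conditional
coalescence*: inside the inversion a ZAL2 lineage can only coalesce
with other ZAL2 lineages, so neutral diversity inside the span is
`2 n_class mu` with `n_class` the class's haplotype count — about 0.75x
the genome background for ZAL2 and 0.25x for ZAL2m. The within-class
reduction for ZAL2m (and the expected Ne ratio of 1/3 under balanced
morphs, `arrangement_count_ratio()`) follows directly. Second,
*whole-span linkage*: with `c_suppress = 0` the rearranged class is
effectively asexual inside the inversion (barring rare SW
transmissions), so any selective event on ZAL2m — a sweep, or balanced
backbones — imprints on the entire span at this scale, not on a local
window. Localized ZAL2m sweep signals of the kind seen on a 100 Mb
chromosome over deep time are physically unattainable on a 1 Mb
desk-scale contig; the sweep-recovery tests therefore place the sweep
on the recombining standard arrangement.

## What the generator does not emulate

Read mapping and mapping bias (fragments are abstract
(position, allele) observations), sequencing-depth heterogeneity beyond
a Poisson DP field, indels and multi-allelic sites, gene conversion,
overlapping generations, geographic structure, and batch structure in
expression data. A green recovery test therefore establishes that the
statistics recover the simulated signal, not that they would survive
every artefact of a real sequencing study.

# Phasing by fixed differences

`call_fixed_differences()` applies the morph pattern — all TS
homozygous for one allele, all SW homozygous for the other, all WS
heterozygous — with a configurable per-class missingness allowance
(default 0, mirroring the "no missing information" filter).
`pattern_null_probability(n_TS, n_WS, n_SW, labelings)` gives the
chance of that pattern at one site under independent Hardy-Weinberg
genotypes at frequency 0.5:
`labelings * (1/4)^(n_TS+n_SW) * (1/2)^n_WS`. With the study's sample
sizes (13/49/1) and `labelings = 2` (two assignments of alleles to the
homozygote classes) this is 1.32e-23; the printed literature value
2.6e-23 corresponds to a multiplicity of 4 and is treated as an upper
bound.

Fragment assignment (`assign_fragments()`) labels a fragment by perfect
concordance of its alleles at overlapped fixed-difference sites;
mixtures are `conflict` and discarded rather than majority-voted (the
conservative behaviour of read-sorting tools). Pseudo-haplotypes
(`build_pseudo_haplotypes()`) take the majority allele among a sample's
class-labelled fragments, require `min_support` observations, leave
ties missing, and phase TS/SW samples directly from homozygous
genotypes — heterozygous sites in homokaryotypes are left missing on
both haplotypes rather than randomly phased, to avoid fabricating
haplotype structure.

One practical note: the study-style site filters include a
population-level MAF cut (0.05). Variation private to the rearranged
class segregates at a quarter of its within-class frequency in the
population, so that cut selectively removes class-specific variants;
analyses of class-resolved diversity in the tests disable it.

# Window statistics

All per-window denominators use *accessible length* — the overlap of
the window with the user-supplied accessibility mask — rather than the
window span, correcting the upward bias that arises when a
variants-only VCF cannot distinguish missing sequence from monomorphic
sequence. Windows are fixed-size 0-based half-open tiles (10/25/50 kb);
trailing partial windows are dropped. Pi uses the unbiased per-site
estimator `n/(n-1) 2p(1-p)` with per-site non-missing counts; F_ST is
Hudson's estimator as a ratio of sums (the source study does not name
its estimator; Hudson's is the standard choice for haplotype data);
Tajima's D follows the 1989 constants; the folded SFS supports
singleton exclusion (applied to variant counting, never to pi);
pi_N/pi_S uses Nei-Gojobori mutational-opportunity site counting
(sense-to-stop changes count as nonsynonymous, stop-to-stop as
synonymous, and the terminal stop codon participates so that site
counts conserve the CDS length) aggregated over 20-gene windows with
5-gene steps.

# Selection scans

The H statistic at a focal position is the mean, over haplotype pairs,
of the length of the maximal tract around the focal position free of
pairwise differences, truncated at the contig ends (a conservative
choice that deflates H near edges; the original tool's edge handling is
undocumented). Focal positions default to the segregating sites. Window
summaries take the maximum H per window; empirical p-values rank each
window within SNP-count bins (50-SNP increments, merged above 100
SNPs), counting the window itself so p >= 1/bin-size; candidates are
windows with p < 0.05 strictly.

Because the empirical p has support `{k/m}` for bin size `m`, the
candidate rate attainable below 0.05 is `(ceil(0.05 m) - 1)/m`. On the
default 1 Mb contig with 25 kb windows (m = 40) that is 0.025 — outside
any +/-3 SE band around 0.05 *by construction*, before any data are
seen. The calibration and sweep-recovery tests therefore run the scan
on 10 kb windows (one of the study's window sizes), where m ~ 100 gives
an attainable rate of 0.04.

Sweep recovery is asserted at footprint level: measured completed
sweeps place their top-H focal sites on the flanks of the swept region
(the centre retains few or no focal SNPs), so the test requires every
candidate window to fall within the sweep footprint (+/-150 kb,
~`1/(r_eff T_sweep)`), with at least one candidate — an event with
probability below ~1% on a neutral track — rather than pinning the
single window containing the swept site, which the flank effect makes
unstable at this scale.

The beta statistic is a declared stand-in for BetaScan's weighting: for
each core SNP, neighbours within `window_bp` are weighted by a
triangular kernel `max(0, 1 - |f_i - f_core|/d)` on folded frequencies
(`d = 0.2`), rescaled by the expected weight under a uniform folded
frequency so the neutral expectation is ~0, and `beta = theta_beta -
theta_W`. It is validated by recovery properties, not by equivalence to
BetaScan. In the balanced scenario the rearranged span contributes well
over 5% of all cores, so the recovery test compares the balanced-locus
beta against the 95th percentile of *background* cores (outside the
span); a genome-wide percentile would be dominated by the signal
itself. Patterson's D uses the standard per-site ABBA/BABA frequency
products summed per window.

# Region analysis and haplogroups

`detect_outlier_regions()` flags maximal runs of at least `min_windows`
(default 5) consecutive windows with pi above the track's 95th
percentile — our operationalization of the study's multi-scaffold
outlier region — and attaches a permutation p for elevated Tajima's D
from circular rotations of the window sequence, which preserve the
track's autocorrelation (the study's permutation scheme is
unspecified). Haplogroups are found by average-linkage hierarchical
clustering of pairwise Hamming distances with the group count chosen by
mean silhouette over k = 2..5 and groups below 3 haplotypes reported as
ungrouped — replacing the study's manual genotype-plot inspection, and
mirroring its exclusion of an n = 2 putative third group.
`genotype_plot_matrix()` reproduces the major/minor/missing genotype
plot against the rearranged-homozygote reference.

# Expression integration

`allelic_bias()` tests per-gene rearranged-allele proportions against
0.5 with a one-sample Wilcoxon signed-rank test and BH correction
(genes where every sample sits exactly at 0.5 get p = 1).
`gene_h_assignment()` gives each gene the H value of its overlapping
20 kb bin, averaging when a gene spans bins. `ab_h_association()` is an
ordinary least-squares fit of log2 allelic ratio on log2 H — a
documented simplification of the study's mixed models with
batch/tissue random effects; batch structure is not simulated, so
nothing is lost at desk scale. `morph_bias_enrichment()` is the
two-proportion z-test comparing differential-expression fractions
inside and outside the rearrangement, with a Fisher fallback for empty
margins. The DE calls themselves are upstream inputs (out of scope).

# Scenario parameters used by the tests

| Scenario | Changes from default | Used for |
|---|---|---|
| default | — | calibration, fragments, expression coupling |
| sweep | `sweep = list(pos 512500, class 0 (ZAL2), s 0.15, start 1880)` | sweep recovery |
| balanced | 2 Mb contig, inversion [0.95, 1.05) Mb, `balanced = list(pos 1e6, s_b 1)` | outlier region, haplogroups, d_XY ordering, beta |
| phasing | `fidelity = 0.85` | fixed-difference precision/recall |

The phasing scenario lowers mating fidelity because the
fixed-difference caller *requires* an SW sample: at `fidelity = 0.99`
the expected SW count in 500 birds is ~0.3 (most runs contain none),
while 0.85 keeps SW rare (~0.9% of birds, matching their rarity in the
wild, where an SW bird nonetheless appeared in a 63-bird sample) but
present. The sweep sits on the standard arrangement for the
physical reason given above; its start generation places fixation
shortly before sampling so the haplotype tracts have not eroded.
Module-level property tests run a scaled-down scenario (N = 150,
300 kb, 500 generations) to stay inside the suite's time budget; the
acceptance tests run the full default scale.

# Numerical choices and degenerate inputs

Ties in pseudo-haplotype votes are missing, not broken randomly.
Windows with zero accessible length or no segregating sites give `NA`
statistics. The empirical p includes the focal window in its own null
count, guaranteeing p > 0. Distance pairs with a monomorphic member are
skipped in LD decay. `quantile()` type 7 defines the outlier threshold.
The Ne-ratio bootstrap resamples windows (block = window, 1000 reps).
Missing haplotype alleles are handled pairwise-complete in Hamming
distances and H tracts. All simulator randomness flows through R's RNG,
so a `sim_config` seed fixes the run byte-for-byte.

# Known limitations

Single-contig simulations; no indel or multiallelic support; CLI
`stats`/`scan`/`regions` subcommands operate on the phase TSV format
only; configuration files are JSON (no YAML parser in the supported
dependency set); the beta statistic approximates, and does not
reproduce, BetaScan; mixed-effects expression models are replaced by
OLS; the H-scan window-size discrepancy in the source material (25 kb
in methods, 50 kb and 20 kb in results contexts) is resolved by making
the window size a parameter everywhere.
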