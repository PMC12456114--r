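---
title: "Simulating local-ancestry-aware captive breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating local-ancestry-aware captive breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labreed)
```

`labreed` simulates a captive breeding program for a population whose
founders carry introgressed ancestry from a related population, and asks
how selection rules that exploit *local ancestry* — the per-segment,
per-haplotype assignment of genome to source population — trade off
introgression removal against loss of the target population's own
diversity. This vignette documents the model, its assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
construction existed.

## The haplotype model

One generation is an `N × 2 × L` triple of aligned arrays: genotype `G`
(binary alleles), ancestry `A` (1 = target, 0 = introgressed) and founder
labels `F`. Founder labels implement an exact local pedigree: at the
founder generation, individual `i`'s haplotypes receive the constant labels
`2i − 1` and `2i`, and labels are inherited unchanged through meiosis.
Identity-by-descent between any two haplotypes at any locus is therefore an
exact indicator `I(F = F')`, not an estimate. On real data `F` is not
observable — the package treats every input haplotype as a founder
haplotype, so kinship is measured relative to the input generation —
while `A` would come from a local-ancestry inference pipeline upstream.

Meiosis is a no-interference crossover process on a chromosome of genetic
length `D` Morgans: starting from a uniformly chosen haplotype at position
0, segment lengths are i.i.d. Exponential(1) in Morgans and the active
haplotype flips at each breakpoint. The breakpoint count on the chromosome
is thus Poisson(`D`). Marker-level haplotype switches slightly undercount
that process (two crossovers inside one inter-SNP gap cancel; the expected
shortfall is about `D²/L`), so `simulate_gamete()` records the true
breakpoint count alongside the inheritance vector and `count_crossovers()`
prefers it. There is no mutation, no interference, no sex-specific map and
no sex structure; generations are discrete and non-overlapping. SNPs are
evenly spaced by default (`R_l = lD/L`), with a hook for custom strictly
increasing position vectors.

## Selection measures

Seven pairwise measures compare potential parents, each an expectation over
the four equiprobable haplotype pairs an offspring could inherit, averaged
over loci: kinship `K` (founder-label sharing; minimize), heterozygosity
`H` (allelic mismatch; maximize), target admixture `Q` (ancestry dose;
maximize), their ancestry-masked versions `PH` (heterozygosity masked to 0
where the pair is not fully target ancestry; maximize) and `PK` (kinship
masked to 1; minimize), and weighted blends `WPH = (1−δ)Q + δPH`,
`WPK = (1−δ)(1−Q) + δPK`. The default `δ = 0.5` weights diversity and
ancestry dose equally; per realized locus it yields the values
0 / 0.25 / 0.5 / 1 (weights 0:1:2:4) for no / one / two-identical /
heterozygous target alleles.

Two implementation routes exist deliberately. `per_locus_pair_measure()`
evaluates each kernel by explicit enumeration of the four haplotype pairs;
`expected_pair_matrix()` computes all `N²` entries at once from matrix
cross-products over haplotype tracks (founder-label matching uses a sparse
one-hot encoding with the label space compacted to the labels still
segregating). The test suite checks both against a third, independent
oracle that enumerates hypothetical offspring and averages their realized
single-individual statistics, and against Monte-Carlo means over simulated
offspring.

The matrix diagonal is computed with the same kernels at `i = j` (so
self-kinship is at least 0.5); it participates in ranking averages only —
self-pairs are never bred.

## The breeding program

Ranked-mean selection proceeds in two stages. *Ranking*: iteratively
compute each remaining individual's breeding score as the mean of its
pairwise measure over the other remaining individuals, and eliminate the
worst onto a stack. The self term is excluded from the mean: including it
would add a constant-like ≥ 0.5 kinship component that pushes all scores
toward uniformity. Ties break by ascending index, making runs fully
reproducible from the seed. *Pairing*: consume the stack best-first, two
per pair; each pair draws a Poisson(4.2) brood until the fixed capacity
`N = 150` is reached. The last brood is truncated to hit `N` exactly; if
all pairs are consumed while short of capacity, pairing restarts from the
best pair with fresh draws; with an odd pool the single worst individual
sits out the cycle.

Under a compliance rate `c < 1`, each recommendation is followed with
probability `c`; otherwise the *recommended partner* is skipped (returning
to the unpaired pool) and a substitute is drawn uniformly from the unpaired
individuals ranked below the proposing parent. The proposing parent itself
is never displaced.

The threshold rule ranks individuals by their realized individual score for
the chosen measure, keeps the fraction above the quantile (default: the
better half, `N − floor(qN)` individuals, ties by index) and mates the
survivors randomly (distinct uniform parents per offspring).

`RANDOM` bypasses measures entirely: each offspring draws two distinct
uniform parents (Wright–Fisher), which is the neutral-drift baseline.

## The simulated study population

Two source populations diverge from a common ancestor under the
Balding–Nichols model: ancestral frequencies `f ~ U(0.05, 0.95)` per locus
and population frequencies `Beta(f(1−F)/F, (1−f)(1−F)/F)` with drift
`F = 0.2` each, so `E[(f_A − f_I)²]/(f(1−f)) = F_A + F_I = 0.4` by
construction (`F = 0` degenerates to a point mass). Haplotypes are drawn
Bernoulli per locus — linkage equilibrium within sources; linkage
disequilibrium then accrues mechanistically through admixture and drift.

The wild history runs `T_init` Wright–Fisher generations in which each
parent of each offspring comes from the (static) introgressing panel with
probability `alpha[g]` — the default schedule is a two-generation pulse of
0.2, giving expected introgression `1 − 0.8² = 0.36`. Captive formation
takes two further generations: a uniform *bottleneck* sample (fraction
0.25) whose members become the labelled founders, one round of random
breeding at the bottleneck size, then *selection* of the least introgressed
quarter, bred up to `N = 150`. The introgression pulse is therefore
`T_init + 2` generations old when the program starts, and that age is the
`delay_generations` sweep parameter. The two captive-formation steps at
defaults bring mean introgression from 0.36 to roughly 0.25–0.28.

Source panel sizes are not prescribed by the study design beyond being
"large"; both default to 500 diploids, big enough that source-panel drift
over ten generations is secondary to the pulse and bottleneck. Where a
*specific* initial introgression level is required (the
`initial_introgression` sweep), the pulse rate is set to
`alpha = 1 − sqrt(1 − q_raw)` and `q_raw` is calibrated by a short
multiplicative fixed-point search (3 simulated captive formations per
iteration, tolerance 0.02) so the *post-selection* captive mean matches the
target; the calibration mechanism is this package's own construction.

## Demography

The Poisson brood mean 4.2 is derived from a stud-book style schedule:
brood-size distribution (0.23, 0.36, 0.30, 0.10, 0.01) over 1–5 young
(mean 2.3), and a per-age breeding probability
`0.5 · (1 − 0.3) · (1 − 0.1)^(a−1)` for ages 1–7 (summing to 1.83 expected
attempts; 2.3 × 1.83 ≈ 4.2). The schedule is implemented exactly as that
product reads — the 30% first-year survival enters as the single factor
`(1 − 0.3)` at every age — rather than re-derived as a life table; note
the literal formula makes the result *decrease* in first-year survival,
which is a property of the printed calculation, not of a survival model.

## The wildcat-like synthetic fixture

`make_wildcat_like_fixture()` emulates the summary statistics of a small,
heavily admixed felid panel observed on one chromosome: 36 diploids on a
1.26-Morgan map (default 2,000 SNPs; the full-scale panel would have
17,720, and the SNP count only changes measurement granularity), with
per-haplotype target-ancestry fractions of mean ≈ 0.6 spanning roughly
0.14–1. It is generated by the package's own wild history — pulse rate
sized for 40% mean introgression (`1 − (1−a)² = 0.4`), `T_init = 6` so
ancestry tracts are long and per-haplotype fractions spread widely — and
is synthetic throughout: no real genotypes are consumed or distributed.
The captive program is then founded the way the real program would be:
rank by genome-wide target fraction, keep the top 24 as labelled founders,
and expand to 150 by one random-breeding step.

What the fixture does *not* emulate: real site-frequency spectra and LD
from deep coalescent history, local-ancestry inference error (ancestry
here is exact by construction), variable recombination rate, and
relatedness structure among the sampled 36. Conclusions from it are about
the breeding algorithms under realistic ancestry-tract geometry, not about
any particular real population.

## Numerical and design choices

- **Defaults**: `N = 150`, `D = 5` Morgans, `L = 500` SNPs, `δ = 0.5`,
  offspring mean 4.2, compliance 1, `T_init = 10`, pulse 0.2 × 2,
  bottleneck and selection fractions 0.25, drift 0.2 + 0.2, horizon 20
  generations. `L = 500` was chosen where two plausible defaults existed
  (500 vs 2,000); `L` is exposed in every constructor.
- **Determinism**: a single R RNG stream drives everything; drivers derive
  per-replicate seeds (kept below 2³¹) so any replicate reproduces in
  isolation. Scripted gametes (`start_hap`, `seg_lengths`) allow exact
  hand-traced replay in tests.
- **Tie-breaks**: all argmin/argmax ties (ranking, threshold retention,
  captive selection) break by ascending index.
- **Degenerate inputs**: `L = 0` maps give empty gametes; a breakpoint
  exactly on a SNP starts the new segment at that SNP (`p_b ≤ R_l < e_b`);
  self-mating is rejected; threshold retention below two individuals is an
  error.
- **Compliance evaluation horizon**: on the 1.26-Morgan fixture, every
  compliance level removes essentially all introgression within 20
  generations, so compliance effects are compared at a 10-generation
  horizon, where the recovery-speed differences the compliance model
  creates are identifiable.
- **Problem sizes in tests**: the test suite runs full-scale
  (`L = 500, N = 150`) for the strategy-ordering and deintrogression
  checks (10 and 6 replicates respectively), `L = 2000` for the fixture
  compliance check (8 replicates), and reduced panels (tens of
  individuals, ≤ 120 SNPs) for algebraic and structural properties, where
  scale adds nothing. Monte-Carlo checks use 10⁴ gametes/offspring or 10⁵
  frequency draws with 3-standard-error acceptance bands.

## Known limitations

Discrete generations without age or sex structure; no mutation; no
fitness consequences of inbreeding or outbreeding; ancestry and IBD are
exact rather than inferred, so all results are upper bounds on what noisy
local-ancestry calls would deliver; kinship from genotype-based IBD
estimation is out of scope, as are the upstream bioinformatics (alignment,
variant calling, phasing, local-ancestry inference). The threshold rule
and compliance model are deliberately simple stand-ins for the range of
constraints real programs face.
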