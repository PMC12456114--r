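# labreed

Local-ancestry-aware selection for hybridized captive breeding programs.

## The problem

Captive breeding programs for threatened populations are sometimes founded
from individuals that carry *introgressed* ancestry — genomic segments
inherited from a related, more numerous population that has hybridized with
the conservation target (genetic swamping). Classical breeding management
minimizes mean kinship or maximizes heterozygosity, but neither can tell a
diverse target-population haplotype from a diverse introgressed one:
selecting for diversity retains introgression, and selecting against
introgression alone collapses diversity.

Modern sequencing pipelines can assign a source population to every segment
of every phased haplotype (*local ancestry*). `labreed` asks and answers,
by forward-time simulation with exact haplotype tracking, the question: how
effectively can a breeding program use local ancestry to purge introgressed
DNA while keeping the target population's own diversity?

## The machinery

The simulator tracks one generation of `N` diploids as three aligned
`N × 2 × L` arrays over `L` SNPs: genotype `G` (0/1 alleles), local
ancestry `A` (1 = target, 0 = introgressed) and founder labels `F` (which
founder haplotype each segment descends from — an exact local pedigree, so
identity-by-descent is read off rather than estimated). Meiosis is an
independent crossover process: segment lengths are Exponential(1) in
Morgans, giving Poisson(`D`) crossovers per gamete on a `D`-Morgan
chromosome, and all three tracks are propagated with the same inheritance
vector.

Pairs of potential parents `i, j` are compared through pairwise expected
measures, each an average over the four equiprobable haplotype pairs
`(a, b)` an offspring could inherit and over loci:

- kinship `K_ij = mean over l of (1/4) Σ_ab I(F_ial = F_jbl)` (minimize);
- heterozygosity `H_ij = mean (1/4) Σ_ab I(G_ial ≠ G_jbl)` (maximize);
- target admixture `Q_ij = mean (1/8) Σ_ab (A_ial + A_jbl)` (maximize);
- population heterozygosity
  `PH_ij = mean (1/4) Σ_ab I(A_ial + A_jbl = 2) I(G_ial ≠ G_jbl)` —
  heterozygosity with non-target haplotype pairs masked to 0 (maximize);
- population kinship
  `PK_ij = 1 − mean (1/4) Σ_ab I(A_ial + A_jbl = 2) I(F_ial ≠ F_jbl)` —
  kinship with non-target pairs masked to 1 (minimize);
- weighted versions `WPH = (1−δ) Q + δ PH` and
  `WPK = (1−δ)(1−Q) + δ PK`, with `δ = 0.5` by default. Per realized locus
  at `δ = 0.5`, WPH scores 0 / 0.25 / 0.5 / 1 for no target allele / one
  target allele / two identical target alleles / heterozygous target
  alleles — relative weights 0:1:2:4.

Breeding uses ranked-mean selection: iteratively eliminate the individual
with the worst mean pairwise score against the remaining pool, then pair
from the best end of the resulting stack downwards, each pair drawing a
Poisson brood (mean 4.2, derived from a stud-book demographic schedule)
until the fixed capacity `N` is reached. A compliance rate `c < 1` replaces
recommended partners with random lower-ranked ones; a simpler threshold
rule (keep the better half, mate randomly) is also provided.

Study populations are simulated from a common ancestor via the
Balding–Nichols model (`f_pop ~ Beta(f(1−F)/F, (1−f)(1−F)/F)`, drift
`F = 0.2` per population, divergence 0.4 by construction), followed by a
two-generation introgression pulse, neutral drift, and captive formation by
a sampling bottleneck plus selection of the least introgressed quarter.

## Worked example

```r
library(labreed)
set.seed(1)
cfg <- program_config()            # N = 150, D = 5 Morgans, L = 500 SNPs
cap <- simulate_captive_founders(cfg$history, cfg$map)
cap
#> <hap_panel> generation 0: 150 diploids x 500 SNPs
#>   mean target ancestry: 0.7403
tr <- run_program(cap, breeding_config("PK"), cfg$map)
print(tr[c(1, 6, 11, 21), ], digits = 3)
#> # A tibble: 4 × 6
#>   generation   S_Q   S_H     S_K  S_PH  S_PK
#>        <int> <dbl> <dbl>   <dbl> <dbl> <dbl>
#> 1          0 0.740 0.316 0.00761 0.159 0.456
#> 2          5 0.891 0.297 0.0343  0.225 0.231
#> 3         10 0.950 0.279 0.0543  0.242 0.149
#> 4         20 0.991 0.270 0.0853  0.263 0.103
```

The captive founders start with 26% introgressed ancestry (`1 − S_Q`).
Twenty generations of ranked selection on population kinship drive it below
1% while heterozygosity `S_H` declines only mildly (0.32 → 0.27, roughly
the drift expectation at this population size) and target-ancestry
heterozygosity `S_PH` *rises* from 0.16 to 0.26 as the masked fraction of
the genome shrinks. `autoplot(tr)` draws the trajectories;
`run_strategy_comparison()` and `run_sweep()` reproduce multi-strategy and
sensitivity analyses, and `make_wildcat_like_fixture()` builds a synthetic
36-diploid panel emulating a heavily admixed felid chromosome
(1.26 Morgans, per-haplotype target ancestry of mean ≈ 0.6).

A thin command-line front end lives at `inst/cli/labreed.R`
(`simulate`, `breed`, `compare`, `sweep`, `demography`, `fixture`,
`score`), reading YAML/JSON configs via `read_run_config()`.

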