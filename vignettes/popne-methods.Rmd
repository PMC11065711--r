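---
title: "Models and methods: LD decay and effective population size from SNP panels and pedigrees"
author: "popne"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: LD decay and effective population size from SNP panels and pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popne estimates the population dynamics of managed livestock populations —
the motivating case is composite (crossbred) dairy cattle such as Karan
Fries, bred from indicine cows and taurine bulls and then closed — from two
independent sources of information: linkage disequilibrium (LD) in a SNP
array panel, and a herd book. This vignette is the package's own account of
the models, the tunable parameters, the simulators used to validate the
estimators, and the numerical choices made where the design was open.

```{r setup}
library(popne)
```

## Genotype substrate and quality control

Genotypes enter as PLINK text PED/MAP and are held as a samples x variants
dosage matrix (0/1/2 copies of a recorded counted allele, `NA` missing). The
counted allele is the first non-missing allele seen in file order, with a
lexicographic tie-break when the first genotype is heterozygous. This makes
re-reading a file bit-reproducible; it has no effect on r², which is
invariant to allele coding — only the sign of D depends on it. A genotype
with one missing allele is treated as wholly missing, and positions follow
the 1-based MAP convention with distances taken as simple position
differences.

Marker QC applies, in order: autosome restriction (cattle chromosomes 1–29,
known position), call rate ≥ 0.90, minor allele frequency ≥ 0.05, and an
exact Hardy–Weinberg test at a removal floor of p < 1e-5. The HWE test is
the standard two-sided conditional exact test (probabilities of heterozygote
counts no more probable than observed, conditioning on allele counts; no
mid-p), computed by the stable recurrence from the modal heterozygote count.
Thresholds are inclusive (a marker exactly at 0.90 call rate passes), each
failing marker is attributed to the first rule it fails, and no
animal-level QC is applied — the criteria are marker-level only. Whether
HWE should be tested within subpopulations is left to the caller: the test
is applied to whatever dataset is supplied.

## Pairwise LD and its decay

For two biallelic loci, `D = pAB − pA pB`, `D′ = |D|/Dmax`, and
`r² = D²/(pA(1−pA)pB(1−pB))`. The workhorse statistic is the genotype-dosage
r²: the squared Pearson correlation of 0/1/2 dosages over pairwise-complete
samples, the PLINK default for unphased data. Haplotype-frequency-based D
and D′ are available on request via an EM that resolves the
double-heterozygote phase ambiguity (tolerance 1e-10, 1000-iteration cap,
linkage-equilibrium start); with no double heterozygotes the EM reduces to
a direct gamete tally. Pairs where a locus is monomorphic among the
complete cases are skipped with a reason, never zero-filled, and scan
output is ordered by (chromosome, left index, right index) so results are
byte-reproducible.

The scan is restricted to same-chromosome pairs within 500 kb by default:
beyond that, r² in cattle panels is typically far below useful levels, and
the pair count grows quadratically. Decay is summarised over the
conventional distance bins 0–10, 10–25, 25–50, 50–100, 100–200 and
200–500 kb. Bins are half-open `(lo, hi]` — the conventional bin labels
overlap at their edges and do not fix a convention, so a pair at exactly
10 kb falls in the first bin.

The *useful-LD crossing* is the distance where bin-mean r² first falls
below a threshold, conventionally 0.2 (the level associated with ~0.85
accuracy of genomic breeding values). Two statements are produced: a
linear interpolation between consecutive bin summary points
`(mean_dist, mean_r2)` — smooth and reproducible — and a coarse value at
10 kb granularity, the style in which such results are usually quoted.
The panel size for equidistant marker placement is
`floor(genome_len_kb / spacing_kb)`; with the 2,510,605 kb cattle autosomal
genome and 40 kb spacing this gives 62,765 markers.

## Historical Ne from distance-binned LD

Under drift-recombination equilibrium, LD at recombination rate c reflects
the effective size roughly `t = 1/(2c)` generations ago. The estimator
inverts the equilibrium expectation bin by bin:

1. physical distance to map distance, `d = k δ` with `k = 1e-8` Morgan/bp
   (1 cM/Mb);
2. map distance to recombination fraction by the Sved–Feldman modifier
   `c = d(1 − d/2)` rather than the crude `c = d`;
3. sampling-bias adjustment `r²_adj = r² − 1/(βn)` with β = 1 for unphased
   genotypes (2 if phase were known) and n the number of genotyped
   individuals — a single panel-level n, matching the single n of the
   adjustment formula, not per-pair complete counts;
4. `Ne(t) = (1/(4 f(c))) (1/r²_adj − α)` with `f` the identity and α = 1
   (no mutation correction).

Pairs are partitioned into equal-width physical-distance bins between a
configurable minimum and maximum distance (defaults 10 kb – 4 Mb, 30 bins);
each bin contributes one `(t, Ne)` point with t from the arithmetic mean
pair distance of the bin. Equal-width binning and the arithmetic mean are
the simplest reproducible choices; bin counts and the window are exposed
because widening the maximum distance reaches larger c and hence more
recent generations. Bins whose adjusted r² is ≤ 0 (over-corrected) or
≥ 1/α (Ne would be non-positive) are dropped and reported with reasons —
clamping would fabricate estimates. Generations are reported as floats; no
interpolation onto integer generations is silently applied.

Choosing `f(c) = c` reproduces the plain Corbin inversion; the slot exists
so alternative recombination mappings can be configured without touching
the estimator. The closed-form round trip — feeding
`E[r²] = 1/(α + 4Nc) + 1/(βn)` through the adjustment and inversion —
returns N to machine precision, which the test suite asserts over a grid
of N and c.

### Accuracy limits inherited from the Sved expectation

`1/(1 + 4Nc)` is a first-order approximation. In forward simulations at
`4Nc ≈ 2` the equilibrium mean r² sits roughly 20% above it (and
MAF-filtering the panel raises the mean further, since rare-allele pairs
have low bounded r̂²); at `4Nc ≳ 8` the approximation is good on average.
The LD-based Ne estimator consequently understates Ne somewhat at distant
generations (small c) and is noisiest at recent generations (large c,
where per-replicate drift variance of LD is large). This is why the
recovery validation below targets the median over a generation range and a
±40% band rather than pointwise agreement.

## Pedigree-based Ne

The additive kinship (coancestry) matrix is built by the tabular method:
`C(x, y) = ½(C(sire_x, y) + C(dam_x, y))` for y processed earlier,
`C(x, x) = ½(1 + C(sire_x, dam_x))`, unknown parents contributing zero, so
the diagonal carries `(1 + F)/2`. Pedigree depth is measured by equivalent
complete generations, `t_i = Σ (1/2)^g` over known ancestors.

Rates of drift accumulation are referenced to pedigree depth:

- pairwise increase in coancestry `ΔC_ij = 1 − (1 − C_ij)^(2/(t_i + t_j))`
  and `NeCi = 1/(2 mean ΔC)` over unordered pairs of distinct reference
  individuals (founder pairs with `t_i + t_j = 0` are excluded and
  counted);
- individual increase in inbreeding `ΔF_i = 1 − (1 − F_i)^(1/(t_i − 1))`
  for individuals with `t_i > 1` (the exponent is undefined otherwise;
  ineligible individuals are excluded and counted) and
  `NeFi = 1/(2 mean ΔF)`;
- the equivalent-subpopulation ratio `S = NeCi/NeFi`, near 1 under
  panmixia and below 1 when mating management slows inbreeding relative to
  coancestry accumulation.

The default reference set is every non-founder; a birth-year cohort can be
selected instead. The choice matters for NeCi: pairs spanning distant
cohorts share ancestry only up to the older cohort's depth while being
normalised by the mean of both depths, which dilutes ΔC. Recovery tests of
NeCi therefore use the most recent cohort as reference — the natural
"current population" — while NeFi, an average of per-individual rates, is
insensitive to this choice. Zero accumulated coancestry or inbreeding is
reported as an undefined Ne with a reason, not as infinity.

## Simulators and what passing recovery tests shows

Two simulators generate data of known truth.

The genotype simulator is a forward-in-time diploid Wright–Fisher model:
discrete generations, two parents drawn uniformly with replacement
(selfing allowed, as the classical model assumes), gametes formed with
crossovers as a Poisson process at 1e-8 per bp, loci initialised
independently (linkage equilibrium) at uniform [0.05, 0.5] frequencies,
and no mutation afterwards — which makes α = 1 exactly right and keeps
recovery tests clean. The genotyped sample is a cohort of `n_sampled`
offspring bred from the final generation, mirroring how a herd of ~50
breeding animals can yield 96 genotyped individuals; the sampling
adjustment then uses the cohort size. Monomorphic loci are retained for QC
to remove. Multiple chromosomes are independent replicates with distinct
labels. Everything is reproducible from the recorded seed, and the
simulator also records the final population allele frequencies so drift
itself can be checked against the variance law
`p(1−p)(1 − (1 − 1/(2N))^t)`.

The pedigree simulator implements hierarchical random mating: `n_sires`
breeding males and `n_dams` breeding females per discrete generation,
parents drawn uniformly from the previous generation's breeders, sexes
assigned to maintain the breeder counts, and the theoretical
`Ne = 4 Ns Nd/(Ns + Nd)` recorded. It forbids selfing by construction (two
sexes), deliberately different from the genotype simulator — the two feed
different estimators.

Validation problem sizes were chosen as a realistic desk-scale portrait of
the motivating system: constant N = 50 (the FAO minimum-concern level and
the right order for an organised crossbred herd), 96 genotyped offspring,
two chromosomes of 30 Mb with 1,500 initial SNPs each, and a burn-in of
200 = 4N generations, the standard scale for approaching
drift-recombination equilibrium. After QC-driven attrition this leaves
thousands of informative pairs in the 0.5–5.2 Mb window, which maps to
generations 10–100. Across 20 seeded replicates the median LD-based Ne
over that range recovers 50 well within the ±40% band that the
approximation error and drift variance warrant. The pedigree estimator is
validated at 25 sires × 25 dams × 100 offspring × 10 generations
(theoretical Ne = 50) over 10 replicates; the NeFi median recovers 50
within ±25%.

What passing does *not* show: the simulators emulate neutral drift with
uniform recombination and random mating. Real cattle data add selection,
migration/admixture (the very history composite breeds are made of),
pedigree errors, array ascertainment bias, and non-uniform recombination;
none of these are modelled, so recovery here demonstrates correctness of
the estimators under their own assumptions, not robustness to violations
of them.

## Numerical and degenerate-input conventions

- Dosage r² requires ≥ 2 pairwise-complete samples and both loci
  polymorphic among them; otherwise the pair is skipped with a machine-
  readable reason.
- HWE tie comparison uses `p ≤ p_obs (1 + 1e-10)` to guard floating-point
  ties in the "no more probable than observed" rule.
- EM haplotype frequencies: tolerance 1e-10 on the largest frequency
  change, 1000 iterations, non-convergence warns and flags the result.
- An empty QC result is a warning, not an error; an empty LD window or a
  fully-dropped trajectory likewise warn and return empty tables with
  diagnostics.
- All pipeline outputs are tab-separated text with headers; the run
  manifest (JSON) echoes every threshold and constant, records input MD5
  digests and seeds, and manifest-identical runs produce byte-identical
  outputs (no timestamps).

## Worked example

```{r example, eval = FALSE}
truth <- simulation_truth(
  ne_schedule = data.frame(n_generations = 200, size = 50),
  n_sampled = 96, n_loci = 1500, chrom_length_bp = 3e7,
  n_chromosomes = 2, seed = 4201)
res <- run_genomic(truth = truth, out_dir = "popne_out",
                   ne_config = ne_ld_config(n_bins = 18, min_dist_bp = 5e5,
                                            max_dist_bp = 5.2e6))
subset(res$trajectory, t_gen >= 10 & t_gen <= 100)

ped <- simulate_pedigree(25, 25, 100, 10, seed = 601)
pedigree_ne(ped)
```

## Known limitations

- The LD estimator assumes a roughly linear/steady demography per bin; it
  cannot resolve abrupt recent size changes (methods built for that, such
  as genetic-algorithm trajectory fitting, are out of scope here).
- No confidence intervals on the LD trajectory yet (jackknife over
  chromosomes is the natural extension).
- Genomic (ROH-based) inbreeding, relatedness pruning and sample-level QC
  are out of scope by design.
- The PED/MAP reader targets the text dialect only; binary BED and VCF
  are not parsed.
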