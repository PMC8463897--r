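---
title: "Detecting the Meselson effect: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the Meselson effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meselson)
```

## The scientific problem

In a diploid organism that reproduces clonally for a long time, the two
haplotypes of each chromosome stop being shuffled by meiosis and accumulate
mutations independently. Over time this produces a characteristic set of
population-genomic patterns — the *Meselson effect* — that distinguish
long-term clonal evolution from sexual reproduction:

1. **Signature I** — divergence *within* individuals exceeds divergence
   *between* populations.
2. **Signature II** — heterozygous variants are *shared* across individuals
   and populations far in excess of Hardy–Weinberg expectations, and
   per-individual inbreeding coefficients are strongly negative.
3. **Signature III** — per-region haplotype trees separate haplotypes A and
   B at their deepest split, rather than separating populations.
4. **Signature IV** — the two haplotype subtrees have *matching* topologies
   (parallel divergence through the same lineage and population history).

This package implements each signature as an explicit statistical test on
multi-individual diploid polymorphism data (an all-sites VCF, per-individual
read-backed phase blocks, coverage tracks, and sample metadata), plus a
simulator that generates clonal and sexual datasets with known truth so the
whole pipeline is verifiable without access to any particular dataset.

## Models and procedures

### Signature I: ordination and AMOVA

Individuals are compared by the dosage L1 ("raw Hamming") distance
`d(i,j) = Σ_s |g_i − g_j|`, `g ∈ {0,1,2}`, which equals the identity-by-state
allele mismatch count for biallelic sites. Classical (Torgerson)
multidimensional scaling provides the two-dimensional ordination.

The hierarchical AMOVA decomposes allele-level variance at three levels
(among populations / among individuals within populations / within
individuals). Each diploid contributes two allele rows; all sums run over
every pairing of allele copies between two individuals, which makes the
decomposition *phase-invariant* (asserted by tests). Squared inter-haplotype
distances are Hamming distances, the standard choice for sequence AMOVA.
Method-of-moments components use the usual unequal-size coefficients;
negative components are truncated to zero before percentages are formed, and
flagged. Significance of the among-population component comes from permuting
whole individuals across populations with the add-one p-value estimator
`(1 + #{σ²_perm ≥ σ²_obs})/(n_perm + 1)`.

The verdict for signature I is the variance comparison itself (within-
individual % > among-population %); the permutation p-value is reported
alongside rather than gating the verdict, because a small but genuine
population component can be statistically detectable even when it explains
far less variance than within-individual divergence.

### Signature II: heterozygosity, F, and the conditional SFS

Per-individual heterozygosity is the fraction of heterozygous genotypes over
all retained sites (monomorphic sites included, so denominators are
comparable across individuals). The per-individual inbreeding coefficient
within a group of `n` diploids is

F = (O_hom − E_hom) / (N − E_hom),  E_hom = Σ_s [1 − 2p(1−p)·2n/(2n−1)]

with `p` the nonreference allele frequency *including* the focal individual
— the same method-of-moments estimator as the classical VCF toolkit option.
Sites monomorphic within the group are excluded (they carry no information),
which is why different groups report different site counts. The species
comparison uses an exact rank-sum test: the Mann–Whitney `W` with mid-rank
ties and a two-sided p-value by complete enumeration of all
`choose(nA+nB, nA)` label assignments (restricted to ≤ 25 values).

For shared heterozygosity, the null is Hardy–Weinberg *conditional on the
observed allele count*: given `j` nonreference alleles among `2m` slots, an
ordered genotype profile has probability `Π w(g_i)/C(2m, j)` with `w(het)=2`,
`w(hom)=1`. Conditioning on `j` (not on an estimated frequency) keeps the
null exact at any sample size; the closed form is validated against complete
allele-placement enumeration for small `m`. The fold excess of a profile
(e.g. "heterozygous in all seven individuals") is its observed share among
sites with that `j` divided by this probability. Sites containing a
homozygous-alternate genotype are excluded from the three shared-het branch
categories (they are neither "shared het" nor "private het") but remain in
the SFS.

### Phaseable regions

Regions are maximal unions of per-individual phase blocks chained by
pairwise cross-individual overlaps of at least 100 bp, kept when they span
≥ 100 bp and involve ≥ 2 individuals. The region interval is the *union* of
chained blocks; each individual is masked (`N`) outside its own blocks and
wherever its coverage falls below the masking threshold (default 10, the
same cutoff as genotype filtration). Haplotypes are labeled per individual:
A is the sequence closer to the reference over unambiguous columns, ties
break lexicographically and are flagged. Collapsed paralogs are screened by
the ratio of the region's median genomic read coverage to a single-copy
baseline; the flag threshold of 1.5 sits midway between the single-copy
(1×) and duplicate (≈2×) coverage classes.

### Signature III: constrained topologies, Δ, and AU tests

Per region, three trees are fitted under JC69 by maximum likelihood:
an unconstrained best tree (neighbor joining on JC69 distances followed by
nearest-neighbor-interchange hill climbing), and two constrained trees — the
*asex tree* (haplotypes A and B separated at the base, then lineages, then
populations) and the *sex tree* (no haplotype separation; lineages, then
populations). JC69 is fixed deliberately: at the ~1% divergences involved,
model choice is immaterial, and a single fixed model keeps the likelihood
engine cross-checkable against closed forms (the two-taxon ML length equals
the JC69 distance to 1e-6). Constraint polytomies are resolved
deterministically and branch lengths re-optimised; unsupported resolving
branches simply fit to near-zero length, so the branch-score Δ is
insensitive to which resolution was chosen — this replaces a
constraint-restricted topology search, which would add cost without
changing Δ.

Δ = d(best, asex) − d(best, sex) in Kuhner–Felsenstein branch-score
distance (the square root of summed squared branch-length differences over
the union of bipartitions). Negative Δ means the region's best tree
resembles the asexual constraint more.

Fit differences are tested by RELL resampling of per-site log-likelihoods
(no refitting) at bootstrap scales 0.5–1.4, with the approximately unbiased
(AU) correction: `qnorm(1 − BP_r)` is regressed on `d·sqrt(r) + c/sqrt(r)`
by weighted least squares and `p = 1 − Φ(d − c)`. Site log-likelihood
vectors differing by less than 1e-6 anywhere are *indistinguishable*: the
asex/sex comparison is then untestable (the analogue of regions skipped for
insufficient variation), and a constrained tree indistinguishable from the
unconstrained fit cannot be rejected against it (p = 1). When all bootstrap
proportions are 0 or 1 the p-value collapses to the degenerate value and is
flagged. Each region is assigned one of five categories
(unconst=asex>sex, asex>sex, no-difference, sex>asex, unconst=sex>asex),
evaluated in that order at α = 0.05 (the conventional level; the underlying
p-values are all reported).

### Signature IV: parallel divergence

Best ML trees are rebuilt per lineage with the coverage mask relaxed to 5
(trading call confidence for informative sites, hence more nonpolytomous
trees). A tree is *resolved* when collapsing internal branches shorter than
1e-6 substitutions/site leaves it fully binary — the formal surrogate for a
visual polytomy screen. A resolved tree *separates haplotypes* when some
edge bipartitions all `_A` from all `_B` leaves, and shows *parallel
divergence* when the two sides, rooted at that edge and stripped of their
suffixes, are isomorphic as rooted leaf-labeled topologies (branch lengths
ignored; exact isomorphism is the fixed rule). Under the null that each
side is an independent uniform rooted topology, a pair matches with
probability `x = 1/(2k−3)!!`; the significance of `k` matches among `n`
separating trees is the exact binomial upper tail `P(X ≥ k | n, x)`.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates all pipeline inputs with known truth. The
`oppiella_like_config()` preset mirrors the structure of a well-studied
oribatid-mite system: nine individuals in three populations (H, KF, SA);
in clonal mode two divergent lineages (I: H1, H2, SA1, SA3; II: H3, KF1,
KF2) plus two near-homozygous singletons (KF3, SA2) with a high
loss-of-heterozygosity rate.

Parameters (all times in expected substitutions/site — no calendar dating
is attempted because per-generation mutation rates are not known for these
organisms):

* `T_hap = 0.0065` — haplotype split; pairwise A–B divergence `≈ 2·T_hap`
  targets ~1.3% heterozygous sites, the top of the observed 0.4–1.3% range.
  A deep split is what makes the branch-score signal (the separating edge)
  dominate branch-length estimation noise in Δ.
* `T_lin = 0.003`, `T_pop = 0.0022`, `T_tip = 0.0006` — lineage,
  within-lineage subclade, and terminal splits. The subclade minus terminal
  gap (≈ 0.0016) controls how often within-lineage trees are resolved; the
  value was chosen so the resolved-tree fraction matches the ~15–30% seen
  in real transcriptome data of this kind.
* `loh_rate = 0.05` (`0.7` for the singleton individuals) — per-site
  probability of being covered by a homogenizing (gene-conversion-like)
  tract; tracts have geometric lengths (mean 300 bp) and overwrite one
  haplotype with the other. This is a phenomenological surrogate for the
  inverted-meiosis/terminal-fusion machinery discussed for these organisms,
  which is not modeled mechanistically.
* `region_length_bp = 600`, `phase_block_mean_bp = 550`,
  `phase_dropout = 0.1` — region and phase-block scale, matching the
  published 358–563 bp median phased-region lengths.
* `coverage_mean = 60` with a 2% low-coverage component (mean 5) exercises
  the depth filter; `genome_coverage_mean = 126` and
  `paralog_fraction = 0.05` exercise the paralog screen (paralogous regions
  are emitted at doubled coverage).
* `n_regions = 150` — a scale-down of the ~281 phased regions in the
  emulated study, chosen so the parallel-divergence stage still accumulates
  enough separating trees while the full pipeline runs in minutes.

In sexual mode, populations split at `T_pop = 0.004` (the most divergent,
SA, at `T_lin = 0.007`) and the two allele copies of each individual
coalesce within populations by a Kingman process with mean pairwise
coalescent time `coal_scale = 0.00325` (≈0.65% heterozygosity); alleles are
paired into individuals at random, so genotypes are in Hardy–Weinberg
proportions within populations.

The reference sequence is the (post-homogenization) A haplotype of one
designated individual, emulating a reference genome assembled from a single
individual. This matters: with a single-haplotype reference every
individual's reference-proximal haplotype belongs to the same clade, so
per-region A/B labels are mutually consistent. An outgroup-free "ancestral"
reference would make labels incoherent across individuals and destroy
signature III/IV power — a useful reminder that these analyses depend on
the reference being a real haplotype.

Simplifications relative to real data: no recombination or selection, no
indels, sites evolve independently under JC69, the clonal genealogy is
shared by all regions (exactly what clonality implies), the within-
population coalescent is compressed to finish before the population split,
phase blocks are emitted one per individual per region with random
orientation, and sequencing error is represented only through the
low-coverage depth component. Passing tests therefore demonstrate that the
statistics behave correctly under the idealized generative model, not that
any particular real dataset satisfies the model.

## Numerical choices and degenerate inputs

* Filter order is fixed (depth mask → indels → multiallelic → incomplete →
  monomorphic) so per-filter removal counts are well defined; "monomorphic"
  means all non-missing calls homozygous *reference* (an all-hom-alt site is
  a nonreference variant and is kept).
* Internal coordinates are 0-based half-open; VCF I/O is 1-based; BED and
  bedGraph are 0-based half-open.
* JC69 distances saturate at mismatch fraction 0.75 (infinite-distance
  sentinel); neighbor joining refuses saturated inputs, and the
  unconstrained search falls back to a fixed ladder start when a pair
  shares no usable column.
* Negative NJ branch lengths are clamped to zero with the deficit moved to
  the adjacent branch.
* Branch-length optimisation runs to the library's default convergence
  (log-likelihood improvements below ~1e-8); per-site log-likelihoods are
  expanded from site patterns.
* The exact rank-sum doubles the smaller tail and caps at 1, matching the
  convention of the classical test; mid-ranks handle ties.
* The permutation p uses the add-one estimator and never returns 0.
* Paralog ratio at exactly the threshold flags (≥).
* Blocks whose two haplotypes differ in length are rejected (indels inside
  phases are out of scope).

## Problem sizes used by the test suite

Unit tests run on toy matrices and short simulated alignments. The
parameter-recovery tests run the full pipeline on one clonal and one sexual
preset dataset (150 regions × 600 bp, nine individuals); the AU-test size
check uses 200 six-taxon regions of 400 bp. These sizes were chosen so the
complete suite exercises every stage end-to-end while remaining a
minutes-scale run on a single CPU.

## Known limitations

* The AU implementation follows the multiscale-bootstrap quantile
  regression; it is validated by a size/calibration simulation, not against
  an external implementation (none is available in this package's
  dependency set).
* The AMOVA permutation test permutes individuals freely across
  populations; unbalanced designs with very few individuals have a coarse
  permutation distribution (hence the `n_perm ≥ 99` requirement).
* Subtree matching is exact isomorphism; partial congruence of larger
  subtrees is not scored.
* The homogenization model removes heterozygosity uniformly along the
  genome; real loss of heterozygosity is likely clustered around
  recombination/conversion hotspots, which would make region-to-region
  heterogeneity stronger than simulated.
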