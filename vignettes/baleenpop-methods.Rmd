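---
title: "Methods and design choices in baleenpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in baleenpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baleenpop)
```

`baleenpop` targets a specific inferential regime: whole-genome data from
two or three individuals of a species for which no larger sample exists.
This vignette explains the statistical machinery behind each module, the
parameters that matter, the choices we made where the design was genuinely
open, and what the simulation-based validation does and does not
demonstrate.

## The data model

Everything runs off a `genotype_table`: a shared grid of biallelic SNP
sites (one record per scaffold/position) with a diploid genotype code and a
read depth per individual. The grid is shared because joint calling
produces one site list for all samples, and several statistics
(identity-by-state sharing, ABBA-BABA) need genotypes for all individuals
at the same site. For that reason the depth filter (default 20 reads, a
level at which heterozygotes are unlikely to be miscalled as homozygotes)
marks a shallow call as *missing for that individual* instead of deleting
the site. Scaffold-level exclusion (for example sex-linked scaffolds, which
would bias autosomal diversity) removes sites outright.

Heterozygosity denominators come from a `callable_mask`, not from the
variant records: a VCF of variant sites says nothing about how many
monomorphic positions were callable, so the mask — per individual, merged
0-based half-open intervals with a total bp count — is an explicit input.
VCF positions are 1-based, masks are BED-style half-open, and all internal
interval arithmetic is half-open, so both standards are matched exactly at
their boundaries. No phasing is assumed anywhere; all statistics are
genotype-based.

Only SNPs are ingested (multi-allelic records are dropped by default, and
indels are outside the data model): every downstream statistic is defined
on biallelic single-nucleotide genotypes.

## Heterozygosity and equilibrium Ne

For one individual, `theta_genome` is the count of heterozygous,
non-missing calls inside the mask divided by the mask's callable bp.
`theta_no_roh` applies the same definition after removing ROH territory
from numerator and denominator. Definitions of the "outside ROH" rate vary
between counting SNPs and counting sites; we use callable bp outside ROHs
as the denominator and heterozygous calls outside ROHs as the numerator so
that the two θ values are directly comparable — same units, same mask.

`ne_from_theta` inverts the neutral-equilibrium relation θ = 4·Ne·μ with
μ per generation assembled from a yearly substitution rate and a generation
time. Defaults are baleen-whale values: 4.8e-10 bp⁻¹ yr⁻¹ (credibility
interval 1.5e-10 to 10e-10 — baleen whale substitution rates are reported
to be several-fold slower than in most mammals) and 18.9 years (midpoint of
the 15.5–22.3 range). The reported interval on Ne propagates the
substitution-rate CI only; the generation-time range is not propagated,
since the rate dominates the uncertainty and varying one axis keeps the
interval interpretable.

## Runs of homozygosity

A ROH is a tract whose two haplotypes coalesce recently — autozygosity —
visible as a long stretch of homozygous calls. The scanner slides a window
of `window_snps` consecutive sites (default 20) along each scaffold; a
window is *eligible* if it holds at most 1 heterozygous and 1 missing call.
Maximal unions of overlapping eligible windows form candidate runs.

The subtle part is turning candidates into reported runs. We require a
reported run to satisfy, as a whole: at most 1 heterozygous call, at most 1
missing call, at least `window_snps` homozygous sites, and a bp extent of
at least 1 kb. A candidate as a whole usually cannot satisfy the
heterozygosity cap, for a structural reason: the window anchored at the
nearest flanking heterozygous SNP (that SNP plus the first 19 homozygous
sites of the tract) is itself eligible, so the union almost always absorbs
one flanking het on *each* side, for a total of two. Rejecting such
candidates outright would reject essentially every true tract embedded in
normally variable sequence. We therefore emit, within each candidate, the
maximal-site-count subinterval satisfying all run-level constraints
(leftmost on ties), and process the remainders on either side the same way.
This rule is deterministic, reduces to "emit the candidate unchanged"
whenever the candidate already passes the caps, never merges runs across a
disqualifying site, and is simple enough to verify against a brute-force
oracle that enumerates every subinterval directly — which the test suite
does on dozens of random genotype strings.

Run coordinates span the first to last member SNP, so they are reproducible
from the site grid alone (no midpoint interpolation between flanking SNPs).
Summaries report N_ROH, mean length with the n−1 standard deviation, total
length, and F_ROH = total length / genome size (default 2.4 Gb, a typical
baleen whale assembly size). Between-individual comparisons use the Welch
unequal-variance t-test on raw lengths and the asymptotic two-sample
Kolmogorov–Smirnov test on the length distributions, both two-sided.

## Identity-by-state relatedness and the PPC test

At a site with allele frequencies p and q, two members of one randomly
mating population are both heterozygous with probability (2pq)² = 4p²q²
and are discordant homozygotes (AA/BB or BB/AA) with probability 2p²q².
The expected HetHet : HomHom ratio is therefore 2 for any allele-frequency
spectrum, which makes it a convenient relatedness diagnostic: related pairs
share alleles and push the ratio above 2; pairs drawing recent ancestry
from different pools fall below 2.

The pairwise population concordance (PPC) test conditions on a site being
informative (HetHet or discordant HomHom): under the null the site is
HetHet with probability 2/3, so the test is an exact binomial test of
k = n_HetHet out of n = n_HetHet + n_HomHom against 2/3. We use the
one-sided alternative "less" — a *deficit* of HetHet sharing is what
indicates separate mating pools — so related pairs produce p-values near 1
and only genuinely discordant pairs produce small p. (The symmetric
per-site probability of a discordant homozygote pair is 2p²q², counting
both AA/BB and BB/AA configurations; a single-configuration reading p²q²
would imply a null ratio of 4 and is inconsistent with the 2:1 expectation
above, so we use 2/3 throughout.)

Site selection: pooled minor allele frequency at least 0.01 (with two or
three genomes this mainly removes fixed sites), both genotypes called, and
greedy left-to-right thinning of informative sites so consecutive retained
sites are ≥ 500 kb apart within a scaffold, limiting linkage
disequilibrium. Greedy thinning is deterministic: the same table and
configuration always select the same sites.

## The ABBA-BABA D statistic

For four genomes — ingroup P1, P2, a potential introgressor P3, and an
outgroup O — sites where the derived allele is shared by P2 and P3 (ABBA)
or by P1 and P3 (BABA) are discordant with the species tree. Incomplete
lineage sorting produces both patterns at equal rates, so
D = (nABBA − nBABA)/(nABBA + nBABA) has expectation 0 without gene flow;
an excess in either direction indicates admixture.

With single diploid genomes there are no population allele frequencies, so
one allele is sampled uniformly per individual per site (sites with any
missing genotype, or a heterozygous outgroup, are excluded; the outgroup
allele defines the ancestral state, and "derived" means any non-outgroup
allele). The sampling is seeded, and the uniform draws are keyed to the
*individual* (ordered by table column) rather than to the topology slot,
which makes D exactly antisymmetric under exchanging P1 and P2 at the same
seed and makes rotation tests internally consistent.

Standard errors come from a delete-one block jackknife over contiguous
blocks (default 10 Mb, aligned to scaffold starts, terminal partial blocks
retained with their own weight; scaffolds shorter than 10 Mb are excluded as
too short to contribute a stable block). Blocks are weighted by their
informative-site counts using the standard weighted-jackknife variance; an
unweighted delete-one variant is available for sensitivity checks. The test
suite verifies on null simulations that the jackknife SE tracks the
replicate spread of D and that |Z| > 3 occurs in about the nominal fraction
of null replicates. `run_topology_tests` evaluates the three rotations of
the ingroup trio against a fixed outgroup and flags |Z| > 3.

## Inputs and rescaling for coalescent demographic inference

The sequentially-Markovian coalescent HMM itself is deliberately outside
this package: any compatible engine can be used. `baleenpop` owns the
surrounding contract. `export_hetsep` writes the standard multihetsep
records (heterozygous position plus the number of callable sites since the
previous record, counted from the mask) for scaffolds ≥ 30 Mb — long
scaffolds are needed to observe past recombination. `bootstrap_datasets`
builds replicate datasets by sampling floor(L / 5 Mb) chunks of 5 Mb with
replacement from each scaffold, so each replicate matches the original
retained length; the chunk count per scaffold is our reading of "sample
5 Mb sequences from each scaffold", chosen so replicate size is preserved.
Records keep their own callable-since-last counts across chunk boundaries
(capped at the re-indexed positional gap), the same approximation the
standard multihetsep bootstrap tooling makes.

`scale_segments` converts scaled output (times in expected mutations per
site, coalescence rates λ) with years = scaled time / yearly rate and
diploid Ne = 1/(2·λ·μ_gen). The Ne convention is isolated in one function
so factor-of-two variants are a one-line change, and tracks at the rate CI
bounds are emitted alongside the point track.

## Habitat envelopes

Habitat suitability uses the classical environmental-envelope construction:
per variable, a trapezoid that is 0 outside the absolute tolerance range, 1
inside the preferred range, and linear on the shoulders; at a degenerate
shoulder the closed preferred interval wins, so the shared bound scores 1.
Per-variable scores are combined per cell by product (default) or geometric
mean — the geometric mean dominates the product cell-wise and both are
annihilated by a zero, and since the external tools in this space do not
document their exact combination rule, both are provided and the choice is
an explicit argument. Envelope values are user configuration, not package
constants. Grids are plain lattices in headered ASCII-grid text with an
explicit NODATA sentinel; no map-projection handling is attempted.

## What the simulators emulate — and what they do not

`simulate_diploid_table` places polymorphic sites as a Bernoulli process
(default 1.5e-3 per bp), draws heterozygous calls at a rate calibrated so
genome-wide heterozygosity matches a target θ (default 6.7e-4, a gray-whale
magnitude), plants autozygous tracts with exponential lengths (default mean
200 kb, the "long recent ROH" regime; the mean is configurable down to the
short ancient regime) in which heterozygosity is zero, and applies
het-to-hom genotyping error and missingness (default 0.002). The implied
per-site heterozygosity at polymorphic sites (≈ 0.45) mirrors the fact that
variable sites in a tiny sample are mostly sites where someone is
heterozygous. `simulate_hwe_pair` draws per-site allele frequencies from
Uniform(0.05, 0.5) and genotypes under Hardy–Weinberg, with a full-sibling
mode that transmits parental alleles through one shared parental pair.
`simulate_pattern_blocks` is multinomial at the pattern level: the
statistics under test consume pattern counts, so this exercises the D
statistic and jackknife completely and controllably; a genealogy-based
four-taxon simulator would add realism but no additional coverage of the
estimator.

These generators validate the *estimators*, not the biology: real genomes
have linked sites, variable recombination and mutation rates, mapping
artefacts, and depth-dependent genotyping error, none of which the
generators model. Passing the recovery tests shows the implementations
compute what they claim on data satisfying their assumptions — it does not
certify behaviour on real alignments.

## Numerical and testing choices

Validation problem sizes were chosen to exercise each statistic at
meaningful precision while keeping the full suite fast: 10 Mb genomes for
F_ROH recovery at planted fractions 0.05/0.10/0.20 (tolerance ±0.02), 50,000
unlinked sites for the sharing-ratio null (three binomial standard errors),
200 replicates of 100 blocks × 10,000 sites for the D-statistic null and
power checks, and brute-force oracle comparisons on strings of up to 200
sites where exhaustive enumeration is feasible. Degenerate inputs error
early with named messages (empty masks, zero informative sites, jackknife
with fewer than two informative blocks, chunk lengths exceeding a scaffold).
All simulation entry points take an explicit integer seed and restore the
caller's RNG state.

## Known limitations

* ROH-length-class dating of inbreeding events is not implemented; only the
  length distributions and their comparisons are.
* The MAF filter with two or three genomes has very coarse frequency
  resolution; it is documented as mainly a fixed-site filter.
* D statistics here are the single-genome, sampled-allele form; no
  f-statistics or admixture-fraction estimation.
* Bootstrap hetsep tracks approximate callable counts at chunk boundaries.
* The habitat module scores environmental layers only; it does not fetch
  occurrence records or future-scenario layers.
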