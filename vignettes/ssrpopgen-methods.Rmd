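---
title: "Models and methods behind ssrpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpopgen)
```

`ssrpopgen` implements the marker-development-to-fingerprinting analysis
chain used in EST-SSR surveys of non-model plants. This vignette explains
the statistical models, the conventions chosen where several are in common
use, the synthetic-data generator, and the numerical decisions — the
things a user needs in order to trust (or challenge) the numbers.

## The data model

Everything operates on a long-format diploid genotype table: one row per
individual × locus, with the call stored as a sorted pair of positive
integer allele identifiers (fragment sizes in base pairs) or as the `NA`
sentinel for a missing genotype. Missingness is never represented by 0
inside the package; 0 appears only in the serialized GenAlEx dialect,
whose layout (header row of counts and population block sizes, title row
with population names, two allele columns per locus) is pinned to the
GenAlEx 6.5 codominant export. Allele sizes are taken as-is: fragment
binning belongs to the upstream peak-calling software and is deliberately
out of scope.

## SSR mining

Perfect repeats of unit length 1–6 are detected as maximal non-extendable
tandem runs meeting per-unit-length minimum repeat counts. The defaults
(mono ≥ 10, di ≥ 6, tri–hexa ≥ 5) follow the MISA convention that also
matches the repeat-count minima observable in published EST-SSR tables;
they are configurable per unit length. Three less obvious rules:

* a run whose unit is itself periodic (`ATAT`) is reported at its
  smallest period (`AT`), so each physical run is reported exactly once;
* runs are broken at `N`, and any other non-ACGT character is an input
  error rather than silently skipped;
* when candidate repeats of different unit lengths overlap, the longer
  span wins, ties go to the smaller unit, then to the leftmost start —
  giving a deterministic, non-overlapping report.

Nearby repeats on one sequence (gap ≤ 100 bp, the MISA default, also
configurable) are fused into compound loci. Motif classes are
standardized to a rotation- and reverse-complement-invariant label
`"X/Y"`, with `X` the lexicographically smaller of the minimal rotations
of the motif and of its reverse complement. This is the only place where
our summaries can deviate from published per-motif tables, which
sometimes list strand-specific variants of the same class separately.
Summary percentages use the compound-inclusive locus total as
denominator.

The scanner is validated against a brute-force oracle (direct extension
at every start × unit length followed by the same resolution rule) on
random 2 kb sequences with planted repeats, and for strand symmetry of
the class/count multiset.

## Diversity statistics

All statistics derive from allele frequencies in which each non-missing
call contributes two observations, with `N` the non-missing individual
count — so per-locus `N` varies below the sample size, as in any real
dataset with dropout. The implemented forms are the GenAlEx ones:
`Ne = 1/Σp²`, Shannon's `I = −Σp ln p` (natural log, the GenAlEx
convention), `He = 1 − Σp²`, `uHe = He·2N/(2N−1)`, `F = 1 − Ho/He` (`NA`
for monomorphic loci rather than an error), and Botstein's
`PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²`. Two identities are exact by
construction and tested to 1e−12: `He = 1 − 1/Ne` and
`uHe/He = 2N/(2N−1)`. Mean rows are unweighted means over groups with
`NA` cells excluded and the divisor reduced. Per-population tables
average the within-population per-locus statistics over loci and attach
standard errors `sd/√(n loci)`.

Hardy–Weinberg testing is a chi-square goodness of fit of observed
genotype counts against expectations from the observed allele
frequencies, with `g(g−1)/2` degrees of freedom for `g` alleles. This is
a screening test only; exact or permutation HWE tests are out of scope,
and with many rare alleles the asymptotic p-values should be read
cautiously.

## F-statistics, gene flow and genetic distance

We use the Nei frequency-form estimators rather than Weir–Cockerham
variance components: per locus, `Hs` is the unweighted mean of
within-population expected heterozygosities, `Ht = 1 − Σ(p̄)²` with `p̄`
the unweighted mean frequency vector, and `Ho` the unweighted mean
observed heterozygosity; then `Fis = (Hs−Ho)/Hs`, `Fit = (Ht−Ho)/Ht`,
`Fst = (Ht−Hs)/Ht`. Unweighted (per-population) averaging is the GenAlEx
default and the defensible choice under severely unbalanced designs
(population sizes down to a single individual are retained, as field
surveys sometimes must). These forms satisfy
`(1−Fit) = (1−Fis)(1−Fst)` exactly, which the tests assert per locus.
Gene flow uses the island-model inversion `Nm = (1−Fst)/(4·Fst)`, with
`Fst ≤ 0` mapping to `NA` and `Fst = 1` to 0.

For pairwise population comparisons the same machinery is restricted to
each pair and loci are combined by averaging `Hs` and `Ht` before the
ratio (ratio of averages, the Nei convention, which is less noisy than
averaging per-locus ratios when some loci are nearly monomorphic). One
consequence worth knowing: with only two populations, `Ht` is computed
from the two-population mean frequencies, which bounds the
between-population variance contribution by a factor `1 − 1/r` (`r` = 2),
so pairwise Fst values run systematically lower than the many-population
per-locus Fst — the same pattern seen in published surveys that report
both. Nei's identity uses the 1972 standard form,
`GI = J̄xy/√(J̄x·J̄y)` with the three J-terms averaged over loci before
the ratio, and `GD = −ln GI` (infinite for `GI = 0`).

## Trees, ordination, ΔK

Individual-level distances are shared-allele distances: per comparable
locus the multiset intersection of the two calls over 2, averaged,
subtracted from 1. Missing loci drop out pairwise; a pair with no
comparable locus yields an `NA` cell and tree construction refuses with a
clear error rather than guessing. This metric is a declared convention —
published studies often say only "genetic similarity coefficients" — and
is the one place a reconstructed dendrogram may legitimately differ from
a published figure.

UPGMA is implemented directly (size-weighted average linkage, node height
half the joining distance) with ties broken by the smallest pair of
cluster indices and children printed smallest-original-leaf first, so the
newick output is fully deterministic; the suite checks ultrametricity and
equivalence with an independent average-linkage implementation. PCoA is
classical metric scaling: double-center `−D²/2`, eigendecompose, keep
positive eigenvalues; negative eigenvalues (which arise whenever the
distance is non-Euclidean, as shared-allele distances routinely are) are
dropped from the variance denominator — the GenAlEx-compatible choice —
and counted in the output. Axis signs are fixed by making the first
nonzero loading positive. A Euclidean input round-trips to 1e−9.

Bayesian admixture inference itself (STRUCTURE) is consumed, not
reimplemented: the package parses replicate log-likelihood tables and
computes the Evanno statistics, `ΔK = |L''(K)|/sd(L(K))` with sample
standard deviations across runs. ΔK needs at least three consecutive K
values and two runs per K; a zero standard deviation yields `NA` with a
warning rather than an infinite score.

## Fingerprinting panels

An accession is *distinguished* by a marker subset when its multilocus
profile is unique; a missing genotype is its own profile symbol. The
alternative — treating missing as a wildcard — makes "distinguishable"
non-transitive and was rejected. The panel is built greedily in strictly
descending PIC order (ties: higher Na, then name), never skipping a
ranked marker, which mirrors how published fingerprinting panels are
assembled; an `allow_skip` variant that drops non-informative additions
exists but is off by default. Discrimination counts are non-decreasing
along the steps, and an exhaustive subset search (capped at size 8)
provides the optimality reference: the greedy panel can be larger than
the minimal panel, but reaches 100% exactly when some subset does.

## The synthetic-data generator

There is no public genotype matrix for the study system the statistics
were built around, so the package carries its own generative stand-in,
and its defaults *are* the emulated study conditions: 7 populations of
sizes 23, 22, 9, 1, 7, 57, 1 (120 accessions), 19 loci with 7–20 alleles,
θ = 0.2 (inside the published 0.16–0.24 differentiation range),
per-population inbreeding (0.11, 0.12, 0.06, 0, −0.12, 0.29, 0) taken
from the published per-population fixation indices with the two
single-individual populations set to 0 (their printed F = −1 is a
degenerate artifact of N = 1), and a 5% missing rate so per-locus N
lands in the observed 95–120 window.

The differentiation model is Balding–Nichols: ancestral frequencies
Dirichlet(α·1), population frequencies Dirichlet(p·(1−θ)/θ), chosen
because θ is the model's Fst — a clean recovery target. Genotypes are
drawn from inbreeding-adjusted Hardy–Weinberg probabilities
(`P(ii) = p_i² + f·p_i(1−p_i)`, `P(ij) = (1−f)·2p_ip_j`). A negative `f`
requires `f ≥ −p/(1−p)` for every segregating allele; since continuous
Dirichlet draws put some frequencies arbitrarily close to zero, strict
admissibility would refuse almost every negative `f`. `simulate_genotypes()`
therefore keeps the strict contract (refusal naming the binding
constraint) while `generate_dataset()` opts into clamping: negative
homozygote probabilities are floored at zero and the genotype
distribution renormalized, attenuating the heterozygote excess only for
alleles rarer than about `|f|/(1+|f|)`. Allele identifiers are emitted as
plausible fragment sizes (offset plus motif-length steps) so payload
strings look like real electrophoresis output.

Reproducibility: one user seed drives deterministic per-stage sub-seeds
(frequencies, then each population block), so the same configuration
serializes byte-for-byte identically, while stages remain individually
reseedable.

What passing tests on this generator do and do not show: loci are
unlinked, mutation is absent, missingness is uniform, and allele
frequencies are exchangeable across loci — so the tests validate the
estimators under the model's assumptions, not robustness to linkage,
null alleles, allele-size homoplasy or scoring error in real SSR data.

## Validation against published tables

The published 19-marker summary tables shipped in `inst/extdata/` cannot
be regenerated without the unpublished genotype matrix, but they are
internally redundant: He must equal 1 − 1/Ne, F must equal 1 − Ho/He,
uHe must equal He·2N/(2N−1), Nm must follow from Fst, GD from GI, and
the mean rows from their columns. The acceptance suite asserts each of
these through the package's own formulas, with tolerance bands propagated
from the 3-decimal printing (each rounded input contributes up to 0.0005
scaled by the identity's derivative). Three printed cells fail their own
internal arithmetic by far more than rounding can explain — one gene-flow
cell (0.922 where its Fst implies 1.924), one genetic-distance cell
(0.042 where −ln GI gives 0.402, an apparent transposition), and the
gene-flow column mean (1.056 vs a column mean of 1.003) — and are
excluded as data defects, documented in the test code.

The differentiation-recovery experiment simulates 10 datasets (7
populations × 30 individuals, 19 loci, θ = 0.15, f = 0) and requires the
mean estimated per-locus Fst to land in [0.10, 0.20]; the problem sizes
were chosen so the whole suite, including this experiment, runs in well
under a minute on one CPU.

## Known limitations

* Frequency-form F-statistics carry finite-sample bias with very small
  populations; no small-sample (Weir–Cockerham or jackknife) correction
  is applied.
* HWE testing is asymptotic chi-square only.
* Rarefied allelic richness, null-allele estimation, AMOVA and bootstrap
  supports on trees are out of scope.
* The shared-allele distance and the greedy no-skip panel rule are
  conventions; other reasonable choices yield different trees/panels, and
  both are isolated behind single functions for that reason.
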