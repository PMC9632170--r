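---
title: "Methods: joint analysis of paired BCR and TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of paired BCR and TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossrep)
```

## The problem and the data model

Adaptive immunity stores its history in two receptor repertoires — the B
cell receptor (immunoglobulin heavy chain, IGH) and the T cell receptor
beta chain (TRB). The two compartments share recombination machinery and a
lifetime of common antigen exposures, so their statistical structure
within one individual need not be independent. `crossrep` quantifies that
dependence at two resolutions: (i) summary statistics — does an
individual's B-side clonality/diversity co-vary with their T-side
clonality/diversity across a cohort? — and (ii) individual public
clonotypes — are there sets of B and T CDR3 sequences whose per-individual
abundances rise and fall together?

The unit of data is a *repertoire*: one individual × one chain, a table of
unique CDR3 amino-acid clonotypes with read/cell counts and normalized
proportions. Clonotypes are keyed on the CDR3 amino-acid string alone
(`junction_aa`); the same CDR3 with different V/J assignments is one
clonotype. This matches the definition of a *public* clonotype — an
identical CDR3 found in two or more individuals — which anchors the
cluster analysis; keying on (CDR3, V, J) would fragment publicity and is
deliberately not done. Rows whose junction contains a stop (`*`) or
frameshift (`_`) marker, or any character outside the 20-letter alphabet,
are treated as nonproductive and dropped with a logged count. Missing or
zero counts default to 1, the single-cell convention, so CellRanger-style
exports load without special handling. A *cohort* groups repertoires by
(study, individual, chain) with a condition label (`healthy`/`disease`)
and an optional per-individual sequencing-quality covariate (fraction of
reads above Q30, consumed as a number, not computed from reads).
Individuals lacking one chain are kept for single-chain statistics but
excluded from every cross-receptor computation.

## Summary statistics

Ten statistics are computed per repertoire. Clonal *volume* is the number
of unique clonotypes. Four clonal-space proportions capture the abundance
distribution's two tails: the cumulative proportion of the 100 most
frequent clonotypes (boundary ties broken alphabetically, so results are
order-independent); *hyperexpanded* clones with proportion > 0.01; *small*
clones with proportion < 1e-5; and *rare* clones with absolute count below
3\. The hyperexpanded and small thresholds are proportions of clonal space
(not of the clonotype count), the reading consistent with "clonal space"
usage in the field and with immunarch's conventions; both are settable via
`bin_thresholds()` because reported analyses differ in which convention
they quote (1% vs 1/10, 0.001% vs 1/10000). Diversity covers richness and
evenness: Chao1 (bias-corrected form `S + F1(F1−1)/(2(F2+1))` by default;
the classic `S + F1²/2F2` is available and falls back when F2 = 0), Hill
numbers `exp(−Σ p ln p)` (q = 1, natural log, which makes the identity
below exact) and `1/Σ p²` (q = 2), Gini–Simpson `1 − Σ p²`, and the Gini
inequality coefficient of the count distribution. Two identities are
asserted in the tests rather than assumed: `gini_simpson = 1 − 1/hill_q2`
and `avg_degree = density (|V|−1)` for the networks below.

Sequencing depth confounds all of these, so `downsample()` supports two
modes: `"reads"` (multivariate hypergeometric, preserves expected
proportions) for the clonality/diversity sensitivity analysis, and
`"clonotypes"` (uniform clonotype sample, counts discarded) before network
construction, where frequency information is removed by design. Which unit
the original depth-sensitivity analysis used is not stated in the source
material; reads is the default here because it preserves the quantities
the statistics are computed from, and both modes are exposed.

## Cross-receptor correlation and meta-analysis

Within each study and condition group, the Spearman correlation between
individuals' IGH and TRB values of each statistic is computed over paired
individuals (mid-ranks for ties; p from the t approximation with n − 2
degrees of freedom, standard at per-study sizes of 5–100). Studies
contribute only with ≥ 4 paired individuals and a non-constant statistic.
Per-study coefficients are pooled under a common-effect (fixed-effects)
inverse-variance model on the Fisher z scale with var(z) = 1/(n − 3) — the
classical ZCOR estimator; the tests cross-check it against `metafor`'s
fixed-effect model. Correlations of exactly ±1 are clipped to ±0.999999
rather than propagating infinite z. Benjamini–Hochberg adjustment is
applied within one condition group's family of statistics (the family
definition is an argument; published figure families vary). The
Q30 covariate enters through `covariate_adjusted_association()`, an OLS of
one chain's statistic on the other plus the covariate, used to check that
correlations are not artifacts of sequencing quality.

## Similarity networks

Clonotype graphs have one node per unique CDR3 and an undirected edge when
1 ≤ LD ≤ 3 (Levenshtein distance, unit costs). Identical sequences cannot
co-occur as distinct nodes, so the lower bound is vacuous but explicit.
Construction prunes candidate pairs by length difference (|Δlen| > 3 ⟹
LD > 3), an exact optimization verified against the all-pairs computation.
Six global metrics follow the standard definitions: average degree
2|E|/|V|; density; mean local clustering (0 for degree < 2); global
efficiency (mean inverse shortest-path length over pairs, disconnected
pairs contributing 0); local efficiency (mean over nodes of the global
efficiency of the neighbour-induced subgraph); and Newman degree
assortativity (Pearson correlation of degrees across edge endpoints),
reported NA on regular graphs where it is undefined and excluded from
downstream correlation. igraph provides the implementations; the test
suite re-derives every metric with independent base-R linear algebra
(Floyd–Warshall distances, triangle counting via A³) to 1e-9 on
250-node instances. Because these metrics are strongly size-dependent,
they are computed only on clonotype-mode downsamples at fixed sizes, and
per-size results are reported without pooling across sizes.

## Public clonotype proportion clustering

For one chain and condition group, public clonotypes (≥ 2 individuals,
pooled across studies) define a proportion matrix: individuals × public
clonotypes, each entry the clonotype's share of that individual's whole
clonal space for the chain, with an exact 0 when absent. Absence is
informative — an individual not carrying the clonotype is evidence about
co-occurrence — so zeros are data, not missing values. Every B×T clonotype
pair is then correlated across individuals within each study (Pearson by
default, following the explicit choice in the subset analysis; Spearman is
an option) and pooled with the same Fisher-z fixed-effect model; a study
contributes to a pair only when both columns vary within it and it has ≥ 4
individuals.

The pooled matrix is hierarchically clustered — Euclidean distance between
correlation profiles, complete linkage, the base-R `hclust` defaults —
separately on B rows and T columns, and both trees are cut (fixed k by
default, height optionally). Every B-group × T-group block is scored by
its mean |pooled r|; blocks scoring at least `min_score` (default 0.5)
with at least 2 members a side are accepted greedily in decreasing score
order, so each group joins at most one cluster pair. This explicit
criterion replaces the interactive heatmap selection used in the original
workflow: visual selection is not reproducible, so the package substitutes
a parameterised algorithmic cut and reports every parameter. Block scoring
uses |r| (not r²): the sign matters for interpretation and squaring only
discards it. The fraction of public clonotypes assigned to clusters is
reported, never asserted, since it is data-dependent.

A related subset analysis takes the 50 most frequent public clonotypes of
each annotated cell subset (naive/memory B, naive/memory CD4/CD8),
computes within-subset proportions, correlates all selected pairs, and
counts pairs with r above a threshold and p < 0.05 per subset-pair
category, comparing a focal category against its complement with a 2×2
Fisher exact test. The correlation threshold is a required argument: the
source material uses 0.8 in one place and 0.7 in another, so the package
refuses to default silently.

## Cluster characterisation

Clusters are described by (i) mean pairwise Levenshtein distance of the
member sequences, (ii) unweighted means of per-residue physicochemical
properties — the ten Kidera factors, side-chain charge (+1 R/K, −1 D/E, 0
H), Kyte–Doolittle hydropathy, Zamyatnin volume, Grantham polarity,
Miyazawa–Jernigan contact energy, TOP-IDP disorder propensity and a burial
propensity; the last three are transcriptions of the published scales, and
the abundance-unweighted mean (each clonotype counts once) follows the
vdjtools convention — and (iii) enriched motifs. Each feature is compared
against 10,000 random size-matched groups drawn uniformly without
replacement from the same public pool: the per-cluster averages versus the
null averages by two-sample KS test, plus z-scores against the null for
display on a common scale. Pairwise distances and per-sequence property
values are precomputed once over the pool, so the 10,000 iterations cost
seconds.

Motif discovery is a deterministic stand-in for PWM-based tools: all
contiguous substrings of widths 3–10 occurring in ≥ 2 in-group sequences
are counted by sequence-level presence in the in-group and out-group, and
tested one-sided by Fisher exact. The enrichment ratio
`(k_in/n_in)/(k_out/n_out)` is reported as NA when the motif never occurs
outside. Multiplicity is controlled by BH over the *full enumeration
family* — every distinct substring seen, including those occurring in only
one sequence — because adjusting only over the recurring candidates would
condition on an outcome of the data and inflate the false-discovery rate
(with few candidates a single doubleton would otherwise pass at q < 0.05).
Reported motifs are de-duplicated greedily: a motif contained in an
already-reported, at-least-as-significant longer motif is suppressed.
Position-weight matrices, gapped motifs and sequence logos are out of
scope; the discrete scan is sufficient for contiguous planted motifs and
is exactly testable.

T-side clusters are additionally matched — exact CDR3β string equality, no
fuzzy matching, keeping the statistic deterministic — against an
antigen-annotated database table (McPAS-TCR/VDJdb-style TSV, column map
configurable). Per antigen category, enrichment is the cluster match
fraction over the background (all public T clonotypes) match fraction; a
clonotype may match several categories, so ratios are not constrained to
sum to anything.

## Replication

Given clusters from a discovery cohort and an independent replication
cohort, `Fr_B(i, m)` is the fraction of cluster m's B members that
individual i carries, counting a member as carried when the repertoire has
any clonotype within 2 edits of it (B memory of a CDR3 is rarely exact
across cohorts); `Fr_T` uses exact matching. The pooled OLS
`Fr_T ~ Fr_B + C` over all (individual, cluster) records — C is the
individual's total B+T clonal volume, guarding against "bigger repertoire
matches everything" — tests whether carrying a cluster's B side predicts
carrying its T side. Records pool across clusters into one regression
(per-cluster fits are available as a diagnostic); standard errors are
plain OLS, with the caveat that individuals contribute one record per
cluster. Significance is additionally calibrated by refitting on 100
random B/T clusters of matched sizes drawn from the public pools; the
empirical p uses the add-one rule `(1 + #{|slope₀| ≥ |slope|})/101`, whose
floor 1/101 ≈ 0.0099 corresponds to an observed slope outside the entire
null.

## The synthetic cohort generator

`generate_cohort()` produces paired cohorts carrying exactly the structure
the analysis assumes, with ground truth. Per individual, a size latent g
and diversity latent h are shared between chains: log clonal volume is
`μ_locus + σ(ρ_size g + √(1−ρ_size²) ε)`, so the induced between-chain
correlation of log volume is ρ_size²; the Zipf tail exponent of clonal
abundances is modulated as `α exp(α_mod (ρ_div h + √(1−ρ_div²) ε))`.
Counts are one guaranteed read per clonotype plus a multinomial draw over
Zipf weights at ~10 reads per clonotype. Non-cluster public-pool
clonotypes enter each repertoire independently with probability π = 0.5.
For planted cluster k, a per-individual factor `u_ik ~ N(0,1)` is shared
between the cluster's B and T members: member weight is
`softplus(λ u_ik + ε)` (softplus keeps weights positive without hard
truncation) and member *presence* has probability
`plogis(qlogis(π) + 1.5 u_ik)`. Coupling presence, not just abundance, to
the factor is a deliberate design choice: the replication statistic counts
presence, so a generator with factor-independent presence would make the
replication analysis unfalsifiable by construction — no parameter setting
could produce the signal the method is designed to detect. With the
coupling, absence-as-zero also reinforces the proportion correlations the
clustering consumes, as it does in real co-occurrence data.

Cluster member sequences derive from one seed CDR3 per cluster and side by
edits within radius `d_intra = 2`, with a planted 4-mer motif inserted at
a random interior offset of the seed and protected from edits — every
member carries the motif and members are mutually within 2·d_intra edits.
Private sequences are uniform random CDR3s ('C' prefix, 'F'/'W' suffix,
interior uniform over the alphabet, roughly normal lengths: mean 16 for
IGH, 14 for TRB, sd 2). Each individual draws from an RNG stream hashed
from (seed, study, individual), so output is byte-reproducible and
independent of generation order; the public pool has its own stream, so a
replication cohort can share clusters with a discovery cohort by passing
the same `generate_public_pool()` result.

Reference conditions, used by the test suite and the acceptance script: 4
studies × 30 individuals (replication: 1 × 40), mean volumes ~300 (IGH)
and ~500 (TRB), σ = 0.4, ρ_size = 0.9, α = 1, ρ_div = 0.7, public pools
60 B / 120 T, K = 3 clusters of 10 B × 20 T, λ = 2.5, noise sd 0.1. The
volumes are one order below typical bulk AIRR-seq cohorts so that a full
multi-seed recovery study runs on a laptop; all rates and correlations are
scale-free choices, and the vignette's claims about real data are limited
accordingly (below).

## What the synthetic validation does and does not show

Passing recovery tests demonstrates internal correctness: the pipeline
finds exactly the dependence structure it defines, at effect sizes typical
of a strong planted signal, and its null calibrations (type-I error of the
pooled correlation test, the covariate regression, and the KS comparison,
each within [0.02, 0.08] at α = 0.05) are honest. The generator does not
emulate V(D)J recombination biology, somatic hypermutation lineages,
germline gene usage, sequencing error, or the convergent-selection origins
of real public clonotypes; real repertoires have public clonotypes whose
sharing reflects recombination bias rather than co-regulation, and
cross-study batch structure richer than a study-level random factor.
Results on real cohorts therefore depend on assumptions the synthetic
tests cannot certify — above all that proportion correlations across
individuals reflect within-individual co-regulation rather than shared
technical depth, which is why the meta-analytic pooling, downsampling
sensitivity and quality covariate exist.

## Numerical conventions and edge cases

Proportions sum to 1 within 1e-9 per repertoire. Pearson/Spearman
correlations of constant vectors are NA and drop out of pooling;
all-NA pairs are excluded from clustering (imputed 0 only inside the
dissimilarity computation). Efficiency uses 1/∞ = 0 for disconnected
pairs. Chao1's classic form logs and falls back rather than dividing by
zero. Downsampling beyond a repertoire's size skips the repertoire at that
size with a warning, matching the multi-size design. Empirical p-values
are never 0 by the add-one rule. Top-N and ranking ties break
alphabetically, making every reported list deterministic. All stochastic
entry points take explicit seeds and derive independent substreams by
hashing, never by sequential RNG state.
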