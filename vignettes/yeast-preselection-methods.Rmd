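---
title: "Phenotype-based preselection of wine yeast starters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-based preselection of wine yeast starters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oenotype)
```

## The problem

Selecting an indigenous *Saccharomyces cerevisiae* strain to drive
alcoholic fermentation normally requires molecular typing, pilot
fermentations and sensory work for every candidate — infeasible when a
sampling campaign yields hundreds of isolates. `oenotype` implements a
cheap preselection front end: five plate assays with oenological
meaning are scored per isolate, condensed into an ordinal five-digit
phenotype code, and the codes are clustered so that whole groups of
isolates can be carried forward or rejected at once. The grouping is
then validated downstream against fermentation outcome (residual
sugar) and a free-sorting sensory panel of the finished wines.

## The phenotype code

The five digits, in decreasing oenological priority:

| digit | assay | values |
|---|---|---|
| 1 | killer toxin reaction | 1 = neutral, 2 = sensitive |
| 2 | H~2~S production (colony browning) | 0 none … 3 very high |
| 3 | acetic acid production | 0 = producer, 1 = non-producer |
| 4 | SO~2~ resistance | 0 = none, 1 = up to 300 mg/L, 2 = 400–500 mg/L |
| 5 | β-glucosidase | 0 = positive, 1 = negative |

Polarity is *not* uniform: digit 3's zero is the undesirable state,
and digit 5's zero is the desirable one. Codes are kept as integer
vectors rather than concatenated strings, so digits can be weighted in
the distance and none of the range information is lost.

Three choices here were genuinely open:

* **H~2~S collapse.** The assay is read on days 2, 5 and 8 but the
  code has one H~2~S digit. We default to the day-8 (final) reading —
  the plates are read until browning saturates, so the final reading
  is the assay's endpoint — and expose `policy = "max"` and
  `policy = "mean"` as alternatives.
* **Killer-positive isolates.** The coding scheme has no value for a
  killer-positive (K+) isolate, because collections from finished
  spontaneous fermentations essentially never contain one. The default
  is a hard error; `allow_killer_positive = TRUE` maps K+ to 3 for
  forward compatibility with collections where they occur.
* **Non-monotone SO~2~ series.** Growth at 400 mg/L but not 300 mg/L
  is a plate artifact, not a biological profile. We warn and code from
  the highest dose with growth rather than fail, since discarding the
  isolate would be the more destructive error.

## Clustering the codes

Distinct phenotypes (not isolates) are the clustered unit: isolates
carrying the same code are biologically interchangeable at this level
of description. Distances are (optionally digit-weighted) Euclidean;
agglomeration is Ward's method in the Ward.D2 convention — the
Lance–Williams recurrence on squared distances with merge heights
reported on the distance scale, the mathematically standard Ward for
Euclidean input. Ties between equally close merges are resolved by the
canonical (lexicographic) ordering of the distinct codes, which also
makes the fit invariant under permutation of the input rows.

**Multiplicity weighting.** By default each distinct code enters the
clustering weighted by the number of isolates that carry it
(`count_weighted = TRUE`, via `hclust(..., members = )`; this is
equivalent to clustering the isolates directly). The unweighted
alternative treats a phenotype seen once — typically a scoring error —
as the equal of a phenotype seen forty times. In planted-group
simulations the unweighted variant let rare noise codes chain between
groups and claim entire clusters (mean recovery ARI ≈ 0.92 with
frequent failures, and the gap rule rarely found the planted group
number), while the weighted variant recovers the planted structure
reliably (mean ARI ≈ 0.96). We therefore made weighting the default
and kept `count_weighted = FALSE` for dendrograms over the raw
phenotype list.

**Choosing k.** `select_k()` operationalizes the usual dendrogram
reading: sort the merge heights, find the largest increase between
consecutive merges, and cut there; cutting between the *j*-th and
(*j*+1)-th of *n* − 1 merges leaves *n* − *j* groups. Ties go to the
smaller *k*, candidates are capped at `k_max` (default 10), and a
degenerate tree with all-equal heights returns *k* = 2 with a
warning. Because Ward heights grow with cluster size, the top gap can
dominate even for well-separated equal groups, so on noisy panels the
rule occasionally returns 2 or 3 where 4 was planted; replicated
panels settle the question (the modal selection across 25 simulated
panels is stable), and that is how the package's own acceptance
experiment reports it.

**Group labels.** Dendrogram order is arbitrary, so groups are
relabelled by mean undesirability of their codes — the penalty
`3·[killer = 2] + h2s + [acetic = 0] + (2 − so2)`, weighting killer
sensitivity heavily because it alone disqualifies a starter — with
group 1 the most desirable. The raw dendrogram labels are kept in
`$dendro_order`, and the display palette (yellow/grey/green/pink) is
cosmetic metadata only.

## Fingerprint grouping

RAPD and interdelta fingerprints arrive as band-presence tables (gel
image processing is out of scope — band calling is done in the gel
software). Patterns are compared with the Dice coefficient
2|A∩B|/(|A|+|B|) and grouped by UPGMA on 1 − similarity, the standard
pairing for fingerprint data. Clusters are read at a similarity
threshold (default 0.90), and 2–5 representatives per cluster are
drawn reproducibly under a seed for downstream identification. Both
the Ward and UPGMA paths are cross-checked in the test suite against
naive oracles that recompute the merge objective from scratch at every
step.

## Free-sorting sensory analysis

Each panelist's sheet becomes a binary wines × wines matrix (1 = same
group); sheets are summed into a co-occurrence matrix. The conversion
to distances is `m − count` (m = number of panelists), the simplest
monotone transform — the fraction-based `1 − count/m` is available and
differs only by scale. Ward clustering on this non-Euclidean distance
is accepted deliberately (it is the established practice for sorting
data); average linkage is available as a robustness check. Sensory
groups are labelled A, B, … in dendrogram leaf order; which groups
count as "desirable" is metadata supplied by the analyst, not computed
— a sorting task measures similarity, not quality. Free-text aroma
descriptors are tallied per cluster by frequency.

## The H~2~S ANOVA battery

H~2~S is the one assay with enough quantitative structure for formal
testing. `h2s_anova()` fits the one-way model Y~ij~ = μ~i~ + ε~ij~ and
reports the omnibus F test together with the checks that license it:

* **Levene's test**, mean-centered (classical) by default since the
  response is a bounded score with no heavy tails;
  `levene_center = "median"` gives Brown–Forsythe.
* **Kolmogorov–Smirnov** on the externally Studentized residuals
  against the standard normal. Mean and sd are estimated, so this is a
  Lilliefors-flavoured screen, not an exact test; we use it as a
  diagnostic verdict at α = 0.05, not as a reported p-value of record.
* **Runs test** on the residual signs about their median, written
  in-package because no installed package provides one: exact
  enumeration-based p for n ≤ 20 (two-sided as twice the smaller
  tail, capped at 1) and the normal approximation with mean
  1 + 2n₁n₂/n beyond. The exact branch is verified against full
  combinatorial enumeration in the tests.

Post-hoc pairwise comparisons are deliberately absent: the method uses
the omnibus answer only. MANOVA over the three incubation days is a
non-goal (its assumptions fail on this kind of scaled data), as is
repeated-measures modelling.

## Fermentation and concordance validation

Residual sugar is glucose + fructose at the last monitored day,
averaged over replicates; a strain has fermentation capacity when
residual sugar ≤ 10 g/L (the dry-wine bound; the boundary value itself
passes, since "greater than 10 g/L" is the failure condition).
`concordance_table()` reproduces the validation bookkeeping — group
sizes, capacity rate, preliminary × sensory cross-tabulation,
validation rate — and `favorable_groups()` recommends the phenotypic
groups whose capable strains land predominantly (majority) in the
desirable sensory groups. The validation flag itself is taken from the
outcome table, not recomputed: the published bookkeeping counts a
killer-sensitive strain that fermented to dryness but produced an
off-odor wine as *consistent* with its unfavorable group, a judgement
no simple rule reproduces.

Community richness types use bands at ≤ 2, 3–4 and ≥ 5 strains per
sample; 5–6 strains were unobserved in the motivating data, so the
band edges are configurable.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage is testable without any
external data, at the scale of the motivating study:

* `gen_isolate_panel()`: 190 isolates drawn from four prototype codes
  chosen to match the qualitative group profiles (killer-sensitive;
  neutral/low-SO~2~/non-acetic; neutral/low-H~2~S/acetic/resistant;
  high-H~2~S/acetic/resistant/β-glu-positive) at near-equal pairwise
  separation (2.0–2.65). Each digit flips to an *adjacent* ordinal
  value with probability 0.03 — grading error moves a colour score by
  one step, it does not resample it uniformly.
* `gen_sorting_panel()`: 10 panelists, 13 wines, consensus groups of
  sizes 5/4/2/2; each panelist keeps a wine's consensus group with
  probability 0.9, else moves it to a uniformly chosen other group.
* `gen_fermentation()`: exponential sugar decay from 119.5 g/L glucose
  and 120.1 g/L fructose with truncated Gaussian noise (sd 1 g/L) over
  14 days; no lag or Monod phase, because the validation step only
  thresholds the endpoint.

Passing recovery tests on these panels shows the machinery separates
what it was built to separate; it does **not** show that real isolate
collections have four groups, that real phenotype noise is independent
across digits, or that panelists err independently and uniformly. Real
collections also contain correlated assay failures and species-level
structure the generator only sketches (species mixes per group, with
the minor species confined to particular groups).

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs are handled as described above;
similarity-threshold cuts add a 10⁻¹² slack so "at least 90%
similar" includes merges at exactly 0.10 distance. The packaged
experiments use: Ward-vs-oracle on 200 random instances of n ≤ 10,
UPGMA-vs-oracle on 200 instances of n ≤ 12, 100 seeded panels each for
phenotype (flip 0.05) and sorting (agreement 0.9) recovery reported as
the mean adjusted Rand index, 2000 null replicates at 30 observations
per level for the F-test calibration, and 25 replicate panels for the
modal group-number selection — sizes at which each experiment's Monte
Carlo error is far below the margins being checked.

## Known limitations

* The gap rule inherits Ward's size-dependent heights; on single noisy
  panels it can under-split (see above). Inspect `$gap_profile`.
* The Dice/UPGMA threshold for strain-level distinction is exposed as
  configuration because no universal cutoff exists for interdelta
  fingerprints.
* The KS normality screen is approximate (estimated parameters).
* Sensory desirability of sorting clusters is analyst metadata; the
  package will not invent it.
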