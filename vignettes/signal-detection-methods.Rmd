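---
title: "Methods: disproportionality, onset profiling and network analysis in srsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, onset profiling and network analysis in srsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsignal)
```

## The counting model

Every analysis in srsignal counts **reports**, not drug rows or event
rows: a report with three montelukast entries and two identical
preferred terms contributes one observation. Spontaneous reports carry
no exposure denominator, so all inference is *within-database
disproportionality* — the comparator for a drug–event pair is all other
reports in the same database, with no restriction to a pharmacological
comparator class. The exposure definition follows each database's role
coding: primary suspect (`PS`) for FAERS, `suspect` for JADER and CVAR,
both configurable via the `roles` argument.

Deduplication precedes everything. FAERS publishes successive versions
of a case under new `primaryid`s; we keep, per `caseid`, the version
with the greatest key built from the FDA receipt date and the report id
(ties resolved to the lexicographically greatest id and logged). JADER
and CVAR extracts are deduplicated by dropping identical rows in the
drug/event tables and keeping one case record per id. Name matching is
Unicode-NFKC + casefold + whitespace-squash throughout, because trade
names appear in inconsistent case and width across the three dialects.

## The four statistics and the joint criterion

For a 2×2 table (a, b, c, d) with N = a+b+c+d and E = (a+b)(a+c)/N:

* ROR = ad/bc with Wald interval exp(ln ROR ± z√(1/a+1/b+1/c+1/d)).
* PRR = [a/(a+b)]/[c/(c+d)] with the analogous Wald interval, and the
  Pearson χ² **without** Yates continuity correction. The uncorrected
  variant was chosen because back-reconstruction of published LTRA–EGPA
  rows from their printed marginals matches it to well under 0.1%,
  whereas the corrected statistic does not.
* IC: the default reporting variant is the *raw* information component
  log₂(a/E), which published tables satisfy exactly (they obey
  IC = log₂ EBGM row by row); the credibility-shrunk variant
  log₂((a+½)/(E+½)) is available via `ic_variant = "shrunk"`. IC025 is
  reported two ways: the closed approximation
  IC − 3.3(a+½)^(−1/2) − 2(a+½)^(−3/2) (the default, which reproduces
  printed bounds), and a Monte-Carlo 2.5th percentile of log₂λ under the
  Gamma(a+½, E+½) posterior. The two agree within ~0.02 bits for large
  counts **on the shrunk variant**; anchored at the raw IC the closed
  form inherits the raw/shrunk offset, which is visible when E is small.
* EBGM: the full gamma–Poisson shrinker is available — fit the
  two-component mixture prior by marginal maximum likelihood over all
  drug–event pairs (`fit_gamma_poisson_prior()`, BFGS on log/logit
  scales from the conventional start (0.2, 0.1, 2, 4, 1/3)), then score
  pairs by the posterior-mixture geometric mean with the 5th-percentile
  EB05. The *default reporting variant*, however, is the unshrunk
  large-count limit EBGM = a/E with EBGM05 the 2.5th percentile of the
  limiting Gamma(a, E) posterior: published tables match this
  convention (their printed "EBGM05" is a two-sided lower limit, not
  DuMouchel's one-sided 5th percentile), and at the case counts of
  interest (hundreds) the shrinkage correction is below 1%.

A pair is a signal only under the conjunction: ROR lower bound > 1 and
n ≥ 3; PRR > 2 and χ² ≥ 4; IC025 > 0; EBGM05 > 2. The PRR flag uses the
point estimate (the phrase "95% CI of PRR > 2" is ambiguous; the CI is
reported alongside). No multiplicity adjustment is applied — the joint
criterion itself is the guard, and its family-wise behaviour is
characterized empirically in the test suite (≤5% false-positive rate at
E ≈ 5 under the null; in practice far lower).

Zero cells error by default; an explicit Haldane +0.5 policy is
available and flagged in the output (`corrected = TRUE`). Under that
policy a zero a-cell also switches the IC to the shrunk variant, since
log₂(0) is undefined.

### Subgroups and co-medication

Each stratum (age < 65 / ≥ 65, sex, indication) is analyzed as its own
complete database: all four cells are recomputed inside the stratum, and
reports missing the stratifying field are excluded from that axis. For
the indication axis, only index-drug reports carry an indication, so the
asthma / other-indication split applies to exposed reports while
non-exposed reports form a shared background — the only reading under
which the background cells remain non-empty. Co-medication analysis
restricts (`require`) or removes (`exclude`) reports listing the
co-medication in *any* role before rebuilding the table, mirroring the
sequential-exclusion design used to probe corticosteroid confounding.

## Weibull time-to-onset

Time-to-onset is onset date minus the earliest start date of the index
drug, in days; non-positive and incomputable intervals are excluded with
reason counts. Partial dates (year or year-month only) are imputed to
the 1st and flagged; a sensitivity switch excludes imputed records.

The two-parameter Weibull(α scale, β shape) is fit by maximum
likelihood: the profile score for β,
1/β = Σtᵝ ln t / Σtᵝ − mean(ln t), is solved by bisection (bracket
doubling upward from β = 10⁻³), and α = (mean tᵝ)^(1/β) follows in
closed form. 95% CIs use the observed information on (ln α, ln β),
computed by central differences (h = 10⁻⁴) and back-transformed — a
standard choice that reproduces the right-skewed asymmetry of published
intervals; coverage is verified empirically at 93–97% in the test suite
(500 simulations, n = 300). Failure type follows the shape CI: *early*
if β̂ < 1 with the whole CI below 1 (hazard decreasing — the pattern
reported for LTRA-associated EGPA), *wear-out* if both above 1, *random*
otherwise, with a CI touching 1 counted as random. Degenerate samples
(n < 3, or all values identical) error rather than returning a fit.

## Network stage

Gene symbols are upper-cased and deduplicated. Target lists from
multiple prediction sources are unioned with per-symbol provenance; the
drug–disease overlap is a plain set intersection with Venn counts. The
interaction network loader accepts STRING-format TSV (integer 0–1000
scores rescaled to [0, 1]), drops self-loops, collapses duplicate pairs
keeping the maximum score, and applies the 0.4 combined-score threshold
by default.

MCODE is implemented from the classic three-stage description: vertex
weighting by the order × density of the highest k-core of each closed
neighborhood; seeded expansion in decreasing weight order, recruiting
neighbors with weight ≥ seed weight × (1 − node score cutoff) to a
depth limit; optional haircut (the cluster's 2-core, retaining the seed)
and fluff. Density is defined without self-loops, 2|E|/(|V|(|V|−1));
the loop-including variant of the original description is not used.
Clusters are scored density × size and ordered by score, then size,
then seed name, making the output invariant to node input order. All
MCODE parameters are surfaced (`mcode_params()`) with the common
Cytoscape defaults (degree 2, node score cutoff 0.2, k-core 2, haircut
on, fluff off), since published analyses rarely state them. The
implementation is verified against an independent adjacency-matrix
transcription on random graphs of ≤ 8 nodes.

Enrichment is the upper-tail hypergeometric test per term with
Benjamini–Hochberg FDR across all tested terms; the universe defaults
to all genes in the annotation collection and is configurable. Terms
with zero overlap are omitted. Deriving disease gene lists from raw
expression data is out of scope — the module consumes a prepared gene
list, and the bundled fixtures are explicitly synthetic.

## The synthetic-report generator

`generate_srs()` emulates the structure the analyses rely on, with
closed-form ground truth:

* drug exposures are independent Bernoulli draws per report; each
  event's baseline probability is multiplied by the pair's relative
  reporting rate when the paired drug is present. This independence
  design gives exact expected 2×2 cells for oracle tests but does not
  reproduce real co-prescription correlation (a planted confounder must
  be constructed explicitly, as the test suite does).
* one present drug per report is primary suspect, chosen uniformly;
  the rest are concomitant.
* onsets for signal pairs are drug start + a Weibull(scale, shape) draw
  (rounded up to whole days, floored at one day); other events get
  arbitrary recent onsets.
* duplicates are injected as re-versioned copies with later receipt
  dates, so the deduplication module's removed count has the injected
  count as its exact ground truth.
* missingness is completely at random, per field; real SRS missingness
  is surely informative, so passing tests show correctness of the
  mechanics, not robustness to informative missingness.

The default configuration mirrors the conditions of the LTRA–EGPA
study: the four LTRA ingredients at FAERS-like exposure frequencies
(montelukast 2×10⁻³), an EGPA-like rare event (3×10⁻⁵) plus the legacy
synonym term, a planted montelukast pair at relative rate 180 with
Weibull(391.08 d, 0.76) onset — the observed-to-expected ratio and
onset profile reported for that association — common co-medications,
5% duplicates, and demographic mixtures (54% female, ~12/66/22%
child/adult/elderly age mixture, log-normal weight around 72 kg) chosen
as typical of adverse-event reporting populations. At the default rare
event rate a realistic number of reports (tens of millions) is needed
for large case counts; tests and examples therefore scale the exposure
and event probabilities up rather than the database size, keeping
expected cell counts comparable while staying fast.

## Numerical choices

* Mixture likelihoods use a two-term log-sum-exp; optimizer excursions
  are clamped to ±25 on the log/logit working scale.
* EB05 under the full prior is solved by `uniroot` on the posterior
  mixture CDF to 10⁻¹⁰; the implementation is tested to 10⁻⁶ against
  piecewise adaptive quadrature of the unnormalized posterior.
* The IC Monte-Carlo percentile uses a seeded draw that restores the
  global RNG state, so adding it to a pipeline does not perturb other
  seeded stages.
* Contingency cells are stored as doubles: Pearson χ² numerators exceed
  32-bit integer range even at moderate database sizes.
* Reconstructed background cells (`reconstruct_table()`) are fractional
  because the printed ROR anchor is rounded; cells are deliberately not
  rounded, keeping the anchor exactly consistent.

## Problem sizes

The shipped tests run the Weibull coverage study at 500 × n = 300,
prior-weight recovery at 10⁵ pairs, criterion specificity at 10³ null
pairs (E ≈ 5) and power at 500 pairs (relative rate 50), MCODE
verification on 100+ random graphs of ≤ 8 nodes, and enrichment
enumeration on universes of ≤ 20 genes — sizes chosen so the whole
suite completes in a few minutes on one CPU while keeping Monte-Carlo
margins comfortable.

## Known limitations

* Disproportionality quantifies reporting imbalance, not incidence or
  causation; the package deliberately reports all four statistics and
  their flags rather than a single decision.
* The JADER dialect reader uses a simplified romanized schema rather
  than the raw Japanese column headers; map columns accordingly when
  ingesting original extracts.
* No probabilistic record linkage: deduplication is rule-based
  (versioning and exact row duplicates) as in the standard FDA
  recommendation.
* MedDRA hierarchy roll-ups (SOC/HLT) and RxNorm mapping are out of
  scope; event queries are explicit preferred-term sets.
* Censoring-aware survival modelling and parametric alternatives to the
  Weibull are not implemented; the shape-parameter test assumes
  uncensored onset intervals as recorded in the reports.
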