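---
title: "Building a second-hand smoke job exposure matrix: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a second-hand smoke job exposure matrix: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shsjem)
```

## The exposure model

A job exposure matrix (JEM) for second-hand tobacco smoke (SHS) assigns to
every 4-digit occupation code three ordinal ratings agreed by an expert
panel:

* **likelihood** $L \in \{0, 1\}$ — whether at least 10% of the code's
  jobholders are exposed to SHS at work;
* **frequency** $F \in \{0,\dots,4\}$ — from never to daily with more than
  one hour of exposure per day;
* **intensity** $I \in \{0,\dots,3\}$ — from none, through outdoor or
  passing exposure and well-ventilated indoor spaces, to poorly ventilated
  indoor spaces.

The scheme is **conditional**: a rater who scores $L = 0$ rates nothing
else (frequency and intensity are missing, which is distinct from the
substantive level 0), and a finished JEM record with $L = 0$ carries
$F = I = 0$. A single per-code score, the **compound severity**
$S = L \times F \times I$, summarises exposure; exhaustively enumerating the
13 legal consensus triples shows its attainable image is exactly
$\{0, 1, 2, 3, 4, 6, 8, 9, 12\}$ with maximum 12 (daily prolonged exposure
indoors in a poorly ventilated space):

```{r severity-image}
enumerate_severity_triples()
```

Missing ratings are represented by an explicit `NA`, never by level 0,
because conflating "not rated" with "never/none" corrupts both the
agreement statistics and the consensus step. Occupation codes are stored as
character strings throughout — they are identifiers, and leading zeros and
dialect variants must survive round-trips.

## Inter-rater agreement

Agreement across the panel is Fleiss' $\kappa$ for $n$ raters and $N$
items: with $n_{ij}$ the number of raters assigning item $i$ to category
$j$,

$$P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)}, \qquad
  \bar P = \frac{1}{N}\sum_i P_i, \qquad
  \bar P_e = \sum_j p_j^2, \qquad
  \kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e},$$

where $p_j$ is the overall share of assignments in category $j$. By default
only the **likelihood axis** is assessed: frequency and intensity are
unrated whenever a rater scores likelihood 0, so pooling them would
artificially depress apparent agreement. Agreement on the conditional axes
is available behind an explicit opt-in
(`rating_agreement(..., include_conditional = TRUE)`) and is then restricted
to the codes every rater rated on that axis.

Numerical edge cases are handled explicitly rather than silently:

* items with missing ratings are **excluded with a logged count**, never
  imputed — the Fleiss formulation assumes equal rater counts per item, and
  silent imputation would bias $\kappa$;
* when every assignment falls in one category, $\bar P_e = 1$ and $\kappa$
  is undefined; the package returns $\kappa = 1$ if observed agreement is
  also perfect and raises a "degenerate margin" error otherwise;
* the test suite checks the implementation against an independent
  brute-force oracle that enumerates all rater pairs per item, to within
  $10^{-12}$, and verifies invariance under permutations of items, raters
  and category labels.

No variance or confidence interval is attached to the point estimate; a
percentile bootstrap over items (`fleiss_kappa_boot_ci()`, seed-controlled)
is offered as an optional extra.

## Consensus adjudication

After the panel's discussion round, remaining conflicts are resolved
mechanically per axis, likelihood always first:

| panel | rule | provenance |
|---|---|---|
| all ratings equal (incl. a single rating) | that value | `unanimous` |
| three ratings, two equal | the repeated value | `majority` |
| two distinct ratings | the higher (worse) value | `higher_of_two` |
| three distinct ratings | policy tie-break | `tiebreak` |

Two design points were genuinely open and are resolved as follows:

* **Two equal ratings** resolve as `unanimous`, not `higher_of_two`: the
  higher-value rule exists to settle *conflicting* ratings, and two equal
  ratings do not conflict.
* **Three distinct ratings** are undefined by the adjudication rules (a
  human consensus process guarantees a majority or a two-rater case). The
  default policy takes the **ordinal median** — it respects the ordering and
  is the least-assumption choice — logs the event, and flags the record's
  provenance as `tiebreak` so the deviation stays auditable; a strict policy
  (`consensus_policy("error")`) aborts instead.
* The higher-value rule is applied uniformly across axes; on the binary
  likelihood axis the maximum of two distinct values is simply 1 (logical
  OR), so uniformity costs nothing.

If the consensus likelihood is 1, frequency and intensity are each resolved
over the subset of raters who rated that axis; raters who scored likelihood
0 contributed no conditional ratings and are absent from those panels. A
consensus likelihood of 1 with *no* rater supplying a frequency or
intensity cannot arise from a table that passes validation, but the builder
still guards it with a named error rather than fabricating a level.
Adjudication is defined for panels of one to three ratings per axis,
matching the three-rater design; larger panels abort rather than silently
extending the rules.

## Workforce weighting and cross-tabulation

Jobholder counts per 4-digit code come from official labour-market extracts
whose counts are rounded to the nearest 100; the reader can assert that
convention (`read_workforce_csv(..., rounded = TRUE)`). When the JEM and
the workforce use different classification versions, counts are recoded
through a **crosswalk** of `(source, target, weight)` rows with weights
summing to 1 per source. One-to-many splits require explicit weights: how a
source code's jobholders divide across targets materially changes counts,
so a crosswalk file without a weight column falls back to an equal split
only with a loud warning. Each target's total is rounded **half-to-even**
once, after summation, so the total workforce is conserved to within 0.5
per target code; the realised drift is reported in an attribute, never
hidden.

`cross_tabulate()` accumulates each code's jobholders into the cell indexed
by its frequency and intensity; all workers in likelihood-0 codes fall in
the (0, 0) cell, and structurally impossible cells (frequency 0 with
positive intensity, or positive frequency with intensity 0) are `NA`, not
zero. From the cross-tab, `exposed_worker_estimates()` derives the number
of workers employed in codes rated likely, their share of all jobs, and the
lower bound `min_prevalence × n_in_exposed_jobs` on individually exposed
workers — the bound follows directly from the likelihood definition: a code
is rated likely only when at least `min_prevalence` (default 0.10) of its
jobholders are exposed. One published headline ("workers in codes where
exposure occurs daily indoors" as a share of "codes where exposure likely
occurs indoors") is ambiguous about whether "indoors" means intensity level
3 only or levels 2–3; both denominators are computable from the cross-tab's
columns, and the package asserts neither.

Reported percentages are displayed to one decimal place but always written
alongside their numerator and denominator, so rounded displays remain
auditable; underlying values are kept at full precision.

## The synthetic-data generator

`sim_config()` defines a complete synthetic study. Defaults mirror the UK
study conditions: 412 four-digit codes in 26 two-digit groups, 3 raters,
and a 84/412 (20.4%) prevalence of codes with true likelihood 1. Values the
study conditions do not pin down were chosen once as realistic and are not
tuned:

* `rater_error = 0.1` — a 10% per-axis deviation probability, consistent
  with substantial-but-imperfect expert agreement;
* frequency law over levels 1–4 = (0.20, 0.30, 0.35, 0.15) and intensity
  law over 1–3 = (0.40, 0.35, 0.25) for truly likely codes — most exposed
  occupations see weekly-to-daily, outdoor-or-ventilated exposure, with
  heavy indoor exposure rarest;
* workforce counts lognormal with `meanlog = log(50 000)`, `sdlog = 1.1`,
  rounded to the nearest 100 — right-skewed code sizes totalling roughly
  the UK workforce across 412 codes;
* the crosswalk mixes identity, merge (2→1) and split (1→2, weighted)
  mappings, 0.8/0.1/0.1 by default.

Rater noise uses an **adjacent-level kernel** on the ordinal axes (a
deviating rater moves one step, reflecting at the scale boundaries) because
expert disagreement on ordinal exposure scales is overwhelmingly between
neighbouring levels; a uniform relabelling kernel is available for
worst-case tests. The binary likelihood axis flips with probability
`rater_error`, independently. A rater who (even mistakenly) reports
likelihood 1 must rate the conditional axes, so false positives draw
frequency and intensity from the configured laws; a rater reporting
likelihood 0 reports nothing else. Every generated table satisfies the
validator by construction, and identical config plus seed yields
byte-identical written outputs.

What the generator does **not** emulate: real SOC code semantics (titles
are synthetic), correlation of exposure across related codes within a
group, rater-specific bias or learning between rounds, and the human
discussion that moves round-1 ratings toward round-2 consensus. Passing
tests on synthetic panels therefore demonstrate the *mechanics* of the
pipeline — validation, agreement, adjudication, weighting, conservation —
not the validity of any particular expert panel's judgements.

## Reference fixtures

Two plain-text fixtures ship with the package. The national
jobholders-by-frequency×intensity cross-tabulation for the UK in 2020 is
typed in as printed (`uk_jobholders_by_exposure_2020.csv`).
`synthetic_reference_jem.csv` is a fully synthetic consensus JEM
(deterministically constructed by `synthetic_reference_jem()`) carrying the
published summary structure of the UK SHS-JEM — 84 of 412 codes likely,
overall mean severity exactly 1.0, three maximum-severity codes (6116,
6135, 6137) and the reported group fractions — for use where the deposited
matrix itself is not redistributed. Below those marginals, the identity of
likely codes and each code's frequency/intensity pair are arbitrary
synthetic choices.

## Problem sizes and numerical tolerances

The test suite exercises the kappa implementation against the brute-force
oracle on 1000 random tables of up to 12 items × 4 raters (tolerance
$10^{-12}$); consensus recovery on 250-code panels (exact at zero rater
error; at least 95% likelihood recovery at 10% error with 3 raters, fixed
seed); monotone degradation of mean κ over error rates {0, 0.1, 0.3, 0.5}
with 200 replicates each on 40-code panels; and workforce conservation
under random crosswalks against an exact (unrounded) oracle. These sizes
were chosen to make the distributional checks stable at fixed seeds while
keeping the default test run fast. Crosswalk weight sums are checked to
within $10^{-9}$.

## Known limitations

* The adjudication rules are those of a three-rater panel; the package
  deliberately refuses larger panels rather than inventing an extension.
* Fleiss' κ is the only agreement statistic provided (no weighted κ,
  Krippendorff's α or Gwet's AC1), matching the construction being
  implemented.
* NS-SEC-style class mappings and the occupation-code universe are always
  user-supplied lookup files; the package embeds no official classification
  definitions and does not re-derive socioeconomic classes from employment
  relations.
* The per-group mean severity is an unweighted mean over codes; a
  workforce-weighted view requires joining the cross-tab, and the two are
  kept distinct to avoid ambiguity.
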