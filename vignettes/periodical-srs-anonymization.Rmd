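---
title: "Anonymizing periodical SRS releases against cross-release linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing periodical SRS releases against cross-release linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmsanon)
```

## The problem

Spontaneous reporting systems (SRSs) such as FAERS publish adverse drug
event reports quarterly.  Each report carries quasi-identifiers (QID: sex,
age, weight), multivalued sensitive terms (indications and reactions), and
a *CaseID* that links follow-up reports of the same event across quarters.
Single-release k-anonymity is not enough here: the CaseID gives an
adversary a join key across releases.  If a target's group in release
$R_i$ holds candidate CaseIDs $CI$, the adversary can discard every
candidate whose record in an *earlier* release carries a published QID
that cannot cover the target's true leaf QID (B-attack), do the same with
*later* releases (F-attack), and — knowing the target's first report falls
in $R_i$ — discard every candidate already published before (L-attack).
The package ships a three-quarter worked example in which each quarter is
3-anonymous yet the three attacks reduce a target to a single candidate
with a certain HIV diagnosis (`example_series_vulnerable()`).

## The privacy model

A series $R_1,\dots,R_n$ satisfies PPMS$(k,\theta^*)$-bounding when, for
every target, (a) $|CI - (B\cup F\cup L)| \ge k$ and (b) the confidence
$conf(v \to s_j) = \sigma_{s_j}(g)/|g|$ never exceeds the term's threshold
$\theta_j$, where $\sigma_s(g)$ counts the *cases* in the target's group
containing $s$.  Thresholds are per term because a fever is not an HIV
diagnosis; three setting schemes are provided (`set_thresholds()`):
uniform, frequency-based (population mean/SD bands over per-term counts
mapping to 0.2 / 0.6 / 1.0), and level-wise labels (high/low/non →
0.2 / 0.4 / 1.0).

Two mechanisms enforce the model:

* **NC-bounding** — every emitted group must contain at least $k$ *new*
  CaseIDs.  Old cases are presumed excludable (B/L-attacks target exactly
  them), so the group must survive their loss.  The per-term occurrence
  bound follows: keeping $conf \le \theta_s$ after the worst-case
  exclusion of all old cases requires
  $\sigma_s(g) \le \eta_s(g) = \lfloor \theta_s |NC(g)| \rfloor$.
* **QID-covering** — an old case's published QID must cover its designated
  prior publication, so no later release can contradict an earlier one
  (cover tests are transitive along a CaseID's chain).  This defeats the
  F-attack for candidates that matter.

## The algorithms

Each quarter passes through three stages (`anonymize_quarter()`):
same-CaseID rows merge into super records; old cases are pre-generalized
for covering; a greedy clustering grows QID groups from a random seed by
repeatedly admitting the record minimizing
$\Delta IL'(g,r) = \Delta IL(g,r) \times PR(g,r)$, where $\Delta IL$ is
the size-weighted widening of the group's generalization and
$PR(g,r) = 1 + \sum_{s \in S_r} \sigma_s'/(\eta_s' - \sigma_s' + 1)$
penalizes candidates whose terms are already frequent in the group
(infinite, hence never chosen, past the bound).  Ungrouped records are
then assigned to the feasible group with minimal $\Delta IL'$, or
suppressed when none exists; super records split back and every group
publishes one common generalized value.

The variants differ in covering economy: `ppms` covers the most recent
prior publication (generalization accumulates along the follow-up chain),
`ppms+` covers only the *earliest* one (later publications belong to old
cases, which B/L-attacks can exclude regardless, so covering them buys
nothing), and `ppms++` additionally keeps old cases out of group formation
— a pre-generalized old seed makes $\Delta IL'$ blind among the leaf
records it covers, so old cases are placed only after the groups exist.
`ms` is the single-release baseline (no covering, size-based $k$); it is
deliberately unsafe across releases and serves as the comparison point.

## Numerical and design choices

* **Information loss.**  $IL(g) = |g| [\sum_i \frac{\max(N_i,g)-\min(N_i,g)}
  {\max(N_i)-\min(N_i)} + \sum_j \frac{h(C_j,g)}{h(C_j)}]$ with taxonomy
  node heights measured from the leaf level (leaf 0, root $h$), numeric
  generalization by min–max interval hulls, and intervals closed on both
  ends.  $\Delta IL$ is the size-weighted *widening*
  $(|g|{+}1)(w_{new}-w_{old})$, which is zero exactly when the group value
  already covers the record — the property the `ppms++` design exploits;
  the additive form $IL(g\cup r)-IL(g)$ would charge every admission the
  group's standing per-record loss and blur that distinction.
* **Bound projection during growth.**  Enforcing $\eta_s$ at every
  intermediate size deadlocks for $\theta < 0.5$: a two-member group has
  $\lfloor 2\theta \rfloor = 0$.  Admission during growth therefore
  evaluates $\eta_s$ at $|NC|$ projected to the required $k$ ($\eta$ is
  monotone in $|NC|$, so admitted records remain admissible in the
  finished group); the close-out check uses the actual count.
* **Ties.**  Argmin ties break by smallest CaseID, then input order; the
  first seed of a quarter is drawn uniformly from the pool under the run's
  seed, each next seed is the remaining record with the largest pairwise
  $\Delta IL$ to the last-added one.  Identical seeds give identical
  releases.
* **Stopping and suppression.**  Grouping stops when the remaining pool
  cannot form a group (fewer than $k$ new cases, or some term's share of
  the remaining new cases exceeds its threshold).  Records with no
  feasible placement are suppressed and logged, never force-placed; a
  quarter in which some term's total count exceeds
  $\lfloor \theta_s |NC(D)| \rfloor$ is diagnosed as globally infeasible
  (`infeasibility_report()`), mirroring what happens to real quarters in
  which a single symptom covers a fifth of all reports.
* **Life span.**  A CaseID reappearing more than `lifespan_x` (default 8)
  quarters after its last publication is treated as new.  The audit has no
  such window (the attack definitions do not), so a gap longer than the
  window could in principle re-expose a case; the synthetic generator's
  `lifespan_max` (4) keeps the study conditions inside the window.

## The synthetic generator

`generate_series()` emulates the structure the method targets: each
quarter brings `cases_per_quarter` new cases (default 2,000 over 6
quarters) plus follow-ups of open cases (probability 0.3 per quarter over
a life span of up to 4 quarters, with gap probability 0.25 producing
present–absent–present patterns); follow-ups keep the person's leaf QID —
exactly what the attacks exploit.  Symptoms (200) follow a Zipf law
(exponent 1.2, about 1.3 terms per case); drugs a flatter one; one
demographic rule (drug D01, Age > 60 → MyocardialInfarction, lift 25) is
planted so signal recovery is testable.  Under these defaults the top
symptom reaches ≈34% of cases and ≈46% of *new* cases once follow-ups
inflate the numerator, so the feasible uniform threshold used in the
series-level checks is $\theta^* = 0.6$ (per-group capacity
$\lfloor 0.6 \cdot 5 \rfloor / 5 = 0.6$); tighter thresholds (0.2/0.4)
are exercised in the infeasibility tests, where suppression is the
correct outcome.

What the generator does *not* emulate: FAERS's multi-file layout, true
duplicate reports under distinct CaseIDs, demographic drift within a
follow-up chain, missing values, or MedDRA term hierarchies.  Passing
tests therefore demonstrate the mechanism — not performance figures on
real FAERS quarters, whose scale and skew are far harsher.

## What the checks compute

The worked-example checks are exact (candidate sets, surviving CaseIDs,
the 1/3 → 1/2 → 100% confidence chain).  The series-level guarantee runs
each variant at $k{=}5$, uniform $\theta^*{=}0.6$ on a seeded 6×2,000
series and asserts zero dangerous-identity and dangerous-sensitivity
ratios under the full BFL audit, with the `ms` baseline strictly positive.
The auditor is checked against a brute-force enumeration of the attack
definitions on 200 random mini-series.  The information-loss ordering
(mean NIL of `ppms++` ≤ `ppms+` ≤ `ppms`) is asserted over 20 seeds on a
4×150-case series — at that scale one anonymization takes well under a
second, which keeps the 60-run comparison practical; the ordering is a
statement about expectations, and individual seeds do fluctuate.

## Limitations

Suppression is the only escape hatch for infeasible records (no
counterfeit-record insertion); the audit assumes the strongest adversary
(true leaf QIDs, first-appearance knowledge) and therefore overstates
weaker ones; thresholds interact with group granularity through the floor
in $\eta_s$, so a term feasible in aggregate can still be suppressed at
the margin; and nothing here addresses duplicate reports filed under
different CaseIDs, which the publishing model inherits from the source
systems.
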