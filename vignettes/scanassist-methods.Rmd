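---
title: "Methods: knowledge-based scan assistance and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-based scan assistance and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanassist)
```

## The knowledge model

Early-pregnancy ultrasound semiology is modeled as a triple store over a
small fixed vocabulary. Entities carry a kind (`sign`, `disorder`,
`echographic_view`, `anatomical_structure`, `ultrasound_route`,
`ultrasound_mode`), a SKOS preferred label, and optionally a definition and
opaque reference-image identifiers. Domain relations are `epo:has_sign`
(disorder → sign), `epo:suggests` (sign → disorder), `epo:requires_view`
(sign → view) and `epo:located_in`.

Three design choices shape the store:

* **Canonical direction with materialized inverse.** `epo:has_sign` is the
  authoritative relation; `epo:suggests` is derived (and vice versa: either
  direction in the input materializes both). There is a single source of
  truth, yet both query directions are always available, which is exactly
  the inference the reasoning pattern needs. Full description-logic
  classification is deliberately out of scope: the assistant's protocol
  derivation exercises only this one inference.
* **A minimal Turtle dialect.** Serialization uses prefix declarations,
  one subject–predicate–object statement per line, and plain string
  literals — no blank nodes, collections or datatype tags, because the
  schema needs none of them. The reader rejects undeclared prefixes,
  predicates outside the vocabulary, and literals in IRI positions, with
  line numbers. Keeping the dialect this small makes the parser fully
  testable; the round-trip `load(save(kb))` is identity on the triple set
  and is property-tested on random stores.
* **Determinism everywhere.** Triples, query results, protocol items and
  differential rows are sorted (byte order on IRIs, with documented
  tie-breaks), so every output is reproducible bit for bit.

`kb_validate()` returns integrity issues as data (never as errors): missing
labels or declarations, kind mismatches in relations, broken inverse
closure, signs with no required view, disorders with no sign. This supports
a simple curation loop where domain experts review labeled triples.

## The reasoning algorithm

From identified signs $S$ and signs assessed absent $A$:

1. $D(S) = \bigcup_{s \in S}\mathrm{suggests}(s)$ — the differential;
2. $C = \bigcup_{d \in D}\mathrm{signs}(d)$ — all signs relevant to it;
3. $P = C \setminus (S \cup A)$ — the signs still worth seeking;
4. one protocol item per view $v \notin$ completed views with
   $\mathrm{seek}(v) = \{p \in P : v \in \mathrm{views}(p)\} \neq \emptyset$.

Two orderings are artifact conventions (the underlying idea prescribes an
"ordered list" without a criterion):

* **Protocol order**: descending $|\mathrm{seek}(v)|$, ties by ascending
  view label then IRI. Most-informative-first maximizes signs assessed per
  acquisition and is reproducible.
* **Differential order**: descending support ($|\mathrm{signs}(d) \cap S|$),
  then descending completeness (support / total signs), then label. This is
  the simplest defensible evidence ordering, not a probabilistic claim.

Absent signs retire from $P$ but never from $S$-driven suggestion: presence
is an observation, absence a failed search. If the same sign is recorded
present in one image and absent in another, presence wins. This rule makes
the derived sets deterministic and lets the guidance loop terminate: each
protocol step assesses at least one pending sign, so guidance reaches empty
in at most as many iterations as there are signs.

## Scan sessions and reports

A session binds a case to a knowledge base and accumulates image
annotations (controlled keywords: view, structures, signs present/absent,
route, mode), each validated against the KB at entry. Guidance is a pure
function of the derived sets, so the session engine delegates to the
reasoner. Timestamps are caller-supplied — no wall clock is read inside the
logic — and the finalized report is an immutable value: case, operator,
mode, structured conclusion, image list in acquisition order, duration, and
whether the protocol was complete at sign-off.

The report conclusion is a structured statement — location class
(intrauterine / ectopic / pregnancy of unknown location) plus, for ectopic
conclusions, an optional precise site (`tubal`, `interstitial`, ...,
`unspecified`). The free-text criterion "precise location explicitly
stated" maps to `ectopic_site = "tubal"` etc.; `"unspecified"` records an
ectopic conclusion whose site was not stated.

## Scoring schemes

**Quality.** An image set is scored against 15 boolean criteria — five on
the sagittal uterus view (cervix, fundus, endometrial midline, endocervix
visible; uterus over half the image) and five per ovary view (side stated;
follicles, iliac vein visible; long axis under 30°; ovary over a quarter of
the image) — one point each, maximum 15. The criteria are judgments
supplied as data; the module scores, it does not analyze pixels. Views
never acquired score their items as 0 (documented choice for partial image
sets: an unassessable criterion earns no point).

**Trust.** A five-level expert judgment of whether the image set supports
the report's conclusion. Levels 1–3 imply a supervisor examination is
needed; levels 4–5 do not. The canonical level descriptions ship with the
package.

**Agreement bands.** Kappa values below 0.6 are read as poor, between 0.6
and 0.8 as moderate, above 0.8 as good. The wording is
inclusive-ambiguous at the boundaries; this package fixes moderate as the
closed interval $[0.6, 0.8]$ and tests the convention explicitly.

## Evaluation statistics

* **Outcome flags.** `correct_location` requires the definite gold class
  stated in the conclusion; a pregnancy-of-unknown-location conclusion
  commits to no location and is never a correct location diagnosis. This
  convention is forced by the published outcome accounting: with per-mode
  error totals far exceeding the false-positive + false-negative counts,
  the remaining errors can only be indeterminate conclusions, so treating
  them as correct would make the printed table internally inconsistent.
  `fn_ep` is any ectopic gold not concluded ectopic (the dangerous miss);
  `exact_diagnosis` additionally requires the matching site explicitly
  stated for ectopic golds, and for intrauterine golds coincides with
  correct location (the precision criterion only bites for ectopics, but a
  symmetric rule is needed for totals).
* **Percentages** round half away from zero to integers; this reproduces
  every printed table percentage from its printed numerator/denominator.
* **Paired t** on within-pair differences, classical formula, two-sided p
  from the t distribution; zero-variance differences are a signaled error,
  not NaN (the study summary reports NA for degenerate inputs).
* **Exact McNemar**: $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, 1/2)$ on the discordant-pair counts.
* **Cohen's weighted kappa** with linear or quadratic distance weights;
  quadratic is the default (the evaluation's weighting scheme is not
  stated, so the package exposes both).
* **Wald CI for proportion differences**, unpaired, reported in percentage
  points. This deliberately does *not* reproduce paired published
  intervals: those require the pair-level discordance table, which is not
  printed. The same applies to the published McNemar p values — the
  discordant-pair counts behind them are unpublished, so the test suite
  verifies the statistic against enumeration oracles instead of asserting
  those p values.

## The simulator

`run_study()` replays the crossover design in silico: 32 cases (18
intrauterine, 14 tubal ectopic — the published series mix), two operators,
both modes, 128 scans. What it emulates, and what it does not:

* **Case generation.** Each case fixes which signs are truly demonstrable
  in which view. Intrauterine cases always demonstrate the intrauterine
  sac; yolk sac (p = 0.8), cardiac activity (0.7) and the double decidual
  sac sign (0.6) follow typical early-pregnancy visibility; a minority
  show physiologic free fluid (0.25) or a corpus-luteum-like blob (0.15)
  that can mislead toward ectopic pregnancy. Tubal cases always show an
  empty cavity and an adnexal blob on the affected side, with bagel sign
  (0.45), separate adnexal mass (0.55), pseudogestational sac (0.25) and
  free fluid (0.6) as additional cues. These probabilities are fixed
  design choices of the generator, picked once as clinically plausible;
  no test tunes them.
* **Detection.** An operator scans the standard emergency views and
  reports each demonstrable sign with probability $p_{\mathrm{spont}}$
  (default 0.5). In assisted mode, guided keyword analysis of the entry
  uterus image and guided second looks at protocol-suggested views raise
  the per-sign detection probability to $p_{\mathrm{prompt}}$ (default
  0.95) via a conditional draw with success probability
  $q = (p_{\mathrm{prompt}} - p_{\mathrm{spont}})/(1 - p_{\mathrm{spont}})$.
  Two consequences are load-bearing: when
  $p_{\mathrm{prompt}} = p_{\mathrm{spont}}$, $q = 0$ and the assisted arm
  is distributed exactly like the nonassisted arm (null recovery holds by
  construction), and the assisted advantage grows monotonically with
  $p_{\mathrm{prompt}}$. The defaults were chosen analytically so the
  simulated trainees' error profile is of the same order as the reported
  one (missed adnexal findings dominating nonassisted false negatives;
  assisted false negatives rare). The assistant in the simulation only
  declares a sign absent once every view that could demonstrate it has
  been examined — side-specific signs must not be retired after checking a
  single side.
* **Conclusions.** Simulated operators report the top differential
  disorder when it is unique with support ≥ 1; ties and empty evidence
  yield pregnancy of unknown location (deterministic and conservative,
  mirroring how uncertainty is reported clinically). An ectopic conclusion
  states the precise site only with support ≥ 2.
* **Covariates.** Quality scores are binomial over the 15 items (per-mode
  success probabilities 0.83/0.68, matching the reported means of 12.5 and
  10.2 of 15); trust levels are drawn from per-mode distributions with
  means 4.12/3.42; durations follow a base + per-image + per-import +
  per-step cost model. These are configurable convenience distributions —
  the simulator does not model the expert judgment process, and no
  headline quantity depends on simulated time.
* **Randomness.** Every scan draws from its own stream keyed by (seed,
  case, operator, mode), so record sets are byte-identical across runs and
  insertion order is irrelevant.

What passing the simulator's tests shows is that the *pipeline* — guidance
loop, conclusion rule, outcome classification, summary statistics —
behaves correctly under controlled conditions (null recovery, monotone
effect recovery, perfect-detection limit). It does not validate the
demonstration semiology clinically, and real operators are not two-point
Bernoulli detectors: transfer of simulated effect sizes to real scanning
is explicitly not claimed.

## Fixtures and transcriptions

The published evaluation fixes per-mode outcome counts (52/39 correct
location, 49/30 exact, 1/8 false negatives with case attribution, 3/3
false positives of 64 scans per mode) but not the full 128-row record
table. `table2_records()` completes it deterministically: the
false-negative scans land on the published cases and operators; which
correct ectopic scans state the precise site, which intrauterine scans are
false positives or indeterminate, and all continuous covariates are
synthetic completions, flagged as such. `summarize_study()` on this
expansion reproduces the transcribed counts exactly — a self-consistency
check between the classifier, the summary code and the printed table.

Problem sizes used by the test suite were chosen to keep the full run in
minutes on one CPU: 100 random knowledge bases (≤ ~100 triples) for the
oracle-equivalence and round-trip properties, exhaustive enumeration for
the McNemar identity (all discordant totals ≤ 20) and the quality-score
check (all 32 uterus patterns), 120 seeded study replicates for the
sign-test of null recovery and 4 × 30 for monotone effect recovery.

## Known limitations

* The production semiology of a deployed assistant (hundreds of curated,
  expert-validated signs with reference images) is not published; the
  bundled knowledge base is an illustrative stand-in.
* No OWL reasoning beyond the materialized inverse; no SPARQL endpoint.
* The Wald interval is unpaired by design; paired intervals and the
  published p values need unpublished pair-level data.
* Color-Doppler semiology, image rendering and simulator-device
  integration are out of scope.
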