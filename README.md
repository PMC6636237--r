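# scanassist

Ontology-based scan assistance and evaluation for early pregnancy
transvaginal ultrasound (TVS).

## The problem

Ectopic pregnancy (EP) is implanted outside the endometrial cavity (about
95% of EPs are tubal) and delayed diagnosis is the leading factor in
EP-related maternal death. Experts can usually locate a pregnancy at the
first transvaginal scan; the trainees and sonographers who actually perform
first-line emergency scans often cannot. An intelligent scan assistant
attacks this gap with knowledge engineering rather than black-box learning:
ultrasound semiology (signs, disorders, echographic views) lives in a
curated triple store, and the system derives — live, during the scan — a
*personalized imaging protocol*: which views to acquire next and which
signs to look for in them, given what has already been seen. Every step of
the computation is auditable and human-readable.

`scanassist` is a self-contained implementation of that core for R users:
the knowledge base model and its Turtle serialization, the reasoning
algorithm, the scan-session workflow with structured reporting, the image
quality and report trust scoring schemes, the statistical battery used to
evaluate such a system in a paired crossover study, and a seeded simulator
of the full 2-operator × 32-case × 2-mode evaluation design. It is aimed at
researchers in clinical decision support and medical knowledge engineering
who want an executable, testable model of the approach.

## The core algorithm

The knowledge base is a set of RDF-style triples over a fixed vocabulary:
`epo:has_sign` (disorder → sign; its inverse `epo:suggests` is materialized
automatically), `epo:requires_view` (sign → echographic view),
`skos:prefLabel`, and friends. When the set *S* of identified signs
changes, the reasoner computes:

1. **Differential** — `D = ⋃ {d : s suggests d, s ∈ S}`, ranked by support
   `|signs(d) ∩ S|`;
2. **Candidate signs** — `⋃ {signs(d) : d ∈ D}`;
3. **Pending signs** — `P = candidates − S − A` (signs assessed absent, A,
   are retired);
4. **Protocol** — one item per not-yet-acquired view required by some sign
   in *P*, carrying the signs to seek there, ordered
   most-informative-first (views covering the most pending signs).

The loop "acquire the top view, annotate findings, recompute" strictly
shrinks *P* and terminates.

## Worked example

```r
library(scanassist)

kb <- demo_kb()                       # illustrative early-pregnancy semiology
s  <- new_session(kb, "case_21")      # clinical info defaults to the standard
                                      # "moderate pelvic pain and positive
                                      # pregnancy test"
add_image(s, image_annotation("img1", "epo:uterus_sagittal_view",
                              signs_present = "epo:empty_uterine_cavity"))
next_guidance(s)
#> <imaging_protocol> 3 view(s) to acquire
#>   1. left adnexal view  [seek: epo:adnexal_blob_sign, epo:adnexal_mass_separate_from_ovary, epo:bagel_sign, epo:empty_adnexa]
#>   2. right adnexal view  [seek: epo:adnexal_blob_sign, epo:adnexal_mass_separate_from_ovary, epo:bagel_sign, epo:empty_adnexa]
#>   3. view of the pouch of Douglas  [seek: epo:free_fluid_pouch_of_douglas]
```

An empty uterine cavity alone cannot separate an ectopic pregnancy from a
pregnancy of unknown location, so the protocol sends the operator to the
adnexa. Following it:

```r
add_image(s, image_annotation("img2", "epo:left_adnexal_view",
          signs_present = c("epo:adnexal_blob_sign", "epo:bagel_sign")))
differential(kb, identified_signs(s))[, c("label", "support", "total_signs")]
#>                           label support total_signs
#> 1       tubal ectopic pregnancy       3           6
#> 2 pregnancy of unknown location       1           2

rep <- finalize_session(s, "trainee_1", "assisted",
                        conclusion_from_signs(kb, identified_signs(s)), 14.5)
rep
#> <scan_report> case case_21, operator trainee_1, assisted mode
#>   conclusion: ectopic (tubal)
#>   images: 2, duration: 14.5 min, protocol complete: FALSE
```

The evaluation layer reproduces the crossover-study analysis. On the
bundled per-scan expansion of the published outcome tables:

```r
summarize_study(table2_records())$table2[1:2, c("outcome", "n_assisted",
                                                "pct_assisted",
                                                "n_nonassisted",
                                                "pct_nonassisted")]
#>                                           outcome n_assisted pct_assisted n_nonassisted pct_nonassisted
#> 1 Correct pregnancy location (ectopic/nonectopic)         52           81            39              61
#> 2 Exact diagnosis (with precise ectopic location)         49           77            30              47
```

and a fully simulated study (128 scans; seeded, reproducible):

```r
summarize_study(run_study(study_design(seed = 42)))
#> Study summary (64 scans per mode)
#> ...
#>   Correct pregnancy location (ectopic/nonectopic)  64 (100%) vs 51 (80%)  p = 0.000244
```

A thin command-line wrapper covers the same operations
(`validate-kb`, `protocol`, `session`, `score-quality`, `simulate-study`,
`evaluate`); see `system.file("scripts", "scanassist", package = "scanassist")`.

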