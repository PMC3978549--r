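---
title: "Mining stroke narratives from weblogs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining stroke narratives from weblogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokestory)
```

## The problem

Hospital-based research on cerebral stroke reports sex differences in
symptom presentation: women more often experience *nontraditional*
symptoms — mental status change, pain other than headache, headache,
lightheadedness, other neurologic and nonneurologic complaints — while
*traditional* symptoms are focal neurological signs (hemiparesis,
impaired speech or comprehension, visual disturbance, ataxia, vertigo,
imbalance). Nontraditional presentations can delay the decision to seek
care and complicate diagnosis. Weblog narratives are an alternative data
source for such questions: patients and their relatives tell stroke
stories in public blogs, which can be retrieved, coded, and analysed
like interview transcripts — at the price of a severe retrieval problem
(a few hundred relevant narratives in millions of posts) and fragmentary
reporting (age, stroke type and delays are often omitted).

`strokestory` packages that study design as a reproducible, testable
pipeline. Because the original blog crawl is not redistributable, the
package pairs the pipeline with a synthetic corpus generator that
emulates the statistical structure of the narratives the design targets,
and with a fixture of the published count tables so that every printed
percentage and test statistic can be recomputed from counts alone.

## Pipeline overview

1. **Simulate** (`generate_corpus`) — a seeded corpus of planted stroke
   narratives with gold codes, plus distractors.
2. **Filter** (`noise_filter` / `train_story_classifier`) — the
   personal-story classifier that gates posts into the index.
3. **Retrieve** (`build_index`, `run_feedback_session`) — prototype-story
   query, cosine ranking, Rocchio relevance feedback with
   relevant/irrelevant/skip judgments.
4. **Code** (`auto_code`, `validate_story`, `percent_agreement`) — the
   symptom coding scheme applied to retrieved stories.
5. **Analyse** (`crosstab`, `pearson_chi2`, `fit_logistic`,
   `reproduce_tables`) — contingency and regression analysis.

`run_pipeline()` chains the stages under one root seed and writes a
manifest of output checksums; identical configurations reproduce
identical checksums.

## The synthetic corpus: what it emulates, and what it does not

The generator's defaults encode the observed study margins:

* narrator: 97/191 first person;
* patient sex: 91/174 female among symptom-reporting stories;
* stroke type: 67 ischemic, 29 hemorrhagic, remainder undiagnosed;
* per-sex symptom prevalences at the reported rates (e.g. impaired
  speech or comprehension 59/91 for women, 47/83 for men; see
  `prevalence_defaults()`), with hemiparesis carried as body and face
  flags whose marginal rates count the "both" presentations in each;
* age reported in roughly half the stories, drawn from the seven-band
  distribution; assistance sought in 96% of stories, delay rates of
  35/80 (women) and 24/76 (men), immediate treatment 90%;
* post dates uniform over 2010--2011 (semantically inert).

Two generation modes exist because different tests need different
guarantees: `exact_margins` reproduces the configured narrator, sex and
stroke-type counts with zero error (margins that cannot be hit exactly,
such as an odd total with a 0.5 fraction, are resolved by the
largest-remainder rule in `largest_remainder()` — floors first, then
remaining units to the largest fractional parts, ties in category
order); `sampled` draws them as categorical samples so that recovery
tests see real binomial noise.

Known simplifications, stated rather than hidden:

* **Symptom flags are independent Bernoulli draws per symptom.** Only
  marginal rates are published; the joint distribution (symptom
  co-occurrence, age×sex×narrator dependence) is unknown and is *not*
  modelled. Consequently the generated hemiparesis-any rate is the
  independence composition of the body and face rates, not the
  published any-hemiparesis marginal.
* **Surface text is templated.** Every gold-flagged symptom contributes
  at least one phrase from that symptom's closed lexicon; narrator,
  patient sex and stroke type are realised as deterministic surface
  markers. Real narratives are unboundedly variable; passing round-trip
  tests therefore demonstrate internal consistency of the
  generate→render→code loop, not clinical NLP performance on real text.
* **The distractor mix is designed to make retrieval non-trivial.**
  Besides non-medical personal stories (travel, sports, work) and
  non-story pages, the generator plants two stroke-adjacent classes: a
  non-stroke emergency-room story and stroke-awareness posts that quote
  warning-sign and call-911 advice. In the original study most
  fully-judged retrieved stories were irrelevant, so a realistic
  benchmark must contain posts that collide with the prototype's
  vocabulary without being stroke-experience narratives. Without them,
  the first result page is already perfect and relevance feedback has
  nothing to demonstrate.
* **Symptoms are only planted within the coded window** (onset until
  medical assistance is secured): the generator emits no post-arrival
  symptoms, so the window rule of the code book is enforced at
  generation time rather than parsed from text.

## Retrieval

The index is a bespoke inverted file: documents are tf-idf vectors with
weights `w = (1 + ln tf) · ln(N/df)`, L2-normalised; terms occurring in
every document get idf 0 and are dropped. The tokenizer lowercases,
splits on non-alphanumerics, keeps tokens of length ≥ 2 and all-digit
tokens of length ≥ 3 (so "911" survives); no stemming or stopword
removal — idf already down-weights ubiquitous words, and the scheme
stays exactly reconstructible in tests. The contract here is ranked
retrieval, not a specific engine, so a dependency-light index that can
be verified against brute-force cosine enumeration was preferred over an
external search platform.

Feedback uses the Rocchio update
`q' = α·q₀ + (β/|R|)ΣR − (γ/|I|)ΣI` with the classical SMART defaults
α = 1, β = 0.75, γ = 0.15 (all configurable — the original system does
not publish its weights). Negative weights are clipped to zero and the
query re-normalised, preserving the sparse-vector invariant. Ties in
cosine score break by ascending document id for reproducibility. Judged
documents — including skipped ones — are excluded from later result
pages, matching the queue semantics of the original tool; skipped
documents contribute nothing to the update. Each round logs
precision-at-batch (default batch 10; the benchmark uses 20, a
plausible result-page size).

## The story filter

The upstream system classified posts as personal stories with a stated
precision of 0.66 and recall of 0.5. That classifier (from cited prior
work) is not reproducible here, so the package treats the *operating
point* as the contract: `noise_filter()` selects
`TP = round(recall × #stories)` true stories and
`FP = round(TP·(1−precision)/precision)` non-stories uniformly at
random. Deriving FP from precision and TP — rather than flipping each
post independently — makes the calibration exact at any corpus size, up
to integer rounding. A trainable multinomial naive-Bayes baseline
(`train_story_classifier`) sits behind the same interface for users who
want an actual classifier; empty or out-of-vocabulary text defaults to
non-story.

## The coding scheme

The code book is a typed schema (`coded_schema()`): narrator
(first/third), witness and relation (third person only), patient sex
(mandatory — stories without it were excluded from the original
analysis and are flagged, not dropped, here), age in years and/or band,
thirteen dichotomous symptoms, stroke type, and the
assistance/delay/treatment fields. The taxonomy is closed: 7 traditional
keys (hemiparesis split into body and face flags; "both body and face"
sets both) and 6 nontraditional keys. Mental status change is singled
out in the analyses because it is an internal state, hypothesised to be
more reportable by the patient than by a third-person narrator.

Coder agreement is *raw percent agreement over (story, field) cells*,
with missing-equals-missing counted as agreement — the metric the
original coding workflow reported. Whether that figure was per-field or
per-story is not documented; per-field is computed here and stated.
Cohen's kappa per field is available as a clearly-labelled extra, not a
replacement. The lexicon auto-coder inverts the generator's phrase
pools (a flag is set iff a lexicon phrase occurs) and exists to close
the generate→render→code loop in tests; it makes no claim on real text.

## Statistics and numerical choices

* Pearson chi-square uses `Σ(O−E)²/E` with `E = (row·col)/N` and **no
  continuity correction** — verified necessary to reproduce the
  published .056/.002/.008/.01/.12 values from their printed counts.
  Expected counts below 5 (several sparse cells of the stroke-type
  table) produce a warning, not a silent switch to an exact test,
  because the published analysis used chi-square throughout.
* p-values are rendered in both 2- and 3-decimal publication style
  (".01" vs ".056") because the published tables mix precisions.
* Logistic fits use binomial IRLS (`stats::glm.fit`, deviance tolerance
  1e-10, max 50 iterations) and report Wald (per coefficient),
  likelihood-ratio and Rao score tests (model vs intercept-only). The
  score test is computed directly from the null-model score and
  information, and equals the Pearson chi-square on any 2×2 table — a
  property the tests verify to 1e-10. Fits with any |coefficient| > 15
  are flagged non-converged (complete separation) rather than returned
  silently. The published regressions may have included covariates
  beyond the reported factor; that is unstated, so the single-factor
  model is fitted and all three tests reported.
* Two published p-values are **documented as irreproducible**: .006
  (≥1 nontraditional symptom excluding mental status change, first- vs
  third-person) and .001 (≥1 nontraditional symptom, hemorrhagic vs
  ischemic). From the printed counts (41/92 vs 21/82; 23/29 vs 36/67),
  Pearson, likelihood-ratio and Wald tests all give ≈.009 and ≈.018.
  `reproduce_tables()` reports the recomputed values with a
  `reproduces_printed = FALSE` flag; nothing in the package is tuned to
  match the printed figures.
* Two further printed inconsistencies are taken as printed and noted:
  one table prints "46 (51.5)" where 46/91 is 50.5%, and the
  nontraditional-symptom table heads its male column n=82 while the
  surrounding text uses n=83.
* Percentages round halves away from zero to one decimal (27/48 →
  56.3), matching publication style rather than IEEE half-even.
* The fixture asset stores the published tables *as tables* with an
  integrity checksum; `expand_table_records()` materialises records
  consistent with any single table. Joint consistency across tables
  cannot be recovered from marginals and is not claimed.

## Problem sizes and benchmark conventions

The standard retrieval benchmark is a 2000-post corpus with 200 planted
stroke stories, batch 20, 3 rounds, averaged over 20 seeds — large
enough for stable precision estimates, small enough that the whole
suite runs in well under a minute of retrieval work. Calibration checks
use a 1000-story corpus; prevalence-recovery checks use 2000 profiles
per sex (each symptom within 3 binomial standard errors of its
configured rate); the auto-coder round trip uses 500 planted stories
with a ≥99% flag-accuracy requirement. All randomness flows through
explicit integer seeds (`with_seed()`), and stage-local seeds derive
from the root seed at fixed offsets.

## Limitations

The generator calibrates margins, not joint structure; the auto-coder
and classifier exploit the generator's own regularities; retrieval
behaviour on templated text is cleaner than on real blogs (the
benchmark's feedback curve — imperfect first page, near-perfect later
rounds — demonstrates the mechanism, not field performance). Real-data
features deliberately out of scope: language identification, spam and
duplicate posts, access-restricted blogs (the skip category of the
judgment loop is the hook where those would surface), and any modelling
of blogger demographics beyond the configured margins.
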