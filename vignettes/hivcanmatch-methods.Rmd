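---
title: "Methods: record linkage and cross-province cancer-diagnosis flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: record linkage and cross-province cancer-diagnosis flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

South African public-sector laboratories record HIV diagnostic and care
events (CD4 counts and percentages, rapid tests, qualitative PCR,
antibody/antigen tests) for most of the population, and the national
pathology-based cancer registry records microscopically verified cancer
diagnoses (histology, cytology, bone marrow). Neither source carries a
stable person identifier or a residential address. Two questions follow:

1. **Entity resolution.** Which laboratory records belong to the same
   person, and which person links to which pathology report?
2. **Access geography.** Taking the province where a person received
   their HIV care as a residence proxy, where did they obtain their
   cancer diagnosis? The 9 x 9 cross-tabulation (an origin-destination
   matrix) quantifies cross-province flows for cancer diagnostic
   services among people living with HIV (PLHIV).

The restricted source data cannot be redistributed, so the package is
organised around a synthetic-data generator with known ground truth:
every downstream stage — standardization, blocking, supervised pair
classification, deduplication, cohort filters, tables — is exercised and
measured against that truth, and the printed study tables ship as
cell-count fixtures whose derived totals and percentages the table code
reproduces exactly.

## Pipeline

`run_pipeline()` chains the stages under one seed:

```{r}
library(hivcanmatch)
run <- run_pipeline(sim_config(n_entities = 5000, seed = 1), out_dir = "out")
```

1. **simulate** — draw a population and emit corrupted HIV and cancer
   records plus a truth table;
2. **standardize** — canonical names, Soundex codes, birth years,
   blocking keys;
3. **link** — comparison vectors on blocked candidate pairs, a linear
   maximum-margin classifier, union-find deduplication, cancer-to-cluster
   linkage;
4. **cohort** — eligibility filters and one analysis row per person;
5. **tables** — origin-destination matrix with column percentages,
   demographics, chi-square tests, logistic odds ratios, GeoJSON flows.

## The synthetic generator

The generator emulates the *structure* of the source data, not its
content. Defaults are fixed study conditions chosen once:

* **Population margins.** Female fraction 0.709; race weights 0.896 /
  0.050 / 0.048 / 0.006 (Black / Coloured / White / Asian); age at the
  window midpoint log-normal with median 40 years and `sdlog = 0.28`
  (interquartile range about 33–48). These follow the printed
  demographics of the study population, so synthetic cohorts resemble
  the published one at the margins.
* **Provinces and mobility.** Home-province weights and the default
  mobility matrix (row = home province, column = diagnosis province) are
  the column-normalised packaged origin-destination counts, i.e. the
  generative analogue of the printed flow table.
* **Care-seeking.** Visits per person = 1 + Poisson(2); each visit
  yields one or two test records sharing a date, facility and episode
  number; 5% of visits occur at a facility outside the home province
  (so modal home-province logic is genuinely exercised); HIV result
  labels positive/negative/unknown at 0.7 / 0.2 / 0.1.
* **Cancer.** A configurable fraction of persons (default 0.15) receive
  a pathology report; 10% of cases get a second, later report (so
  incident-report selection is exercised); 2% of reports lack the
  diagnosis province; basis histology/cytology/bone-marrow at
  0.85 / 0.12 / 0.03.
* **Corruption.** Per name field: one typographic edit with probability
  0.05 (substitution 0.4, transposition 0.3, deletion 0.15, insertion
  0.15); nickname swap 0.02; date-of-birth day/month perturbation 0.02;
  date of birth missing 0.02; episode/folder number missing 0.10. The
  real identifier noise is unobservable from the published record, so
  these rates are asserted as plausible registry noise, not estimated.
* **Names.** The packaged banks are 520 first names and 520 surnames
  (synthetic, Southern-African-flavoured composition; see the file names
  `synthetic_*`) sampled with Zipf-type rank weights (`rank^-0.7`), so
  name frequencies are heavy-tailed the way real surname distributions
  are. Heavy tails matter: they create the "name twin" collisions that
  make classification hard.
* **Identity uniqueness.** Entities are redrawn until the
  (first name, surname, date of birth) tuple is unique, *and* until no
  two entities share a date of birth with both name similarities at or
  above Jaro–Winkler 0.85. Exact collisions produce comparison vectors
  that are identical for distinct persons; near-name collisions with a
  shared birth date (a SANDILE vs ANDILE with one date of birth) differ
  by a few hundredths in a single bounded feature, which a soft-margin
  linear classifier will never buy a separating plane for. Either way
  the uncorrupted world would not be exactly recoverable, and exact
  recovery of the truth partition in the zero-corruption run is the
  contract the deduplication oracle tests rely on. Realistic ambiguity
  re-enters through the corruption model. Passing tests therefore bound
  what noise does to linkage — they do not certify performance on real
  data, where true identity twins, family co-residence and non-random
  missingness exist.

Records carry sex and race as uncorrupted pass-through demographics:
the cohort and regression stages need them, and the linkage stage never
uses them.

## Standardization and blocking

Names are upper-cased, diacritics folded to ASCII, punctuation removed
and whitespace collapsed (`normalize_name()`, idempotent); surnames get
classic four-character Soundex codes. A record's blocking keys are

* Soundex(surname) + birth year,
* first two letters of the first name + birth year,
* the episode number, when present,

and a pair is compared iff the key sets intersect. The union-of-keys
design means one corrupted field cannot sever a true pair. Birth year
comes from the date of birth when present, else from the recorded age
and the event year; an age-derived year is interval-censored by the
unknown birthday (it is one of two consecutive years), so both
candidate years contribute keys — without this, records lacking a date
of birth lose both year-based keys about half the time, and measured
blocking recall drops below the 99% the pipeline maintains on default
synthetic data.

## Comparison vectors and the match classifier

Each candidate pair yields six bounded features: Jaro–Winkler similarity
of first names and surnames (prefix weight 0.1, maximum prefix 4 — the
standard name comparator in record linkage), birth-year agreement
`1 - min(|dy|, 5)/5`, exact date-of-birth equality, and episode- and
folder-number equality. Missing episode/folder numbers encode as 0.5:
absence of an administrative key is not evidence against a match. A
missing date of birth scores 0 on the exact-equality feature; the
birth-year feature (encoded 0.5 when unknown on either side) carries the
age signal.

The classifier is a linear support-vector machine (C-classification,
cost 10, no rescaling — features are already in `[0, 1]`), reduced after
fitting to an explicit weight vector and bias so that scoring is one
matrix product and the model serialises to JSON. Non-match errors are
weighted double: the class-balanced training sample overstates the
match prior of the blocked pair space by more than an order of
magnitude, and a false merge propagates through transitive closure
while a missed pair is usually rescued by it, so the margin is placed
conservatively. Pairs at or above the margin zero-point are matches;
the threshold is overridable for precision/recall trade-offs.

**Training-set construction** matters more than the fitting algorithm.
A class-balanced random sample almost never contains the two collision
classes that dominate the error budget at scale:

* *name twins* — distinct persons sharing (nearly) the same name and
  birth year; frequent under heavy-tailed names;
* *identifier twins* — distinct persons with coinciding dates of birth
  inside a block (roughly one blocked pair in 365).

With either class absent from training, the maximum-margin solution
happily pays for it: the boundary collapses onto "names suffice" or
"date of birth suffices", and transitive closure then chains tens of
thousands of false pairs. The sampler therefore draws half of the
negatives as hard negatives, split between the two collision classes by
ranking blocked non-matches on name similarity and on identifier
agreement; the other half is uniform. Training also mixes in labelled
cancer–HIV pairs (half the HIV budget): cross-set pairs systematically
lack shared facility identifiers, and a model trained only on within-HIV
duplicates under-scores them.

## Deduplication and linkage

Match decisions form a graph; clusters are its connected components
(union-find with path halving; a brute-force traversal serves as the
independent oracle in tests). Transitive closure merges clusters even
when an individual in-cluster pair was classified non-match — standard
deduplication practice, documented because it inflates clusters under
high noise. Every cancer record links to at most one cluster: the
highest best-pair score among clusters with a matching pair, ties to the
smaller cluster id.

## Cohort filters

Starting from clusters linked to at least one cancer record, in order:

1. drop clusters with no HIV-positive record;
2. select the incident (earliest; ties by smallest record id) pathology
   report and drop clusters whose first positive HIV date is after it —
   **same-day dates are retained**: of the two published phrasings
   ("earlier than" vs dropping cases "prior to"), the package follows
   the results-side reading that only strictly earlier cancers are
   excluded, and records the ambiguity here;
3. drop clusters whose incident report lacks a diagnosis province.

The attrition log counts each step and is conserved:
`input - sum(drops) = cases`. Home province is the modal province of the
positive HIV records (ties: earliest record's province, then
alphabetical). Age at diagnosis is `floor()` of years between date of
birth and diagnosis, falling back to the recorded age at the nearest HIV
test.

## Tables and models

The origin-destination matrix is laid out as printed: rows = province of
cancer diagnosis, columns = province of HIV care, with **column**
percentages (cell over column cell-sum). All totals are recomputed from
cells because two printed marginal totals are internally inconsistent
with their own cells (the NW and NC column totals are swapped relative
to the cell sums, and one row total differs by 2); the printed *cell*
percentages are consistent with cell sums, which fixes the convention.
Percentages round half away from zero to one decimal — the rule that
reproduces every internally consistent printed percentage exactly. One
derived share cannot be reconciled: the text's "60.7% travelling to
Gauteng" is 9,978 / 16,225 = 61.5% from the printed cells; the package
reports the computed value and flags the discrepancy rather than
resolving it.

Chi-square tests are Pearson `sum((O - E)^2 / E)` without continuity
correction (zero expected counts are an error). The logistic model
regresses the out-of-province indicator on age (continuous, years),
gender (reference Female), Black vs non-Black (reference non-Black) and
cancer type (reference cervix, the most common type); odds ratios are
exponentiated coefficients with Wald 95% intervals. Cancer types with
fewer than 20 cases or an empty outcome cell are pooled into "other"
before fitting — sparse levels would otherwise separate the likelihood;
remaining separation is raised as an error, not silently smoothed. The
out-of-province direction is fixed as outcome = 1 (the published odds
ratios read against their surrounding prose under this coding; the
package states the coding explicitly and leaves the interpretation to
the reader). Flow export emits one record per positive off-diagonal
cell with approximate province-centroid coordinates, as GeoJSON
LineStrings; choropleth rendering is out of scope.

## Calibration experiments and problem sizes

The package's standing experiments (run by `scripts/acceptance.R` and
the acceptance tests) use sizes chosen to make binomial error bars
informative while keeping a single-CPU run in minutes:

* **Linkage quality**: 50,000 entities (about 195,000 HIV records,
  roughly 20 million blocked pairs), default corruption; pairwise and
  link precision/recall against truth, and held-out pair F1. The
  zero-corruption twin run must recover truth exactly.
* **Mobility recovery**: 40,000 entities, every person a cancer case,
  mobility with uniform 0.25 off-diagonal mass, and **no away-from-home
  HIV visits**. The last condition isolates the estimand: the modal
  home-province proxy misclassifies a few percent of persons when a
  minority of visits happen out of province, which biases the recovered
  out-of-province proportion upward by about two percentage points —
  far outside the three-binomial-standard-error band at twenty thousand
  cases. That bias is a property of the residence proxy (worth knowing
  in itself), not of the mobility propagation being calibrated, so the
  calibration run removes its source; the default configuration keeps
  exercising the modal logic.
* **Interval coverage**: 100 replicates of n = 20,000 cases with a true
  odds ratio of 2 for maleness; Wald 95% intervals must cover in at
  least 93.
* **Oracle agreement**: chi-square vs the direct formula (1e-9),
  one-covariate odds ratio vs ad/bc (1e-6), union-find vs brute-force
  components, 100 random instances each.
* **Determinism**: two end-to-end 5,000-entity runs must produce
  byte-identical `cases.csv`.

## Known limitations

* The residence proxy (province of HIV care) conflates migration for
  work or education with referral for care; the generator does not model
  either.
* No test-volume seasonality, facility catchment geography, or HIV
  incidence dynamics; dates are uniform in the 2004–2014 window.
* The corruption model is asserted, not estimated; real identifier
  noise is unknown.
* Transitive-closure clustering can chain distinct persons under heavy
  noise; the classifier threshold trades this against recall.
* Cohort-level published numbers (case counts, adjusted odds ratios)
  require the restricted source data and are deliberately not
  reproduction targets; the regression stage is validated by closed-form
  and recovery oracles instead.
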