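---
title: "Methods: line-of-therapy assignment and prescribing-variation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-of-therapy assignment and prescribing-variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxlines)
library(dplyr)
```

# The problem

Non-insulin antidiabetic prescribing (BNF paragraph 6.1.2) in English
primary care spans six drug classes — metformin, sulphonylureas,
thiazolidinediones (TZDs), DPP-4 inhibitors (gliptins), GLP-1 analogues and
SGLT-2 inhibitors — whose relative use has shifted rapidly while guidance on
the choice of therapy after metformin remains permissive. `rxlines`
implements the analysis machinery needed to study that shift from three
complementary kinds of data:

1. **Patient-level event tables** (CPRD-like prescription, clinical and
   demographic records), from which a type 2 diabetes cohort is ascertained
   and each patient's *line of therapy* — the order in which drug classes
   were first started — is reconstructed.
2. **National annual dispensing tables** (PCA-like; items and net
   ingredient cost per chemical per year), normalised to inflation-corrected
   rates per person with type 2 diabetes.
3. **Monthly practice-level prescribing tables** (NHS-Digital-dialect CSVs)
   plus practice metadata, aggregated to CCG level for geographic-variation
   summaries, decile time series and a lowest-decile potential-savings
   estimate.

Real versions of the first dataset are access-controlled, so the package
ships first-class synthetic generators with known ground truth; every
pipeline stage is validated by recovering what the generators planted.

# Drug classification

Chemicals map to classes through an editable CSV
(`chemical,class,synonym_of`); `classify_chemical()` matches case- and
whitespace-insensitively first, then after stripping punctuation and
salt/hydrate suffixes ("hydrochloride", "maleate", ...). The cascade is
deterministic by design — no fuzzy string distance — so the same input
always classifies the same way; names that fall through are reported as
unresolved, never silently guessed. The class vocabulary is closed: the six
classes above plus `"other"`, which absorbs the remaining 6.1.2 agents
(acarbose, meglitinides, guar gum) and any mixture of two non-metformin
classes.

Combination products follow two dataset-specific conventions
(`resolve_combination()`):

* **patient-level** mode credits a metformin + X product to *both* classes
  (a first-ever combination opens both the metformin and the X histories);
* **aggregated** mode credits it to the non-metformin class only, matching
  how national and practice-level item counts are conventionally reported.

Products with more than two active constituents are rejected; none exist in
this market.

# Cohort ascertainment

`ascertain_cohort()` assigns each patient a diagnosis date — the earliest
of first non-insulin antidiabetic prescription, first HbA1c strictly above
47.5 mmol/mol (6.5%), or first diabetes diagnostic code — and then excludes:

* patients with codes for other forms of diabetes, or for polycystic ovary
  syndrome (metformin is used off-label there);
* patients with no qualifying diabetes evidence at all;
* type 1-like presentations: age at diagnosis under 35, or insulin within
  12 months of diagnosis.

Decisions that were genuinely open and how we fixed them:

* **Age granularity.** Age at diagnosis is `diagnosis year − birth year`;
  de-identified records carry birth year only, and the 35-year rule is not
  sensitive to sub-year precision at cohort scale.
* **Insulin window boundary.** "Within 12 months" is implemented as
  `insulin date ≤ diagnosis date + 365 days`, boundary inclusive. Boundary
  cases are rare; inclusivity errs toward excluding uncertain type 1.
* **Exclusion reporting order.** When several exclusions hold, the reason
  reported follows a fixed priority (other-diabetes code, PCOS, no
  evidence, age, early insulin). This is a reporting convention only;
  included/excluded status is unaffected.
* **Roster.** The demographics table defines the patient universe; it is a
  third input CSV alongside prescriptions and clinical events because the
  age rule requires birth year.

# Therapy lines and episodes

A *new start* is the first-ever prescription of a drug in each class for a
patient, even if prescribed only once; each new start takes the next line
of therapy (1–4), regardless of concomitant treatment, and starts beyond
the fourth are dropped. Starts on or after the patient's first insulin
prescription are censored. Same-date starts — routine, because combination
products open two classes at once — are broken deterministically: metformin
first, then alphabetical class order.

Treatment *episodes* implement the stop rule: a gap of at least 6 months
between consecutive issues of one class closes the episode at the last
issue. "6 months" is fixed at 183 days, measured between issue dates (no
duration or quantity modelling; the data carry issue dates only). Restarts
after a stop do **not** create new line events — lines are keyed to
first-ever starts — but episodes are computed and exposed for inspection
because the stop rule is part of the method.

`line_share_table()` bins line events by the calendar year of their start
date and reports, per (year, line), each class's percentage of new
prescriptions; populated cells sum to 100 exactly and empty cells are
absent rather than zero.

# National trends

The trend stage composes five small, separately-tested operations:

* `per_capita()`: items (or cost) ÷ mid-year population × 1000;
* `inflation_adjust()`: nominal × index(base year)/index(year); the CPI
  table is an *input* (which index series to use is the analyst's choice),
  with base year 2016 by default;
* `extrapolate_prevalence()`: ordinary least squares of prevalence on
  year, extending an observed window (e.g. 2000–2013) over the full
  analysis span; the fit's R² is attached so its quality is visible;
* `per_patient()`: rate per 1000 ÷ (prevalence% × 10) — i.e. per person
  with type 2 diabetes;
* `percent_change()`: rounded half away from zero for display, unrounded
  value attached.

Two denominators coexist deliberately and are never mixed: national
per-patient figures use a *type 2* prevalence series; the geographic module
uses practice-reported QOF prevalence, which covers *all* diabetes in
adults. Likewise costs: national tables carry net ingredient cost (NIC),
practice-level tables carry actual cost; the fields are kept distinct and
no conversion between them exists in the package.

# Geographic variation

Practice-level rows are filtered to standard active general practices
(setting code 4; closed and dormant practices removed), with removal counts
logged per reason. Each CCG's patient denominator is its registered
population aged ≥ 15 multiplied by its list-size-weighted mean QOF
prevalence. `ccg_summary()` aggregates the latest 12 months to one row per
CCG: class shares of items (aggregated combination convention), items and
actual cost per estimated patient. `distribution_stats()` reports the
Table-1-style summary per measure: mean, sample SD (n − 1),
linear-interpolation quartiles (R type 7, the numpy/pandas default), IQR,
and excess kurtosis by the plain moment formula m₄/m₂² − 3 (0 for a normal
distribution; undefined and reported `NA` for constant input).
`decile_series()` gives the 10th–90th percentiles of practice-level share
per month, skipping months with fewer than 10 practices.

`savings_at_decile()` takes the **unweighted** 10th percentile of CCG cost
per patient as the benchmark; each CCG above it contributes
(cost − benchmark) × patients, and CCGs below it are floored at zero. The
unweighted, floored definition is one consistent reading of a
"prescribe-at-the-lowest-decile" counterfactual; both choices (no patient
weighting in the benchmark; no negative savings) are deliberate and
recorded in the output metadata alongside the percentile convention.

# Synthetic data: what is emulated, what is not

## Patient-level generator

`simulate_cohort()` plants, per prescribing *era* (1998–2006, 2007–2012,
2013–2016 by default) and therapy line, a class-probability row. The
default rows trace the era story a prescriber would recognise:
sulphonylurea/TZD-dominated second line early on, gliptins arriving in the
middle era, and a recent era whose second-line row is DPP-4 0.43,
sulphonylurea 0.34, SGLT-2 0.14, remainder 0.09, with SGLT-2 dominating
fourth line. Other defaults: diagnosis years ramp mildly upward over
1998–2016; age at diagnosis ~N(62, 11) truncated to [36, 90]; 28-day issue
intervals (so the 183-day stop rule fires only on planted
discontinuations, themselves planted at rate 0.10 with gaps of 183–302
days); probability 0.65/0.46/0.33 of reaching lines 2/3/4 (matching the
roughly halving patient counts per successive line that cohort studies
report); exponential time-to-intensification with medians 30/27/21 months;
combination products at rate 0.10 when a non-metformin start joins existing
metformin; contamination at 4% early-onset, 4% early-insulin, 2%
other-diabetes codes, 2% PCOS and 1% no-evidence so every exclusion path is
exercised.

Two design points matter for interpreting recovery tests:

* **Conditional rows and exact truth.** A class can start at most once per
  patient, so the planted row at line k is sampled *conditionally*: classes
  already started are removed and the row renormalised. The truth table the
  generator returns is therefore not the raw config row but the exact
  induced marginal per (era, line), computed by enumeration over all
  distinct-class sequences (`line_mix_truth()`; ≤ 7·6·5·4 sequences, exact
  to machine precision, itself cross-checked against brute-force Monte
  Carlo in the test suite). Recovery tests compare pipeline estimates to
  this exact quantity under simultaneous (Bonferroni-adjusted) exact
  binomial 95% confidence intervals — simultaneous because the claim is
  about *every* cell at once.
* **Era keyed to diagnosis.** A patient's whole pathway uses the
  transition rows of their diagnosis era (prescribing culture at entry),
  which keeps the per-era truth exact. Calendar-binned shares (the
  Figure-1-style view) therefore blend adjacent eras: a calendar-2016
  second-line cell mixes recently diagnosed patients with slow
  intensifiers diagnosed under the previous era's habits, and sits between
  the two planted rows. This is a known, documented property of the
  generator, not an estimation bias — the pipeline reproduces the planted
  line events exactly, patient for patient.

What the generator does **not** emulate: HbA1c disease progression (values
are draws around the diagnosis threshold, present only to exercise the
ascertainment rules), dose/quantity, adherence, regimen concomitancy,
mortality/transfer-out, or practice-level clustering of patients. Passing
recovery tests therefore demonstrates that the *pipeline arithmetic* is
correct under known truth — not that real prescribing behaves like the
generator.

## Practice-level generator

`simulate_geo()` draws CCG class mixes from a Dirichlet around a national
mix (metformin 55.6%, sulphonylurea 21.6%, DPP-4 13.5%, TZD 2.5%, SGLT-2
4.1%, GLP-1 2.4%, other 0.3%, in exact thousandths) with concentration 150,
practice mixes from a Dirichlet around their CCG mean (concentration 150),
practice-month item totals from the practice's list size, QOF prevalence
and 11.6 items/patient/year, and costs as items × unit cost per class
(£4–£5 for the generics, £40 for gliptins and flozins, £80 for GLP-1
analogues, £12 TZD, £10 other). Planted closed (5%), dormant (3%) and
non-GP-setting (5%) practices exercise the filters. A `zero_dispersion`
mode makes every practice-month exactly 1000 items split in its CCG's
planted thousandths — a diagnostic configuration in which `ccg_summary()`
must reproduce the planted shares *exactly*, integer arithmetic end to end.
A companion helper, `synthetic_pca_table()`, inverts the per-patient
normalisation to build an annual dispensing table from a planted
trajectory; the shipped default trajectory runs non-metformin totals from
4.1 to 4.8 items and £66 to £102 per patient over 2008–2016, so the
worked percent-change arithmetic (17% and 55%) is recomputed through the
full trend pipeline rather than asserted.

# Numerical conventions and degenerate inputs

* Percentiles/quartiles/deciles: linear interpolation between order
  statistics (type 7) everywhere, recorded in the savings output metadata.
* Kurtosis: moment formula (excess); `NA` for constant vectors.
* `percent_change()` rounds half away from zero; the HbA1c threshold is
  strict (47.5 exactly does not qualify); the episode gap is `≥ 183` days
  (day 183 splits); the insulin window is `≤ 365` days (day 365 excludes).
* Share tables error on zero denominators rather than emitting NaN; CCGs
  with no antidiabetic items are excluded with a warning; decile months
  with fewer than 10 practices are skipped with a warning.
* Readers collect malformed rows into a `rejects` attribute with a warning
  — never a silent drop — and error on missing columns (naming the column)
  and on empty files.
* The pipeline itself draws no random numbers; all stochasticity lives in
  the generators, each governed by a single integer seed, so reruns on the
  same inputs are byte-identical.

# Problem sizes in the shipped checks

The test suite and acceptance script size their simulations as: 5,000
patients for line-share recovery (large enough that every populated
(era, line, class) cell has a usable binomial interval), 200 CCGs for the
between-CCG spread recovery, 50 CCGs × 4 practices × 12 months for the
geographic summary, and 150 patients / 10 CCGs for the end-to-end golden
run. These sizes make the full suite complete in about a minute on one
core while keeping the statistical checks well-powered.

# Known limitations

* The class map ships with the current canonical chemicals and a few
  synonyms; a historic BNF dictionary (discontinued brand names, code
  remappings) is out of scope, as is dose- or formulation-level
  classification.
* Lines are keyed to first-ever class starts; whether a restart after a
  long stop should open a new line is a genuine methodological fork, and
  the package takes the literal first-ever reading (episodes are exposed so
  the other reading can be built on top).
* CCG membership is a single snapshot in the metadata table; membership
  history is not tracked.
* Item counts do not distinguish course lengths; defined-daily-dose
  normalisation is deliberately not implemented (no comprehensive dose
  dataset exists for these drugs, and mixed units make quantity-based
  comparison unfair).

# A worked example

```{r example, eval = FALSE}
td <- tempfile("rxlines-demo-")
config <- write_demo_inputs(td, seed = 20180605)
manifest <- run_pipeline(config)

readr::read_csv(file.path(config$output_dir, "line_shares.csv")) |>
  dplyr::filter(calendar_year == 2016, line == 2)
jsonlite::read_json(file.path(config$output_dir, "savings.json"))
```
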