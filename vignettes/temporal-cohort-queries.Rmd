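---
title: "Time-aware cohort search with cohortql: model, semantics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware cohort search with cohortql}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cohortql)
```

## The problem

Electronic phenotyping — writing down necessary and sufficient record-level
criteria that identify patients with a condition, exposure, or outcome —
is inherently *temporal*: "diabetes diagnosis, then a first-line drug, then
an elevated lab *after* the drug" cannot be expressed naturally in plain
SQL over a relational schema.  `cohortql` implements a temporal query
language (TQL) over an in-memory datastore of *patient objects*: all of a
patient's events live together, keyed by clinical feature, so a query is
evaluated patient by patient without joins, after an inverted feature index
has discarded the patients that cannot possibly match.

## The value model: day-resolution interval sets

Every TQL expression evaluates, per patient, to a set of half-open day
intervals `[start, end)`, with day 0 at 1900-01-01.  A point event on day
*d* is `[d, d+1)`.  Interval sets are kept canonical — sorted, disjoint,
non-adjacent — so a set is in bijection with the set of integer days it
covers.  This is the package's central invariant: *every operator must
agree with the corresponding operation on day-membership bitmaps*, and the
test suite enforces exactly that with an independent day-set interpreter
(see "Validation" below).

Source data are date-stamped, so day resolution is the finest the model
supports; sub-day timing is out of scope.  The half-open convention makes
merging unambiguous: records on consecutive days coalesce into one
interval, records a day apart do not.

## Query language semantics

A program is a list of `var name = <expr>` definitions followed by a final
expression.  References (`$name`) are forward-only, evaluated per patient
in definition order and memoized within that patient's evaluation.

**Feature selectors** (`ICD9="434.91"`, `RX = 310490`,
`LABS("4548-4 [%]", 8, MAX)`, `TEXT("fever")`, `AGE(65 YEARS, MAX)`,
`GENDER="male"`, ...) return the intervals of matching events.
Demographics are patient attributes rather than events; a matching
`GENDER`/`RACE` selector returns the whole observation span, which is what
makes `INTERSECT(GENDER="male", AGE(65 YEARS, MAX))` well defined.
Attribute values are compared case-insensitively (published queries mix
`"male"` and `"FEMALE"`); codes are compared exactly.

**Boolean commands** `AND`/`OR`/`NOT` are patient-level ("had a record at
any time"): they return the whole span or the empty set.  A span-valued
result keeps them composable with the temporal commands; this is a design
choice, since only their patient-level meaning is standard.  `DIFF(a, b)`
is patient-level subtraction that *keeps the first operand's intervals*:
`a`'s result if `b` is empty for the patient, else nothing — the shape a
quality-measure numerator needs ("denominator patients minus treated
patients, keeping the denominator's index dates").

**Temporal commands** operate on interval sets: `UNION`, `INTERSECT`,
`INVERT` (complement within the observation span), `COUNT(x, min, max)`
(pass `x` through iff its number of disjoint intervals lies in the bounds),
`FIRST MENTION` (earliest interval), `NO HISTORY OF` (the span prefix
strictly before the first occurrence, or the whole span if none), and
`NEVER HAD` (whole span iff never present).

`SEQUENCE(a, b*)` relates two event streams; the starred operand's
intervals are returned.  Without a window the non-starred event must start
*strictly before* (star on the second operand) or strictly after (star on
the first) the starred interval's start — same-day events deliberately do
not satisfy "followed by", avoiding self-matching.  A window modifier
`+(lo, hi)` (presence) or `-(lo, hi)` (absence) replaces the ordering test:
it is anchored at the *start day* of each starred interval and asks whether
any non-starred interval *starts* within `[lo, hi]` days of it, boundaries
inclusive.  Anchoring on starts, inclusive boundaries, and fixed-length
units (1 MONTH = 30 days, 1 YEAR = 365 days, and `AGE` uses 365-day years)
are declared conventions: the boundary behavior of published queries such
as `+(-3 MONTHS, 0)` ("the following 3 months") and `-(-1 YEAR, 1 DAY)`
(exclusion look-back) is reproduced by them, and fixed-length units keep
the algebra calendar-free.  `COUNT` counts *coalesced* intervals, not
source rows, so two same-day codes are one occurrence — the conservative
reading of "at least 2 instances".

The grammar covers exactly the commands attested in published TQL
(including `ORIGINAL` and `EXPORT`); anything else fails with an "unknown
command" error rather than guessing.  All calls are parenthesized; `var`
and the variable name may be juxtaposed (`varstroke=`) because published
queries print them that way, and the four bundled example programs
(`tql_example()`) must parse verbatim.

## Knowledge-graph expansion

ICD9/ICD10 codes and ATC drug classes are hierarchies; RxNorm RxCUIs map
into ATC.  At load time every coded event also deposits one *derived*
event, at the same time point, per ancestor of its code (transitive
closure over the child–parent edge list; RX events add their mapped ATC
classes plus ATC ancestors).  A query for a parent code therefore
retrieves patients coded with any descendant; `ORIGINAL(...)` restricts
evaluation to source-coded events.  Expansion happens once at ETL rather
than at query time, so query evaluation never touches the ontology;
derived events never alter intervals, values, or spans, and re-expansion
is a no-op.  Tiny fixture ontologies (a few dozen codes around the ones
the example queries use) ship with the package; real vocabularies drop in
as the same two-column CSV format.

## Two-phase execution

`execute_query()` first combines inverted-index postings structurally into
a candidate set: selector → posting list; `OR`/`UNION` → union;
`AND`/`INTERSECT`/windowless `SEQUENCE` → intersection; any
negation-bearing construct (`NOT`, `INVERT`, `NO HISTORY OF`, `NEVER
HAD`, the second operand of `DIFF`, absence windows) contributes "all
patients" for its branch, keeping the approximation *sound*: a patient
that could match is never dropped.  Only candidates are then fully
evaluated.  The result maps each matching patient to the intervals where
the query was true — the data behind a patient-timeline display — and
feeds summaries (`summarize_cohort()`), timeline tracks
(`cohort_timelines()`), labeled flat-file exports (`export_flat()`), and
JSON serialization.

Age histograms use 10-year bins (0–9 … 100+) and record-length histograms
1-year bins; "most frequent codes" counts distinct matched patients having
at least one *original* event of the code (counting derived events would
let every ancestor of a common code dominate the ranking).

## The synthetic-cohort generator

No real clinical data ships with the package.  The generator
(`generate_cohort()`) emits OMOP-CDM-subset CSVs whose temporal structure
is *planted*, one spec per example query: `diabetes_stroke` plants pairs of
250.00 codes or elevated HbA1c results, glipizide dispensings, and strokes
at controlled offsets (including decoys: stroke before diagnosis, a single
code only, drug before diagnosis); `bronchitis_hedis` plants index
bronchitis events with exclusion-class codes and antibiotics inside and
outside the measure's look-back windows; `breast_ca_trial` plants in-situ
diagnoses with and without prior invasive-cancer codes (some recorded as
child codes to exercise hierarchy expansion); `t2d_labels` plants
qualifying code/lab pairs with type-1 confounders.  Default sizes are
300–400 patients per spec with a handful of deterministic exemplar
positives, demographic mixes (50/50 gender, birth-year ranges chosen so the
age criteria bite), 6–10-year observation windows starting 2008–2011, and
uniform-integer gaps within the stated ranges.

Two properties make the ground truth exact rather than approximate.
First, background noise draws from code pools (hypertension,
hyperlipidemia, osteoarthritis codes, statin/ACE-inhibitor RxCUIs, routine
CPT and creatinine-lab codes) whose ontology closures are disjoint from
every code the example queries mention, so noise cannot create or destroy
a match.  Second, all randomness flows through one counter-based stream
per patient derived from the master seed, so output is byte-identical for
identical seeds and adding patients does not perturb existing ones.  The
`ground_truth.csv` table (patient id + first day the query is satisfied)
is computed analytically from each patient's full event list by per-spec
rules written against the day-set semantics, independently of the engine.

What the generator does *not* emulate: realistic code co-occurrence,
visit structure, measurement units and reference ranges, clinical-text
content, or irregular observation coverage.  Passing the planted-truth
suite therefore shows the engine implements the declared semantics
exactly; it does not validate clinical plausibility of any particular
phenotype definition on real data.

## Validation strategy and problem sizes

The test suite checks, at sizes chosen to exercise the machinery while
keeping a full run in minutes:

* **Bitmap oracle** — every algebra operator against day-membership
  bitmaps, plus the law suite (commutativity, associativity, idempotence,
  double inversion, De Morgan within the span, the `NO HISTORY OF`
  boundary property), 1000 random cases per law.
* **Day-set interpreter** — an independent recursive interpreter over
  logical day vectors, compared with the engine on >10,000 randomized
  AST-times-patient evaluations (spans ≤ 5000 days).
* **Index/scan equivalence** — 100 random queries over the five core
  commands (AND, OR, INTERSECT, UNION, SEQUENCE) with parameters drawn
  from ICD9/ICD10/CPT/RX vocabularies, on a 10,000-patient store:
  two-phase indexed execution must be bit-identical to evaluating every
  patient.
* **Planted truth** — for each default spec, matched ids and
  first-satisfaction days must equal `ground_truth.csv` exactly.
* **Structure** — the quality-measure numerator is nested in its
  denominator and re-verified by direct scan; shard write/reload
  reproduces identical results, and partial shard loads restrict them.

## Degenerate inputs and numerical choices

Degenerate intervals (`start >= end`) are rejected at construction.
Events outside the observation period are clipped at load (dropped when
wholly outside) so that `INVERT`, `NO HISTORY OF`, and `NEVER HAD` have a
well-defined universe.  Empty operand sets are legal everywhere (an empty
match simply means the patient does not qualify).  Ontology edge lists are
rejected if cyclic.  `MAX` is an unbounded sentinel (`Inf` internally);
all day arithmetic is exact integer arithmetic, so there are no numerical
tolerances anywhere in the engine.

## Known limitations

* Calendar-free units: `1 MONTH = 30 days`, `1 YEAR = 365 days`; `AGE`
  boundaries are therefore approximate near birthdays, and
  `AGE(18 YEARS, 64 YEARS)` covers ages 18 up to (not including) the
  64-years-in-days boundary.
* Boolean `AND`/`OR`/`NOT` return span-valued results by convention; other
  conventions (e.g. returning contributing feature intervals) would change
  downstream `INTERSECT`s.
* `COUNT` counts disjoint coalesced intervals; visit- or row-based
  counting would need visit identifiers the model does not carry.
* Single-process sharding only: shard files are self-contained and can be
  loaded partially, but cross-machine query distribution is out of scope,
  as are compressed in-memory encodings.
* The `TEXT` command consumes pre-extracted mention tables; no NLP is
  performed.
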