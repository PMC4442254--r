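---
title: "matcite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{matcite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcite)
```

`matcite` treats the "material examined" passages of taxonomic
treatments as structured occurrence data. This vignette documents the
model behind each component, the conventions adopted where the source
literature is ambiguous, and the limits of what the synthetic tests can
show.

## The record model

An article carries bibliographic metadata (journal, year, ordered
authors, optional DOI/LSID, page count) and treatments. A treatment has
a rank-keyed taxon (order/family/genus/species epithets — a flat
mapping, not a tree, because filters address epithets by rank name), a
status (new species / new combination / new higher taxon, derived from
verbatim tokens such as "sp. nov."), and materials citations. A
citation has a reconciled count triple, a type status from a fixed
seven-member vocabulary (holotype, paratype, syntype, lectotype,
neotype, allotype, none; the first four minus paratype/allotype — i.e.
holotype, syntype, lectotype, neotype — are the *primary types*), zero,
one or many collection codes, and optional country, locality, elevation
(m), event date, collector string and specimen codes.

Unknown status or type tokens are preserved verbatim and surfaced by
`validate_corpus()` rather than silently coerced: when mining legacy
text, auditability beats canonicalisation. Validation returns findings
(severity, record id, message) and never throws, so a whole corpus can
be triaged in one pass.

## Count reconciliation

Specimen lots are heterogeneous: one vial may hold adult males, adult
females and undetermined juveniles under one code. Darwin Core has no
native representation for this, so the convention is to parse the `sex`
text (`"1 male, 4 females"`) and reconcile it with `individualCount`:

* `individualCount` absent → total is the sexed sum;
* `individualCount >= sexed sum` → total is `individualCount` and the
  difference joins the *other* class;
* `individualCount < sexed sum` → the sexed sum wins and a
  reconciliation warning is attached to the triple. Whether the
  upstream convention treats this as an error or an override is
  unspecified; keeping the larger value loses no specimens and the
  warning preserves the audit trail.

The sex grammar accepts comma/semicolon/"and"/"&"-separated tokens of
`<count> <classword>` with a bare classword meaning 1; classwords cover
male/female (including the ♂/♀ symbols) and a small set of non-adult
words (juvenile, juv, imm(ature), subadult, other). Unrecognised tokens
are kept verbatim in `unparsed_tokens`, never guessed at.

## Dates, decades, elevation bands

Event dates keep their stated precision ("1999", "1999-07",
"1999-07-15", "15.07.1999", "3 August 2005", and day ranges like
"12–15 Jul 1999", which use the start date). A year-only date has no
month: in the month chart those specimens sit in an explicit "missing"
column rather than being spread or dropped. Decades are
`floor(year/10)*10`, labelled "1990s".

Elevations are binned into half-open 500 m bands `(k·500, (k+1)·500]`,
labelled "1–500", "1,001–1,500" etc.; an exact 0 m falls in the lowest
band, and a value on a boundary (1500 m) belongs to the band below it
(upper-inclusive). A verbatim range ("1200–1400 m") is represented by
its midpoint before binning — the sources don't say how ranges should be
binned, and the midpoint is the least biased single value.

## Facet semantics

`aggregate_facet()` returns, per facet value, the specimen total, the
number of distinct treatments and the number of distinct articles with
at least one qualifying citation, plus a reserved `"missing"` row. Three
conventions matter:

* **Ambiguous depositories.** A citation can list several collection
  codes against one pooled count (e.g. "154 paratypes distributed among
  five institutions"). Its specimens are counted under `"missing"` —
  the per-institution split is genuinely unknown — while its treatment
  and article count as present in *each* listed code. One can deduce
  that material from the cited locality is in each institution, but not
  how much. Specimens are therefore conserved (every facet's specimen
  column, missing included, sums to the corpus total), while treatment
  presence is deliberately not additive.
* **Lead author.** The `doc.author` filter matches the first author
  only; an author dashboard should not absorb articles where the person
  is a middle co-author. `apply_filter(..., author_scope = "any")`
  widens this when wanted.
* **Reserved label.** A genuine facet value spelled "missing" is
  escaped to `'missing'` on output so the reserved row stays
  unambiguous.

Rows sort by the chosen measure descending with ties broken
lexicographically, so output is deterministic. Filters are conjunctive;
after citation-level clauses, treatments left without qualifying
citations are dropped (and articles left empty likewise), matching how
per-country or per-collector treatment counts are usually quoted.

Collector attribution offers three modes because the verbatim
`collectorName` field does not resolve teams: `raw` keeps the verbatim
string (so differently ordered teams are distinct values), `fractional`
divides each lot equally among the team (conserving the corpus total),
and `full_credit` gives every member the whole lot (the column may then
exceed the corpus total — it answers "how many specimens did this
person help collect"). No name deduplication or initials matching is
attempted; that is a hard open problem and silently merging names would
corrupt attribution.

## Corpus statistics

`summarize_corpus()` reports exact integer counts and full-precision
ratios (printed at one decimal). Sex composition and its percentages
are computed over specimens cited in species-rank treatments, the
denominator on which such compositions are conventionally quoted.

`rarity_stats()` measures rarity among new-species treatments:
*singleton* = cited specimen total exactly 1; *unique* = exactly one
distinct collection event, where an event is the tuple (normalised
lower-cased locality, event date, collector string) — the source
literature defines "unique" only verbally, and this tuple is the
closest observable proxy; *single-locality* = exactly one distinct
non-missing locality string (a species whose citations all lack
locality is not claimed to be single-locality). Singletons and uniques
are independent definitions: no ordering between their counts is
asserted. Because prospectively published corpora quote the singleton
share against species treatments that explicitly cite specimens, that
share (`cited_singleton_rate`) is reported alongside the new-species
rates.

`description_lag()` uses year precision only — legacy dates are often
year-only, and mixing precisions would bias the lag. Per new species
the earliest collection year among dated citations is subtracted from
the publication year; species with no dated citations are excluded and
counted. The standard error is the sample (n−1) standard deviation over
√n.

## Dashboard pages

`build_dashboard()` assembles a canonical 16-chart page: sex pie;
month×sex stacked bar (months 1–12 plus "missing"); specimens by
decade; specimens by elevation band; specimens/treatments/primary-type
specimens by collection; specimens/treatments by country;
specimens/treatments by collector (raw mode); treatments by family and
by status; specimens/treatments by publication year; treatments per
article. Charts are views over facet tables — relabelled or reordered,
never recomputed — so chart totals always equal facet-table totals. The
full chart inventory of a production dashboard is larger and partly a
matter of taste; the canonical set covers every chart family named
above, and `extra_charts` is the extension hook for the rest. A
per-species page is just a genus+species epithet filter, not a separate
engine.

`render_json()` serialises a page with fixed key order (`page_id`,
`filter`, `profile`, `charts`; per chart `chart_id`, `kind`, `title`,
`x_labels`, `series`, where `series` maps series name to a numeric array
aligned with `x_labels`): rendering is byte-deterministic, replacing an
external charts service with static data any plotting layer can
consume.

## The XML dialect

The dialect is deliberately small and hand-writable:

```
article[id, journal, year, doi?, lsid?, pageCount?]
  meta > author+
  treatment[id, rank, status?]
    taxon[orderEpithet?, familyEpithet?, genusEpithet?, speciesEpithet?, authority?]
    materialsCitation[country?, locality?, elevation?, date?, collectorName?, typeStatus?]
      collectionCode*  specimenCount[type ∈ male|female|other|total, count]*  specimenCode*
```

Writing is canonical — fixed attribute order, 2-space indent, UTF-8,
absent fields omitted (never empty) — so the same corpus always
serialises to identical bytes and `read(write(x))` is the identity. The
`total` specimenCount plays the role of `individualCount` and goes
through the same reconciliation as the CSV path. The Darwin Core export
writes one row per citation with a fixed 20-column contract;
multi-valued collection codes are joined with `|` into
`institutionCode` (the dialect's `collectionCode` is Darwin Core's
`institutionCode`), and `basisOfRecord` is constantly
"PreservedSpecimen". Full TaxonX/TaxPub DTD compliance and Darwin Core
Archive packaging are out of scope.

## The synthetic-corpus generator

`generate_corpus()` emulates the structure of marked-up spider
literature: a few articles per corpus, mostly species-rank treatments,
Poisson-ish treatment and citation counts, skewed specimen counts, a
male-biased sex split, 500–3,500 m elevations, collection dates up to a
few decades before publication, configurable missing-field rates, a
small rate of ambiguous multi-collection citations, and collector teams
drawn from a name pool. New species carry a geometric
discovery-to-description lag (`lag_mean`, default 10 years) whose true
value per species is recorded in the ground truth.

Two design points:

* **Independent ground truth.** During generation a second,
  brute-force counting path (`facet_table_bruteforce()` plus plain
  loops) computes every facet table, summary, rarity and lag quantity.
  It shares only the field-level primitives (date parsing, elevation
  binning) with the engine, so disagreements expose aggregation bugs.
* **Exact totals.** `exact_totals` switches the generator from
  sampling totals to *constructing* them: treatments are composed into
  articles by random composition, singleton and single-locality sets
  are chosen explicitly, specimens are partitioned with the right
  minima, and the sex split is realised by shuffling a fixed multiset
  of labels. Unsatisfiable combinations raise a config error rather
  than being silently adjusted. `reference_configs()` packages the two
  corpus conditions the package's acceptance checks use (a 37-article
  legacy set and a 5-article prospective set with their published
  headline totals).

What the generator does *not* emulate: real locality/collector text
(values are drawn from pools), per-collection specimen splits inside
ambiguous citations, nomenclatural acts, or correlated missingness
(fields go missing independently). Passing tests therefore demonstrate
that the *accounting* is exact under realistic structure — they say
nothing about OCR quality, markup errors or name disambiguation in real
corpora.

The generator uses R's seeded RNG locally and restores the caller's
RNG state, so corpora are reproducible from their seed without leaking
global state.

## Numerical and degenerate-input choices

* Ratios are kept at full precision; one-decimal rendering is a print
  concern only.
* Facet ties break lexicographically; JSON key order is fixed; repeated
  runs of any command are byte-identical.
* Empty corpora: summaries are zeros with `means_defined = FALSE`;
  rarity rates are `NA` with `rates_defined = FALSE` when there are no
  new species; an empty filtered dashboard is a page of all-zero
  charts, not an error.
* A collection year after the publication year (a data error) excludes
  that species from the lag records with a warning rather than
  producing a negative lag.
* Fractional attribution conserves totals to within 1e-9 (floating
  division by team size is the only non-integer step).

## Test problem sizes

The suite exercises the engine-vs-ground-truth equality on 100 seeded
corpora of ~3 articles, XML round-trips on 200 corpora of ~2 articles,
conservation and attribution properties on 5-article corpora, and the
reference conditions at full size (37 and 5 articles, ~8,200
specimens); these sizes give full code-path coverage with a suite that
runs in about a minute. Statistical checks (sex-split convergence, lag
mean recovery) use 4-standard-error bands, so seed-to-seed flakiness is
negligible without weakening the check.

## Known limitations

* Collector identity is string-based; "Y. Marusik" and
  "Y. M. Marusik" are different collectors by design.
* The `unique` (collection event) definition conflates events whose
  locality, date and collector are all missing.
* Lag is year-resolution; sub-year lags are 0.
* The dialect models no georeferences; coordinates would be a natural
  extension of `materialsCitation` but no current chart uses them.
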