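# matcite

Specimen data cited in taxonomic literature — the "material examined"
sections of species descriptions and revisions — are among the highest
quality primary biodiversity data, but in legacy publications they are
locked in unstructured text. `matcite` is an R toolkit for working with
these **materials citations** once they have been marked up as
structured XML: it reads and writes a compact treatment-XML dialect,
normalises the messy verbatim fields, exports Darwin Core occurrence
tables, aggregates specimens over filterable facets for dashboard-style
charts, and computes corpus-level biodiversity statistics. It is aimed
at biodiversity informaticians, taxonomists and collections managers who
want to query marked-up taxonomic literature the way they would query an
occurrence database.

## The model

A corpus is a list of **articles**, each containing taxonomic
**treatments** (rank, status, rank-keyed epithets), each containing
**materials citations** — cited specimen lots with collecting-event and
depository fields. Counts in a lot are kept as a reconciled triple

```
total = males + females + other
```

built from the Darwin Core `sex` text and `individualCount` by the rule:
if `individualCount >= males + females + stated other`, the surplus is
added to the *other* class (non-adults etc.); if it is smaller, the
sexed sum wins and a reconciliation warning is attached; if it is
absent, the sexed counts are summed.

On top of the model:

* **Faceted aggregation** — for any facet (country, institutional
  collection code, collector string, collecting month/decade, 500 m
  elevation band, family, status, publication year …) a table of
  (specimens, distinct treatments, distinct articles) per value, with an
  explicit `"missing"` row. A citation that lists several collection
  codes with one pooled count (a common ambiguity in legacy text)
  contributes its specimens to `"missing"` — the per-institution split
  is unknown — while its treatment counts as *present* in each listed
  code.
* **Filters** — conjunctive clauses in the query-string syntax
  `FILTER_tax.orderEpithet=Araneae&FILTER_mat.country=Russia`, at
  document, treatment and citation level.
* **Collector attribution** — raw verbatim strings, fractional credit
  (`total/k` per member of a k-person team; conserves the corpus total)
  or full credit per member.
* **Rarity** — among newly described species: *singletons* (known from
  one specimen), *uniques* (one collection event, identified by the
  normalised locality/date/collector tuple) and single-locality species.
* **Description lag** — per new species, the years between the earliest
  collection year among its dated citations and the publication year,
  with mean, median and standard error (sd/√n).
* **Synthetic corpora** — a seeded generator with independent
  ground-truth bookkeeping; `exact_totals` can pin corpus totals
  exactly, which is how the package's own acceptance checks reproduce
  published corpus statistics.

## Worked example

```r
library(matcite)
gen <- generate_corpus(generator_config(seed = 42, n_articles = 8))
summarize_corpus(gen$corpus)
#> <mc_summary>
#>   articles: 8  treatments: 55 (species-rank: 46)
#>   specimens: 986 (in species-rank treatments: 909)
#>   treatments/article: 6.9 (species-rank: 5.8)
#>   specimens/species treatment: 19.8
#>   new species: 20 (43.5% of species treatments)
#>   sex: 487 male (53.6%), 323 female (35.5%), 99 other (10.9%)

print(aggregate_facet(gen$corpus, "mat.collectionCode"), n = 5)
#> <mc_facet_table> facet=mat.collectionCode (ordered by specimens)
#> # A tibble: 13 × 4
#>   value   specimens treatments articles
#> * <chr>       <dbl>      <int>    <int>
#> 1 MNHN          130         10        6
#> 2 IZAS          118         11        6
#> 3 CAS           102          9        6
#> 4 NHRS          102         11        6
#> 5 missing        98          8        6

rarity_stats(gen$corpus)
#> <mc_rarity>
#>   new species: 20
#>   singletons: 0 (0.0%)  uniques: 7 (35.0%)  single-locality: 6 (30.0%)
#>   cited species treatments: 46, of which singletons: 0 (0.0%)

description_lag(gen$corpus)
#> <mc_lag> n=20 mean=9.80 se=2.63 median=7 range=[0, 46] excluded=0
```

The summary reads: 8 articles carry 55 treatments (6.9 per article), of
which 46 are species-rank; the 909 specimens cited in species treatments
are 53.6% adult males; 43.5% of species treatments describe new species.
The facet table shows the museum (MNHN) holding the most cited
specimens, and 98 specimens not attributable to any single collection.
The lag summary says the 20 new species were described a median of 7
years after their earliest recorded collection.

A command-line interface wraps the same functions
(`inst/cli/matcite validate|export-dwc|stats|dashboard|synth`), and
`build_dashboard()` + `render_json()` produce the 16-chart dashboard
page as deterministic JSON.

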