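toy_corpus_no_new <- function() {
  cp <- toy_corpus()
  cp$articles[[1]]$treatments[[1]]$status <- treatment_status()
  cp
}

test_that("summary fields are exact functions of corpus counts", {
  cp <- mixed_corpus()
  s <- summarize_corpus(cp)
  expect_identical(s$n_articles, 2L)
  expect_identical(s$n_treatments, 3L)
  expect_identical(s$n_species_treatments, 3L)
  expect_identical(s$n_specimens, 7L)
  expect_identical(s$mean_treatments_per_article, 1.5)
  expect_identical(s$n_new_species, 1L)
  sc <- s$sex_composition
  expect_identical(c(sc$males, sc$females, sc$other), c(3L, 4L, 0L))
  expect_equal(sc$pct_females, 100 * 4 / 7)
})

test_that("summary means agree with a brute-force recount on generators", {
  for (seed in c(4, 17)) {
    gen <- generate_corpus(small_config(seed))
    s <- summarize_corpus(gen$corpus)
    t <- gen$truth$summary
    expect_identical(s$n_articles, t$n_articles)
    expect_identical(s$n_treatments, t$n_treatments)
    expect_identical(s$n_species_treatments, t$n_species_treatments)
    expect_identical(s$n_specimens, t$n_specimens)
    expect_identical(s$n_species_specimens, t$n_species_specimens)
    expect_identical(s$mean_treatments_per_article,
                     t$n_treatments / t$n_articles)
    expect_identical(s$sex_composition$males, t$sex[["males"]])
  }
})

test_that("an empty corpus summarizes to zeros with undefined means", {
  s <- summarize_corpus(corpus())
  expect_identical(s$n_treatments, 0L)
  expect_false(s$means_defined)
  expect_true(is.na(s$mean_treatments_per_article))
})

test_that("rarity definitions: singleton, unique and single-locality", {
  # one new species, two citations sharing locality+date+collector:
  # unique (one event) but not singleton (total > 1)
  shared <- list(locality = "same spot", event_date = "2010-06",
                 collector_raw = "A")
  tr <- treatment_record(
    "t1", taxon_name("species", genus = "G", species = "x"),
    treatment_status("sp. nov."),
    citations = list(
      do.call(materials_citation, c(list(counts = count_triple(1, 0, 0)),
                                    shared)),
      do.call(materials_citation, c(list(counts = count_triple(0, 2, 0)),
                                    shared))))
  # a singleton new species
  tr2 <- treatment_record(
    "t2", taxon_name("species", genus = "G", species = "y"),
    treatment_status("sp. nov."),
    citations = list(materials_citation(count_triple(0, 1, 0),
                                        locality = "elsewhere")))
  # a non-new species: never in the new-species denominators
  tr3 <- treatment_record(
    "t3", taxon_name("species", genus = "G", species = "z"),
    citations = list(materials_citation(count_triple(1, 0, 0))))
  cp <- corpus(list(article_record("a1", "J", 2012L, "Z",
                                   treatments = list(tr, tr2, tr3))))
  r <- rarity_stats(cp)
  expect_identical(r$n_new_species, 2L)
  expect_identical(r$n_singletons, 1L)
  expect_identical(r$n_single_collection, 2L)
  expect_identical(r$n_single_locality, 2L)
  expect_equal(r$singleton_rate, 0.5)
  # cited-species singleton share counts all species treatments that cite
  expect_identical(r$n_cited_species_treatments, 3L)
  expect_identical(r$n_cited_singletons, 2L)
})

test_that("rarity rates are flagged undefined without new species", {
  r <- rarity_stats(toy_corpus_no_new())
  expect_false(r$rates_defined)
  expect_true(is.na(r$singleton_rate))
})

test_that("rarity on synthetic corpora equals generator bookkeeping", {
  cfg <- small_config(31, exact_totals = list(
    n_articles = 6, n_treatments = 24, n_species_treatments = 20,
    n_new_species = 10, n_species_specimens = 150,
    n_singletons_new = 4, n_singletons_cited = 7,
    n_single_locality_new = 5))
  gen <- generate_corpus(cfg)
  r <- rarity_stats(gen$corpus)
  expect_identical(r$n_new_species, 10L)
  expect_identical(r$n_singletons, 4L)
  expect_identical(r$n_cited_singletons, 7L)
  expect_identical(r$n_single_locality, 5L)
  expect_identical(r$n_singletons, gen$truth$rarity$n_singletons)
  expect_identical(r$n_single_collection,
                   gen$truth$rarity$n_single_collection)
})

test_that("description lag arithmetic matches the direct oracle", {
  mk <- function(id, pub, years) {
    treatment_record(
      id, taxon_name("species", genus = "G", species = id),
      treatment_status("sp. nov."),
      citations = lapply(years, function(y) {
        materials_citation(count_triple(1, 0, 0),
                           event_date = if (is.na(y)) NULL else
                             as.character(y))
      }))
  }
  cp <- corpus(list(
    article_record("a1", "J", 2014L, "Z",
                   treatments = list(mk("s1", 2014, 2014))),   # lag 0
    article_record("a2", "J", 2011L, "Z",
                   treatments = list(mk("s2", 2011, c(1909, 1999)),  # lag 102
                                     mk("s3", 2011, 2004),           # lag 7
                                     mk("s4", 2011, NA)))))          # excluded
  lag <- description_lag(cp)
  expect_identical(sort(lag$records$lag_years), c(0L, 7L, 102L))
  expect_identical(lag$summary$n_excluded_missing_dates, 1L)
  expect_identical(lag$summary$min, 0L)
  expect_identical(lag$summary$max, 102L)

  # frozen oracle for {0, 7, 14}: mean 7, median 7, SE = sd/sqrt(3)
  cp2 <- corpus(list(
    article_record("b1", "J", 2014L, "Z", treatments = list(
      mk("u1", 2014, 2014), mk("u2", 2014, 2007), mk("u3", 2014, 2000)))))
  s <- description_lag(cp2)$summary
  expect_equal(s$mean, 7)
  expect_equal(s$median, 7)
  expect_equal(s$standard_error, 7 / sqrt(3))
})

test_that("lag recovery: the generator's per-species lags are recovered", {
  for (seed in c(8, 23)) {
    gen <- generate_corpus(small_config(seed, lag_mean = 6))
    lag <- description_lag(gen$corpus)
    book <- gen$truth$bookkeeping$lags
    expect_identical(lag$summary$n, length(book))
    got <- stats::setNames(lag$records$lag_years, lag$records$treatment_id)
    for (tid in names(book)) {
      expect_identical(unname(got[tid]), as.integer(book[[tid]]),
                       label = tid)
    }
  }
})

test_that("specimen-code coverage counts records and specimens", {
  cv <- specimen_code_coverage(toy_corpus())
  expect_identical(cv$n_records, 3L)
  expect_identical(cv$n_records_with_code, 0L)
  cfg <- small_config(12, exact_totals = list(n_citations_with_code = 5))
  gen <- generate_corpus(cfg)
  cv <- specimen_code_coverage(gen$corpus)
  expect_identical(cv$n_records_with_code, 5L)
})
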