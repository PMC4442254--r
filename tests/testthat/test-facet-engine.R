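test_that("filter queries validate their keys", {
  expect_error(filter_query(tax.orderEpitet = "Araneae"), "unknown filter")
  q <- parse_filter_string("FILTER_tax.orderEpithet=Araneae&FILTER_mat.country=Russia")
  expect_identical(q$clauses$tax.orderEpithet, "Araneae")
  expect_identical(q$clauses$mat.country, "Russia")
  expect_error(parse_filter_string("tax.rank=species"), "malformed")
  expect_identical(parse_filter_string("")$clauses, list())
})

test_that("the empty query is the identity", {
  cp <- mixed_corpus()
  v <- apply_filter(cp, filter_query())
  expect_identical(v, cp)
})

test_that("taxon filters retain only matching treatments", {
  cp <- mixed_corpus()
  v <- apply_filter(cp, filter_query(tax.orderEpithet = "Araneae"))
  ranks <- unlist(lapply(v$articles, function(a) {
    vapply(a$treatments, function(tr) tr$taxon$epithets$orderEpithet, "")
  }))
  expect_true(all(ranks == "Araneae"))
  expect_identical(summarize_corpus(v)$n_treatments, 2L)
  # the insect-only article dropped entirely
  expect_length(v$articles, 1)
})

test_that("materials filters select citations and drop emptied treatments", {
  cp <- toy_corpus()
  v <- apply_filter(cp, filter_query(mat.country = "Russia"))
  expect_identical(summarize_corpus(v)$n_specimens, 4L)
  expect_identical(summarize_corpus(v)$n_treatments, 1L)
  v2 <- apply_filter(cp, filter_query(mat.collectionCode = "ZMMU"))
  expect_identical(summarize_corpus(v2)$n_specimens, 2L)  # c2 + c3
})

test_that("doc.author matches the lead author unless scope is widened", {
  cp <- mixed_corpus()
  expect_length(apply_filter(cp, filter_query(doc.author = "B. Co"))$articles,
                0)
  expect_length(apply_filter(cp, filter_query(doc.author = "B. Co"),
                             author_scope = "any")$articles, 1)
  expect_length(apply_filter(cp, filter_query(doc.author = "A. Lead"))$articles,
                1)
})

test_that("sequential filters compose like their conjunction", {
  gen <- generate_corpus(small_config(21))
  cp <- gen$corpus
  pairs <- list(
    c("doc.journal", "Zootaxa", "tax.rank", "species"),
    c("tax.familyEpithet", "Lycosidae", "mat.country", "Russia"),
    c("tax.rank", "species", "mat.typeStatus", "holotype"))
  for (p in pairs) {
    qa <- filter_query(clauses = stats::setNames(list(p[2]), p[1]))
    qb <- filter_query(clauses = stats::setNames(list(p[4]), p[3]))
    qab <- filter_query(clauses = stats::setNames(list(p[2], p[4]),
                                                  c(p[1], p[3])))
    expect_identical(apply_filter(apply_filter(cp, qa), qb),
                     apply_filter(cp, qab))
  }
})

test_that("toy-corpus aggregation matches hand enumeration", {
  cp <- toy_corpus()
  ft <- aggregate_facet(cp, "mat.country")
  expect_identical(ft$value, c("Russia", "China"))
  expect_identical(as.numeric(ft$specimens), c(4, 1))

  # ambiguity rule: pooled count to "missing", presence to each code
  ft <- aggregate_facet(cp, "mat.collectionCode")
  expect_identical(ft$specimens[ft$value == "IBPN"], 3)
  expect_identical(ft$specimens[ft$value == "ZMMU"], 1)
  expect_identical(ft$specimens[ft$value == "missing"], 1)
  expect_identical(ft$treatments[ft$value == "ZMMU"], 2L)  # t1 (c2) + t2
  expect_identical(ft$treatments[ft$value == "IBPN"], 1L)  # t1 only
})

test_that("fig12 fixture: pooled total in missing, presence in each code", {
  cp <- fig12_fixture()
  ft <- aggregate_facet(cp, "mat.collectionCode")
  expect_identical(ft$specimens[ft$value == "missing"], 154)
  codes <- setdiff(ft$value, "missing")
  expect_length(codes, 5)
  expect_identical(unique(ft$treatments[ft$value %in% codes]), 1L)
  expect_identical(unique(ft$specimens[ft$value %in% codes]), 0)
})

test_that("specimen counts are conserved across every facet", {
  facets <- c("mat.country", "mat.collectionCode", "mat.collectorName",
              "mat.typeStatus", "mat.month", "mat.decade",
              "mat.elevationBand", "tax.familyEpithet", "tax.status",
              "doc.year", "doc.journal")
  for (seed in 1:10) {
    gen <- generate_corpus(small_config(seed))
    total <- corpus_specimen_total(gen$corpus)
    for (f in facets) {
      ft <- aggregate_facet(gen$corpus, f)
      expect_identical(sum(ft$specimens), as.numeric(total),
                       label = paste("facet", f, "seed", seed))
    }
  }
})

test_that("aggregation equals the brute-force oracle on small corpora", {
  for (seed in 1:10) {
    gen <- generate_corpus(generator_config(
      seed = seed, n_articles = 3L,
      treatments_per_article = dist_spec("poisson", lambda = 3, min = 1),
      citations_per_treatment = dist_spec("poisson", lambda = 1, min = 1),
      specimens_per_treatment = dist_spec("poisson", lambda = 6, min = 1)))
    for (f in matcite:::TRUTH_FACETS) {
      expect_facet_equal(aggregate_facet(gen$corpus, f),
                         facet_table_bruteforce(gen$corpus, f))
    }
  }
})

test_that("rows sort by the chosen measure, ties broken by label", {
  gen <- generate_corpus(small_config(5))
  ft <- aggregate_facet(gen$corpus, "mat.country")
  key <- order(-ft$specimens, ft$value)
  expect_identical(key, seq_len(nrow(ft)))
  ft2 <- aggregate_facet(gen$corpus, "mat.country", measure = "treatments")
  key2 <- order(-ft2$treatments, ft2$value)
  expect_identical(key2, seq_len(nrow(ft2)))
})

test_that("collector attribution modes follow the team-credit rules", {
  ci <- materials_citation(count_triple(6, 4, 0), collector_raw = "A & B",
                           country = "X")
  cp <- corpus(list(article_record("a1", "J", 2010L, "Z", treatments = list(
    treatment_record("t1", taxon_name("species", genus = "G", species = "s"),
                     citations = list(ci))))))
  raw <- attribute_collectors(cp, "raw")
  expect_identical(raw$value, "A & B")
  expect_identical(as.numeric(raw$specimens), 10)

  fr <- attribute_collectors(cp, "fractional")
  expect_identical(sort(fr$value), c("A", "B"))
  expect_identical(as.numeric(fr$specimens), c(5, 5))

  fc <- attribute_collectors(cp, "full_credit")
  expect_identical(as.numeric(fc$specimens), c(10, 10))
})

test_that("fractional attribution conserves the corpus specimen total", {
  for (seed in 1:8) {
    gen <- generate_corpus(small_config(seed))
    total <- corpus_specimen_total(gen$corpus)
    fr <- attribute_collectors(gen$corpus, "fractional")
    expect_lt(abs(sum(fr$specimens) - total), 1e-9)
    # full credit >= raw for any individual vs their fractional share
    fc <- attribute_collectors(gen$corpus, "full_credit")
    shared <- intersect(fc$value, fr$value)
    expect_true(all(fc$specimens[match(shared, fc$value)] >=
                      fr$specimens[match(shared, fr$value)] - 1e-9))
    expect_gte(sum(fc$specimens), sum(fr$specimens) - 1e-9)
  }
})

test_that("a genuine facet value equal to 'missing' is escaped", {
  ci <- materials_citation(count_triple(1, 0, 0), country = "missing")
  cp <- corpus(list(article_record("a1", "J", 2010L, "Z", treatments = list(
    treatment_record("t1", taxon_name("species", genus = "G", species = "s"),
                     citations = list(ci, materials_citation(
                       count_triple(0, 1, 0)))))))) # second: country absent
  ft <- aggregate_facet(cp, "mat.country")
  expect_setequal(ft$value, c("'missing'", "missing"))
  expect_identical(ft$specimens[ft$value == "missing"], 1)
})
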