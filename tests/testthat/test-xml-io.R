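minimal_xml <- paste0(
  '<article id="a9" journal="Zootaxa" year="2005">',
  "<meta><author>Z. Zed</author></meta></article>")

test_that("a minimal document yields an article with no treatments", {
  a <- read_article(minimal_xml)
  expect_identical(a$article_id, "a9")
  expect_identical(a$year, 2005L)
  expect_identical(a$treatments, list())
  expect_null(a$doi)
})

test_that("treatment status tokens map onto status flags", {
  xml <- paste0(
    '<article id="a1" journal="J" year="2010">',
    "<meta><author>A</author></meta>",
    '<treatment id="t1" rank="species" status="sp. nov.">',
    '<taxon genusEpithet="G" speciesEpithet="x"/></treatment>',
    '<treatment id="t2" rank="genus" status="gen. nov.">',
    '<taxon genusEpithet="H"/></treatment></article>')
  a <- read_article(xml)
  expect_true(a$treatments[[1]]$status$is_new_species)
  expect_true(a$treatments[[2]]$status$is_new_higher_taxon)
})

test_that("ambiguous multi-collection citations keep pooled counts", {
  # counts attached to the event, not to any of the five collections
  xml <- paste0(
    '<article id="a1" journal="Zootaxa" year="2011">',
    "<meta><author>A</author></meta>",
    '<treatment id="t1" rank="species">',
    '<taxon genusEpithet="Pardosa" speciesEpithet="zyuzini"/>',
    '<materialsCitation country="Mongolia">',
    "<collectionCode>ZMMU</collectionCode><collectionCode>IBPN</collectionCode>",
    "<collectionCode>ISEA</collectionCode><collectionCode>NHRS</collectionCode>",
    "<collectionCode>IZAS</collectionCode>",
    '<specimenCount type="male" count="110"/>',
    '<specimenCount type="female" count="44"/>',
    "</materialsCitation></treatment></article>")
  a <- read_article(xml)
  ci <- a$treatments[[1]]$citations[[1]]
  expect_identical(ci$counts$males, 110L)
  expect_identical(ci$counts$females, 44L)
  expect_identical(ci$counts$other, 0L)
  expect_identical(ci$counts$total, 154L)
  expect_length(ci$collection_codes, 5)
  expect_identical(ci$collection_codes[1], "ZMMU")   # input order kept
})

test_that("schema and parse errors are specific", {
  expect_error(read_article("<article id='a'><meta/>"), class = "error")
  expect_error(read_article(paste0(
    '<article id="a1" journal="J" year="2010"><meta><author>A</author></meta>',
    '<treatment id="t1"><taxon/></treatment></article>')), "rank")
  expect_error(read_article("<nope/>"), "article")
})

test_that("unknown elements and attributes are ignored with a warning", {
  xml <- paste0(
    '<article id="a1" journal="J" year="2010" color="red">',
    "<meta><author>A</author></meta><advert/></article>")
  expect_warning(expect_warning(read_article(xml), "color"), "advert")
})

test_that("writer output is canonical, byte-stable and round-trips", {
  cp <- toy_corpus()
  x1 <- write_article(cp$articles[[1]])
  x2 <- write_article(cp$articles[[1]])
  expect_identical(x1, x2)
  expect_match(x1, 'journal="Zootaxa"')
  a2 <- read_article(x1)
  expect_identical(a2, cp$articles[[1]])
})

test_that("absent optional fields are omitted, not written empty", {
  a <- article_record("a1", "J", 2010L, "A")
  x <- write_article(a)
  expect_false(grepl("doi", x))
  expect_false(grepl('=""', x))
})

test_that("seeded corpora round-trip exactly through the dialect", {
  for (seed in 1:25) {
    gen <- generate_corpus(small_config(seed))
    for (a in gen$corpus$articles) {
      expect_identical(read_article(write_article(a)), a)
    }
  }
})

test_that("Darwin Core export has the fixed column contract", {
  df <- export_dwc(toy_corpus())
  expect_identical(names(df), matcite:::DWC_COLUMNS)
  expect_identical(nrow(df), 3L)             # one row per citation
  expect_identical(df$individualCount[1], "3")
  expect_identical(df$sex[1], "2 males, 1 female")
  expect_identical(df$institutionCode[2], "ZMMU|IBPN")
  expect_identical(unique(df$basisOfRecord), "PreservedSpecimen")
  # zero-count citation: individualCount "0", sex empty
  cp <- corpus(list(article_record("a1", "J", 2010L, "A", treatments = list(
    treatment_record("t1", taxon_name("species", genus = "G", species = "x"),
                     citations = list(materials_citation()))))))
  df0 <- export_dwc(cp)
  expect_identical(df0$individualCount, "0")
  expect_identical(df0$sex, "")
})

test_that("export row count equals the number of materials citations", {
  for (seed in c(2, 9)) {
    gen <- generate_corpus(small_config(seed))
    n <- 0L
    for (a in gen$corpus$articles) {
      for (tr in a$treatments) n <- n + length(tr$citations)
    }
    expect_identical(nrow(export_dwc(gen$corpus)), n)
  }
})

test_that("flat Darwin Core ingest reconciles sex text and individualCount", {
  df <- export_dwc(toy_corpus())
  cp2 <- read_dwc(df)
  expect_identical(corpus_specimen_total(cp2),
                   corpus_specimen_total(toy_corpus()))
  # heterogeneous lot: non-adults recovered into "other"
  df <- tibble::tibble(scientificName = "Pardosa x", taxonRank = "species",
                       genus = "Pardosa", specificEpithet = "x",
                       sex = "1 male, 4 females", individualCount = "7")
  ci <- read_dwc(df)$articles[[1]]$treatments[[1]]$citations[[1]]
  expect_identical(ci$counts$other, 2L)
  expect_identical(ci$counts$total, 7L)
})

test_that("the shipped example article parses and validates cleanly", {
  path <- system.file("extdata", "example-article.xml", package = "matcite")
  cp <- read_corpus(path)
  expect_identical(nrow(validate_corpus(cp)), 0L)
  s <- summarize_corpus(cp)
  expect_identical(s$n_treatments, 2L)
  expect_identical(s$n_specimens, 155L)
  ft <- aggregate_facet(cp, "mat.collectionCode")
  expect_identical(ft$specimens[ft$value == "missing"], 154)  # pooled lot
  expect_identical(ft$specimens[ft$value == "ZMMU"], 1)
})
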