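# Shared fixtures, built in code.

# Toy corpus: one article, two treatments, three citations.
# T1: c1 (Russia, IBPN, 2m 1f), c2 (Russia, {ZMMU, IBPN} ambiguous, 1f)
# T2: c3 (China, ZMMU, 1m)
toy_corpus <- function() {
  t1 <- treatment_record(
    "t1", taxon_name("species", order = "Araneae", family = "Lycosidae",
                     genus = "Pardosa", species = "alpha"),
    treatment_status("sp. nov."),
    citations = list(
      materials_citation(count_triple(2, 1, 0), collection_codes = "IBPN",
                         country = "Russia", locality = "site 1",
                         event_date = "1999-07-15",
                         collector_raw = "A & B", elevation_m = 1200),
      materials_citation(count_triple(0, 1, 0),
                         collection_codes = c("ZMMU", "IBPN"),
                         country = "Russia", locality = "site 2",
                         event_date = "2001")))
  t2 <- treatment_record(
    "t2", taxon_name("species", order = "Araneae", family = "Linyphiidae",
                     genus = "Tenuiphantes", species = "beta"),
    citations = list(
      materials_citation(count_triple(1, 0, 0), collection_codes = "ZMMU",
                         country = "China", locality = "site 3",
                         collector_raw = "C")))
  corpus(list(article_record("a1", "Zootaxa", 2010L, c("A. Lead", "B. Co"),
                             treatments = list(t1, t2))))
}

# A mixed-order corpus: toy corpus plus one insect treatment.
mixed_corpus <- function() {
  cp <- toy_corpus()
  t3 <- treatment_record(
    "t3", taxon_name("species", order = "Hymenoptera",
                     family = "Ichneumonidae", genus = "Ichneumon",
                     species = "gamma"),
    citations = list(
      materials_citation(count_triple(0, 2, 0), country = "Malaysia")))
  cp$articles[[2]] <- article_record(
    "a2", "Biodiversity Data Journal", 2014L, "C. Lead",
    treatments = list(t3))
  cp
}

small_config <- function(seed, n_articles = 5L, ...) {
  generator_config(
    seed = seed, n_articles = n_articles,
    treatments_per_article = dist_spec("poisson", lambda = 3, min = 1),
    specimens_per_treatment = dist_spec("poisson", lambda = 8, min = 1),
    ...)
}

expect_facet_equal <- function(engine_tab, brute_tab) {
  a <- as.data.frame(engine_tab)[, c("value", "specimens", "treatments",
                                     "articles")]
  b <- as.data.frame(brute_tab)[, c("value", "specimens", "treatments",
                                    "articles")]
  rownames(a) <- rownames(b) <- NULL
  a$specimens <- as.numeric(a$specimens)
  b$specimens <- as.numeric(b$specimens)
  expect_equal(a, b, ignore_attr = TRUE)
}

corpus_specimen_total <- function(cp) {
  s <- 0L
  for (a in cp$articles) {
    for (tr in a$treatments) {
      for (ci in tr$citations) s <- s + ci$counts$total
    }
  }
  s
}
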