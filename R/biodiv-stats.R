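## Corpus-level statistics: headline summary, rarity prevalence,
## discovery-to-description lag.

treatment_total <- function(tr) {
  sum(vapply(tr$citations, function(ci) ci$counts$total, 0L))
}

#' Headline corpus summary
#'
#' Integer counts are exact; means are exact ratios kept at full
#' precision (the print method renders them at one decimal). Sex
#' composition and its percentages are computed over the specimens cited
#' in species-rank treatments.
#'
#' @param corpus an `mc_corpus` (possibly filtered).
#' @return an object of class `mc_summary`: a list with fields
#'   `n_articles`, `n_treatments`, `n_species_treatments`, `n_specimens`,
#'   `n_species_specimens`, `mean_treatments_per_article`,
#'   `mean_species_treatments_per_article`,
#'   `mean_specimens_per_species_treatment`, `n_new_species`,
#'   `n_new_combinations`, `n_new_higher_taxa`,
#'   `pct_new_species_of_species_treatments`, `sex_composition` (males,
#'   females, other, total and percentages) and `means_defined`.
#' @export
summarize_corpus <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  n_articles <- length(corpus$articles)
  n_tr <- n_sp <- n_new <- n_comb <- n_higher_new <- 0L
  n_specimens <- n_sp_specimens <- 0L
  sex <- c(males = 0L, females = 0L, other = 0L)
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      n_tr <- n_tr + 1L
      tot <- treatment_total(tr)
      n_specimens <- n_specimens + tot
      if (tr$status$is_new_species) n_new <- n_new + 1L
      if (tr$status$is_new_combination) n_comb <- n_comb + 1L
      if (tr$status$is_new_higher_taxon) n_higher_new <- n_higher_new + 1L
      if (tr$taxon$rank == "species") {
        n_sp <- n_sp + 1L
        n_sp_specimens <- n_sp_specimens + tot
        for (ci in tr$citations) {
          sex["males"] <- sex["males"] + ci$counts$males
          sex["females"] <- sex["females"] + ci$counts$females
          sex["other"] <- sex["other"] + ci$counts$other
        }
      }
    }
  }
  means_defined <- n_articles > 0
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sex_total <- sum(sex)
  structure(list(
    n_articles = n_articles, n_treatments = n_tr,
    n_species_treatments = n_sp, n_specimens = n_specimens,
    n_species_specimens = n_sp_specimens,
    mean_treatments_per_article = ratio(n_tr, n_articles),
    mean_species_treatments_per_article = ratio(n_sp, n_articles),
    mean_specimens_per_species_treatment = ratio(n_sp_specimens, n_sp),
    n_new_species = n_new, n_new_combinations = n_comb,
    n_new_higher_taxa = n_higher_new,
    pct_new_species_of_species_treatments = 100 * ratio(n_new, n_sp),
    sex_composition = list(
      males = unname(sex["males"]), females = unname(sex["females"]),
      other = unname(sex["other"]), total = sex_total,
      pct_males = 100 * ratio(unname(sex["males"]), sex_total),
      pct_females = 100 * ratio(unname(sex["females"]), sex_total),
      pct_other = 100 * ratio(unname(sex["other"]), sex_total)),
    means_defined = means_defined
  ), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  d1 <- function(v) if (is.na(v)) "NA" else formatC(v, format = "f",
                                                    digits = 1)
  cat("<mc_summary>\n")
  cat(sprintf("  articles: %d  treatments: %d (species-rank: %d)\n",
              x$n_articles, x$n_treatments, x$n_species_treatments))
  cat(sprintf("  specimens: %d (in species-rank treatments: %d)\n",
              x$n_specimens, x$n_species_specimens))
  cat(sprintf("  treatments/article: %s (species-rank: %s)\n",
              d1(x$mean_treatments_per_article),
              d1(x$mean_species_treatments_per_article)))
  cat(sprintf("  specimens/species treatment: %s\n",
              d1(x$mean_specimens_per_species_treatment)))
  cat(sprintf("  new species: %d (%s%% of species treatments)\n",
              x$n_new_species, d1(x$pct_new_species_of_species_treatments)))
  sc <- x$sex_composition
  cat(sprintf("  sex: %d male (%s%%), %d female (%s%%), %d other (%s%%)\n",
              sc$males, d1(sc$pct_males), sc$females, d1(sc$pct_females),
              sc$other, d1(sc$pct_other)))
  invisible(x)
}

normalize_locality <- function(x) tolower(trimws(x))

event_key <- function(ci) {
  paste(
    if (is.null(ci$locality)) "<NA>" else normalize_locality(ci$locality),
    if (is.null(ci$event_date)) "<NA>" else ci$event_date,
    if (is.null(ci$collector_raw)) "<NA>" else ci$collector_raw,
    sep = "\x1f")
}

#' Rarity prevalence among described species
#'
#' Rarity is measured over new-species treatments: a *singleton* is a new
#' species whose cited specimens total exactly one (abundance-based
#' rarity); a *unique* is a new species known from exactly one collection
#' event, where a collection event is identified by the normalised
#' (locality, event date, collector string) tuple; *single-locality*
#' counts new species with exactly one distinct non-missing locality
#' (incidence-based rarity). The singleton share among all species-rank
#' treatments that explicitly cite specimens is reported alongside
#' (`cited_singleton_rate`), as used for prospectively published corpora.
#'
#' @param corpus an `mc_corpus`.
#' @return an object of class `mc_rarity`: a list with counts and rates
#'   (`rates` as fractions in \[0, 1\]); `rates_defined` is `FALSE` when
#'   the corpus contains no new-species treatment.
#' @export
rarity_stats <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  n_new <- 0L; n_singleton <- 0L; n_unique <- 0L; n_single_loc <- 0L
  n_cited <- 0L; n_cited_singleton <- 0L
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      if (tr$taxon$rank != "species") next
      tot <- treatment_total(tr)
      cited <- length(tr$citations) > 0 && tot > 0
      if (cited) {
        n_cited <- n_cited + 1L
        if (tot == 1L) n_cited_singleton <- n_cited_singleton + 1L
      }
      if (!tr$status$is_new_species) next
      n_new <- n_new + 1L
      if (cited && tot == 1L) n_singleton <- n_singleton + 1L
      if (cited) {
        events <- unique(vapply(tr$citations, event_key, ""))
        if (length(events) == 1L) n_unique <- n_unique + 1L
        locs <- unique(vapply(
          Filter(function(ci) !is.null(ci$locality), tr$citations),
          function(ci) normalize_locality(ci$locality), ""))
        if (length(locs) == 1L) n_single_loc <- n_single_loc + 1L
      }
    }
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    n_new_species = n_new,
    n_singletons = n_singleton, singleton_rate = rate(n_singleton, n_new),
    n_single_collection = n_unique, unique_rate = rate(n_unique, n_new),
    n_single_locality = n_single_loc,
    single_locality_rate = rate(n_single_loc, n_new),
    n_cited_species_treatments = n_cited,
    n_cited_singletons = n_cited_singleton,
    cited_singleton_rate = rate(n_cited_singleton, n_cited),
    rates_defined = n_new > 0
  ), class = "mc_rarity")
}

#' @export
print.mc_rarity <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else
    paste0(formatC(100 * v, format = "f", digits = 1), "%")
  cat("<mc_rarity>\n")
  cat(sprintf("  new species: %d\n", x$n_new_species))
  cat(sprintf("  singletons: %d (%s)  uniques: %d (%s)  single-locality: %d (%s)\n",
              x$n_singletons, pc(x$singleton_rate),
              x$n_single_collection, pc(x$unique_rate),
              x$n_single_locality, pc(x$single_locality_rate)))
  cat(sprintf("  cited species treatments: %d, of which singletons: %d (%s)\n",
              x$n_cited_species_treatments, x$n_cited_singletons,
              pc(x$cited_singleton_rate)))
  invisible(x)
}

#' Discovery-to-description lag
#'
#' For each new-species treatment, the lag in whole years between the
#' earliest collection year among its dated citations and the year of the
#' publication describing it. Species with no dated citations are
#' excluded and counted in `n_excluded_missing_dates`. The standard error
#' is the sample standard deviation over the square root of n.
#'
#' @param corpus an `mc_corpus`.
#' @return a list of class `mc_lag` with `records` (a tibble: one row per
#'   new species with a computable lag) and `summary` (`n`, `mean`,
#'   `standard_error`, `median`, `min`, `max`,
#'   `n_excluded_missing_dates`).
#' @export
description_lag <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  rows <- list()
  n_excluded <- 0L
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      if (!tr$status$is_new_species || tr$taxon$rank != "species") next
      years <- integer()
      for (ci in tr$citations) {
        y <- parse_event_date(ci$event_date)$year
        if (!is.null(y)) years <- c(years, y)
      }
      if (length(years) == 0) {
        n_excluded <- n_excluded + 1L
        next
      }
      earliest <- min(years)
      lag <- a$year - earliest
      if (lag < 0) {
        warning("collection year after publication year for treatment ",
                tr$treatment_id, "; record excluded", call. = FALSE)
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        treatment_id = tr$treatment_id,
        genus = tr$taxon$epithets$genusEpithet %||% NA_character_,
        species = tr$taxon$epithets$speciesEpithet %||% NA_character_,
        publication_year = a$year,
        earliest_collection_year = earliest,
        lag_years = lag)
    }
  }
  records <- if (length(rows) == 0) {
    tibble::tibble(treatment_id = character(), genus = character(),
                   species = character(), publication_year = integer(),
                   earliest_collection_year = integer(),
                   lag_years = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  lags <- records$lag_years
  n <- length(lags)
  summary <- list(
    n = n,
    mean = if (n > 0) mean(lags) else NA_real_,
    standard_error = if (n > 1) stats::sd(lags) / sqrt(n) else NA_real_,
    median = if (n > 0) stats::median(lags) else NA_real_,
    min = if (n > 0) min(lags) else NA_real_,
    max = if (n > 0) max(lags) else NA_real_,
    n_excluded_missing_dates = n_excluded)
  structure(list(records = records, summary = summary), class = "mc_lag")
}

#' @export
print.mc_lag <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mc_lag> n=%d mean=%.2f se=%.2f median=%s range=[%s, %s] excluded=%d\n",
              s$n, s$mean, s$standard_error, format(s$median),
              format(s$min), format(s$max), s$n_excluded_missing_dates))
  invisible(x)
}

#' Specimen-code coverage
#'
#' The share of materials citations (records) carrying at least one
#' specimen code, and the share of specimens those records represent.
#'
#' @param corpus an `mc_corpus`.
#' @return a list with `n_records`, `n_records_with_code`,
#'   `record_coverage` (fraction), `n_specimens`,
#'   `n_specimens_with_code`, `specimen_coverage`.
#' @export
specimen_code_coverage <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  n_rec <- n_code <- 0L
  n_spec <- n_spec_code <- 0L
  for_each_citation(corpus, function(a, tr, ci) {
    n_rec <<- n_rec + 1L
    n_spec <<- n_spec + ci$counts$total
    if (length(ci$specimen_codes) > 0) {
      n_code <<- n_code + 1L
      n_spec_code <<- n_spec_code + ci$counts$total
    }
  })
  list(n_records = n_rec, n_records_with_code = n_code,
       record_coverage = if (n_rec > 0) n_code / n_rec else NA_real_,
       n_specimens = n_spec, n_specimens_with_code = n_spec_code,
       specimen_coverage = if (n_spec > 0) n_spec_code / n_spec else NA_real_)
}
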