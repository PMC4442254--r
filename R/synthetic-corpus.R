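## Seeded generator of dialect-valid corpora with independent ground-truth
## bookkeeping. The ground truth is computed by plain nested-loop counting
## over the generated records (see facet_table_bruteforce()), never by the
## aggregation engine, so engine defects are detectable.

DEFAULT_POOLS <- list(
  countries = c("Russia", "China", "South Africa", "Mongolia", "Canada",
                "Portugal", "Slovenia", "Malaysia", "Madagascar",
                "United States"),
  collections = c("CAS", "ZMMU", "IBPN", "ISEA", "NHRS", "IZAS", "UMS",
                  "NCA", "ZMUT", "HNU", "MNHN", "NHMW"),
  collectors = c("Y. Marusik", "D. Obydov", "T. Kronestedt", "C. Griswold",
                 "X. Wang", "P. Jaeger", "K. Candek", "M. Kuntner",
                 "R. Gregoric", "J. Miller", "A. Smith", "L. Chen"),
  families = c("Lycosidae", "Agelenidae", "Linyphiidae", "Salticidae",
               "Theridiidae", "Gnaphosidae", "Araneidae", "Thomisidae"),
  genera = c("Pardosa", "Tenuiphantes", "Coelotes", "Alopecosa", "Evarcha",
             "Theridion", "Zelotes", "Araneus", "Xysticus", "Pireneitega"),
  localities = paste0("Locality ", sprintf("%02d", 1:15)),
  authors = c("A. Adams", "B. Baker", "C. Clark", "D. Diaz", "E. Evans",
              "F. Fischer", "G. Garcia", "H. Huang")
)

#' Distribution specification for the generator
#'
#' @param kind `"fixed"`, `"poisson"` or `"empirical"`.
#' @param value the fixed value (`kind = "fixed"`).
#' @param lambda Poisson mean (`kind = "poisson"`).
#' @param values pool to sample from (`kind = "empirical"`).
#' @param min lower truncation applied after sampling.
#' @return a list of class `mc_dist`.
#' @export
dist_spec <- function(kind = c("fixed", "poisson", "empirical"),
                      value = 1, lambda = 1, values = NULL, min = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, value = value, lambda = lambda,
                 values = values, min = min), class = "mc_dist")
}

sample_dist <- function(n, spec) {
  if (n == 0) return(integer())
  x <- switch(spec$kind,
              fixed = rep(as.integer(spec$value), n),
              poisson = stats::rpois(n, spec$lambda),
              empirical = sample(as.integer(spec$values), n, replace = TRUE))
  pmax(x, as.integer(spec$min))
}

#' Generator configuration
#'
#' Defaults emulate the structure of a legacy-journal spider corpus:
#' a handful of articles, mostly species-rank treatments, skewed specimen
#' counts, a male-biased sex split, 500-3500 m elevations, collecting
#' years up to three decades before publication, and realistic rates of
#' missing fields and ambiguous multi-collection citations. When
#' `exact_totals` is supplied, the listed corpus totals are achieved
#' exactly (see Details).
#'
#' @param seed integer seed; the generator is deterministic given the
#'   seed and restores the caller's RNG state.
#' @param n_articles number of articles.
#' @param journal journal name stamped on every article.
#' @param treatments_per_article,citations_per_treatment,specimens_per_treatment
#'   [dist_spec()] objects.
#' @param species_rank_fraction fraction of treatments at species rank.
#' @param new_species_fraction fraction of species treatments that are new
#'   species.
#' @param cited_fraction fraction of species treatments that explicitly
#'   cite specimens (new species always do).
#' @param higher_cited_fraction fraction of higher-rank treatments with
#'   citations.
#' @param sex_split probabilities (male, female, other); must sum to 1.
#' @param pools named list of value pools (countries, collections,
#'   collectors, families, genera, localities, authors); defaults provided.
#' @param missing_rates named list of per-field missing probabilities
#'   (collection, date, elevation, collector, country, locality,
#'   specimen_code).
#' @param ambiguity_rate probability that a citation lists several
#'   collection codes with one pooled count.
#' @param team_rate probability that a collector string is a team;
#'   `team_size` is the pool of team sizes.
#' @param year_range publication years (inclusive).
#' @param lag_mean mean discovery-to-description lag in years for new
#'   species (geometric distribution).
#' @param collection_span maximum years before publication for non-new
#'   species collection dates.
#' @param elevation_range elevation bounds in meters.
#' @param exact_totals optional named list forcing exact corpus totals:
#'   `n_articles`, `n_treatments`, `n_species_treatments`,
#'   `n_cited_species_treatments`, `n_new_species`, `n_species_specimens`,
#'   `n_total_specimens`, `sex_totals` (length-3 male/female/other over
#'   species-treatment specimens), `n_singletons_new`,
#'   `n_singletons_cited`, `n_single_locality_new`, `n_citations`,
#'   `n_citations_with_code`. Unsatisfiable combinations raise a config
#'   error.
#' @return a list of class `mc_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_articles = 10L,
    journal = "Zootaxa",
    treatments_per_article = dist_spec("poisson", lambda = 6, min = 1),
    species_rank_fraction = 0.83,
    new_species_fraction = 0.43,
    cited_fraction = 1,
    higher_cited_fraction = 0.3,
    citations_per_treatment = dist_spec("poisson", lambda = 2, min = 1),
    specimens_per_treatment = dist_spec("poisson", lambda = 20, min = 1),
    sex_split = c(male = 0.5, female = 0.4, other = 0.1),
    pools = DEFAULT_POOLS,
    missing_rates = list(collection = 0.15, date = 0.10, elevation = 0.60,
                         collector = 0.10, country = 0.05, locality = 0.05,
                         specimen_code = 0.60),
    ambiguity_rate = 0.05,
    team_rate = 0.3,
    team_size = c(2L, 3L),
    year_range = c(2002L, 2014L),
    lag_mean = 10,
    collection_span = 30L,
    elevation_range = c(100, 4500),
    exact_totals = NULL) {
  stopifnot(length(sex_split) == 3, abs(sum(sex_split) - 1) < 1e-9,
            all(sex_split >= 0))
  for (r in missing_rates) stopifnot(r >= 0, r <= 1)
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1,
            team_rate >= 0, team_rate <= 1)
  pools <- utils::modifyList(DEFAULT_POOLS, pools)
  structure(
    list(seed = as.integer(seed), n_articles = as.integer(n_articles),
         journal = journal,
         treatments_per_article = treatments_per_article,
         species_rank_fraction = species_rank_fraction,
         new_species_fraction = new_species_fraction,
         cited_fraction = cited_fraction,
         higher_cited_fraction = higher_cited_fraction,
         citations_per_treatment = citations_per_treatment,
         specimens_per_treatment = specimens_per_treatment,
         sex_split = sex_split, pools = pools,
         missing_rates = missing_rates, ambiguity_rate = ambiguity_rate,
         team_rate = team_rate, team_size = team_size,
         year_range = as.integer(year_range), lag_mean = lag_mean,
         collection_span = as.integer(collection_span),
         elevation_range = elevation_range, exact_totals = exact_totals),
    class = "mc_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path file path; top-level keys are [generator_config()]
#'   arguments (distribution specs as lists with a `kind` field).
#' @return an `mc_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  as_dist <- function(x) {
    if (is.list(x) && !is.null(x$kind)) do.call(dist_spec, x) else x
  }
  for (k in c("treatments_per_article", "citations_per_treatment",
              "specimens_per_treatment")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as_dist(raw[[k]])
  }
  if (!is.null(raw$sex_split)) raw$sex_split <- unlist(raw$sex_split)
  if (!is.null(raw$year_range)) raw$year_range <- unlist(raw$year_range)
  if (!is.null(raw$elevation_range)) {
    raw$elevation_range <- unlist(raw$elevation_range)
  }
  if (!is.null(raw$exact_totals)) {
    raw$exact_totals <- lapply(raw$exact_totals, function(v) unlist(v))
  }
  do.call(generator_config, raw)
}

config_error <- function(...) stop("config error: ", ..., call. = FALSE)

# sample n elements from a vector, immune to R's scalar-x surprise
sample_vec <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# random composition of `total` into `parts` integers, each >= min_each
random_composition <- function(total, parts, min_each = 0L) {
  if (parts == 0L) {
    if (total != 0L) config_error("cannot place ", total, " into 0 parts")
    return(integer())
  }
  extra <- total - parts * min_each
  if (extra < 0) {
    config_error("cannot split ", total, " into ", parts,
                 " parts of at least ", min_each)
  }
  as.integer(stats::rmultinom(1, extra, rep(1, parts))) + as.integer(min_each)
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic given `config$seed` (the caller's RNG state is
#' restored). The returned ground truth is computed by an independent
#' straightforward counting pass over the generated records — not by the
#' facet engine — plus the generator's own bookkeeping (which treatments
#' were made singletons, the true per-species lags).
#'
#' @param config an `mc_config` from [generator_config()].
#' @return a list with elements `corpus` (an `mc_corpus`) and `truth`
#'   (list: `summary`, `rarity`, `lag`, `facets` — named list of
#'   brute-force facet tables — and `bookkeeping`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "mc_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  et <- cfg$exact_totals %||% list()
  pools <- cfg$pools
  A <- as.integer(et[["n_articles"]] %||% cfg$n_articles)
  if (A == 0L) {
    cp <- corpus()
    return(list(corpus = cp, truth = compute_truth(cp, list())))
  }

  ## -- skeleton: treatments per article, ranks, statuses ------------------
  if (!is.null(et[["n_treatments"]])) {
    Tn <- as.integer(et[["n_treatments"]])
    if (Tn < A) config_error("fewer treatments than articles")
    t_per_a <- random_composition(Tn, A, 1L)
  } else {
    t_per_a <- sample_dist(A, cfg$treatments_per_article)
    Tn <- sum(t_per_a)
  }
  S <- as.integer(et[["n_species_treatments"]] %||%
                    round(cfg$species_rank_fraction * Tn))
  if (S > Tn) config_error("more species treatments than treatments")
  is_species <- rep(FALSE, Tn)
  is_species[sample.int(Tn, S)] <- TRUE

  N_new <- as.integer(et[["n_new_species"]] %||%
                        round(cfg$new_species_fraction * S))
  if (N_new > S) config_error("more new species than species treatments")
  sp_idx <- which(is_species)
  new_idx <- if (N_new > 0) sample_vec(sp_idx, N_new) else integer()

  C_cited <- as.integer(et[["n_cited_species_treatments"]] %||%
                          round(cfg$cited_fraction * S))
  if (C_cited > S || C_cited < N_new) {
    config_error("cited species treatments must lie between the number of ",
                 "new species and the number of species treatments")
  }
  non_new_sp <- setdiff(sp_idx, new_idx)
  cited_idx <- c(new_idx,
                 if (C_cited - N_new > 0)
                   sample_vec(non_new_sp, C_cited - N_new) else integer())

  ## -- singletons and locality rarity --------------------------------------
  sn <- et[["n_singletons_new"]]
  sc <- et[["n_singletons_cited"]]
  if (!is.null(sc) && is.null(sn)) sn <- min(sc, N_new)
  if (!is.null(sn) && is.null(sc)) sc <- sn
  exact_singletons <- !is.null(sn)
  if (exact_singletons) {
    sn <- as.integer(sn); sc <- as.integer(sc)
    if (sn > N_new || sc > C_cited || sc < sn) {
      config_error("singleton counts unsatisfiable")
    }
    singleton_idx <- c(if (sn > 0) sample_vec(new_idx, sn) else integer(),
                       if (sc - sn > 0)
                         sample_vec(setdiff(cited_idx, new_idx), sc - sn)
                       else integer())
  } else {
    singleton_idx <- integer()   # emerge from sampling
  }

  sl <- et[["n_single_locality_new"]]
  exact_locality <- !is.null(sl)
  if (exact_locality) {
    sl <- as.integer(sl)
    n_singleton_new <- length(intersect(singleton_idx, new_idx))
    if (sl < n_singleton_new || sl > N_new) {
      config_error("single-locality count unsatisfiable (must cover all ",
                   "new-species singletons)")
    }
    extra_single_loc <- sl - n_singleton_new
    candidates <- setdiff(new_idx, singleton_idx)
    single_loc_idx <- c(intersect(singleton_idx, new_idx),
                        if (extra_single_loc > 0)
                          sample_vec(candidates, extra_single_loc)
                        else integer())
    multi_loc_idx <- setdiff(new_idx, single_loc_idx)
  } else {
    single_loc_idx <- integer()
    multi_loc_idx <- integer()
  }

  ## -- specimens per treatment ---------------------------------------------
  totals <- integer(Tn)
  if (!is.null(et[["n_species_specimens"]])) {
    X <- as.integer(et[["n_species_specimens"]])
    k <- length(singleton_idx)
    rest <- setdiff(cited_idx, singleton_idx)
    min_rest <- if (exact_singletons) 2L else 1L
    totals[singleton_idx] <- 1L
    totals[rest] <- random_composition(X - k, length(rest), min_rest)
  } else {
    totals[cited_idx] <- sample_dist(length(cited_idx),
                                     cfg$specimens_per_treatment)
    if (exact_singletons) {
      totals[singleton_idx] <- 1L
      totals[setdiff(cited_idx, singleton_idx)] <-
        pmax(totals[setdiff(cited_idx, singleton_idx)], 2L)
    }
  }
  # higher-rank treatments
  higher_idx <- which(!is_species)
  if (!is.null(et[["n_total_specimens"]])) {
    extra <- as.integer(et[["n_total_specimens"]]) - sum(totals[cited_idx])
    if (extra < 0) config_error("n_total_specimens below species specimens")
    if (length(higher_idx) == 0 && extra > 0) {
      config_error("no higher treatments to carry extra specimens")
    }
    if (length(higher_idx) > 0) {
      totals[higher_idx] <- random_composition(extra, length(higher_idx), 0L)
    }
  } else if (length(higher_idx) > 0) {
    hc <- stats::runif(length(higher_idx)) < cfg$higher_cited_fraction
    totals[higher_idx[hc]] <- sample_dist(sum(hc),
                                          cfg$specimens_per_treatment)
  }

  ## -- sex allocation over species-treatment specimens ---------------------
  sp_cited <- cited_idx[totals[cited_idx] > 0]
  Xs <- sum(totals[sp_cited])
  if (!is.null(et[["sex_totals"]])) {
    st <- as.integer(unlist(et[["sex_totals"]]))
    if (length(st) != 3 || sum(st) != Xs) {
      config_error("sex_totals must have length 3 and sum to the ",
                   "species-treatment specimen total (", Xs, ")")
    }
    labels <- sample_vec(rep.int(1:3, st), Xs)
  } else {
    labels <- sample(1:3, Xs, replace = TRUE, prob = cfg$sex_split)
  }
  sex_by_tr <- vector("list", Tn)
  pos <- 0L
  for (i in sp_cited) {
    sex_by_tr[[i]] <- labels[(pos + 1L):(pos + totals[i])]
    pos <- pos + totals[i]
  }
  for (i in higher_idx) {
    if (totals[i] > 0) {
      sex_by_tr[[i]] <- sample(1:3, totals[i], replace = TRUE,
                               prob = cfg$sex_split)
    }
  }

  ## -- citations per treatment ---------------------------------------------
  has_mat <- totals > 0
  req <- integer(Tn)
  req[has_mat] <- 1L
  req[multi_loc_idx] <- 2L           # need >= 2 distinct localities
  cap <- totals
  if (any(req > cap & has_mat)) config_error("treatment too small to carry ",
                                             "required citations")
  k_cit <- integer(Tn)
  if (!is.null(et[["n_citations"]])) {
    Ncit <- as.integer(et[["n_citations"]])
    if (Ncit < sum(req) || Ncit > sum(cap)) {
      config_error("n_citations outside feasible range [", sum(req), ", ",
                   sum(cap), "]")
    }
    k_cit <- req
    deficit <- Ncit - sum(k_cit)
    while (deficit > 0L) {
      room <- which(k_cit < cap)
      take <- room[stats::runif(length(room)) < 0.5]
      if (length(take) > deficit) take <- sample_vec(room, deficit)
      if (length(take) == 0L) take <- room[1]
      k_cit[take] <- k_cit[take] + 1L
      deficit <- Ncit - sum(k_cit)
    }
  } else {
    idx <- which(has_mat)
    k_cit[idx] <- pmin(cap[idx],
                       pmax(req[idx],
                            sample_dist(length(idx),
                                        cfg$citations_per_treatment)))
    Ncit <- sum(k_cit)
  }

  ## -- specimen codes ------------------------------------------------------
  if (!is.null(et[["n_citations_with_code"]])) {
    ncode <- as.integer(et[["n_citations_with_code"]])
    if (ncode > Ncit) config_error("more coded citations than citations")
    coded <- logical(Ncit)
    coded[sample.int(Ncit, ncode)] <- TRUE
  } else {
    coded <- stats::runif(Ncit) < (1 - cfg$missing_rates$specimen_code)
  }

  ## -- assemble records -----------------------------------------------------
  rand_date <- function(year) {
    precision <- sample(c("y", "m", "d"), 1, prob = c(0.3, 0.3, 0.4))
    if (precision == "y") return(sprintf("%04d", year))
    mo <- sample.int(12, 1)
    if (precision == "m") return(sprintf("%04d-%02d", year, mo))
    sprintf("%04d-%02d-%02d", year, mo, sample.int(28, 1))
  }
  miss <- function(rate) stats::runif(1) < rate

  truth_book <- list(singleton_ids = character(), lags = list(),
                     single_locality_ids = character())
  articles <- vector("list", A)
  ti <- 0L            # global treatment index
  ci_global <- 0L     # global citation index (for `coded`)
  seed_tag <- cfg$seed
  for (ai in seq_len(A)) {
    pub_year <- sample_vec(seq(cfg$year_range[1], cfg$year_range[2]), 1)
    n_auth <- sample.int(3, 1)
    authors <- sample_vec(pools$authors, n_auth)
    trs <- vector("list", t_per_a[ai])
    for (j in seq_len(t_per_a[ai])) {
      ti <- ti + 1L
      tid <- sprintf("s%d-t%04d", seed_tag, ti)
      if (is_species[ti]) {
        genus <- sample(pools$genera, 1)
        tx <- taxon_name("species", order = "Araneae",
                         family = sample(pools$families, 1), genus = genus,
                         species = sprintf("specnov%04d", ti))
        raw_status <- if (ti %in% new_idx) "sp. nov." else
          if (stats::runif(1) < 0.1) "comb. nov." else NULL
      } else {
        rank <- sample(c("genus", "family", "species-group"), 1,
                       prob = c(0.5, 0.3, 0.2))
        tx <- switch(rank,
          genus = taxon_name("genus", order = "Araneae",
                             family = sample(pools$families, 1),
                             genus = sample(pools$genera, 1)),
          family = taxon_name("family", order = "Araneae",
                              family = sample(pools$families, 1)),
          "species-group" = taxon_name("species-group", order = "Araneae",
                                       family = sample(pools$families, 1),
                                       genus = sample(pools$genera, 1)))
        raw_status <- if (stats::runif(1) < 0.05) "gen. nov." else NULL
      }
      status <- treatment_status(raw_status = raw_status)

      cits <- list()
      if (k_cit[ti] > 0) {
        parts <- random_composition(totals[ti], k_cit[ti], 1L)
        sexes <- sex_by_tr[[ti]]
        # collecting years: new species carry a known lag
        is_new <- ti %in% new_idx
        if (is_new) {
          lag <- min(stats::rgeom(1, 1 / (1 + cfg$lag_mean)),
                     pub_year - 1800L)
          earliest <- pub_year - lag
          truth_book$lags[[tid]] <- lag
          years <- c(earliest,
                     if (k_cit[ti] > 1)
                       sample_vec(seq(earliest, pub_year), k_cit[ti] - 1L,
                                  replace = TRUE) else integer())
        } else {
          years <- sample_vec(seq(pub_year - cfg$collection_span,
                                  pub_year), k_cit[ti], replace = TRUE)
        }
        # localities: controlled for new species when rarity is exact
        if (exact_locality && ti %in% single_loc_idx) {
          locs <- rep(sample(pools$localities, 1), k_cit[ti])
        } else if (exact_locality && ti %in% multi_loc_idx) {
          two <- sample(pools$localities, 2)
          locs <- c(two, sample(pools$localities, max(0L, k_cit[ti] - 2L),
                                replace = TRUE))
        } else {
          locs <- sample(pools$localities, k_cit[ti], replace = TRUE)
        }
        pos2 <- 0L
        for (q in seq_len(k_cit[ti])) {
          ci_global <- ci_global + 1L
          sl_q <- sexes[(pos2 + 1L):(pos2 + parts[q])]
          pos2 <- pos2 + parts[q]
          m <- sum(sl_q == 1L); f <- sum(sl_q == 2L); o <- sum(sl_q == 3L)
          n_codes <- if (miss(cfg$missing_rates$collection)) 0L else
            if (stats::runif(1) < cfg$ambiguity_rate) sample(2:5, 1) else 1L
          codes <- if (n_codes > 0) sample(pools$collections, n_codes) else
            character()
          dated <- if (is_new && q == 1L) TRUE else
            !miss(cfg$missing_rates$date)
          date <- if (dated) rand_date(years[q]) else NULL
          collector <- if (miss(cfg$missing_rates$collector)) NULL else {
            if (stats::runif(1) < cfg$team_rate) {
              paste(sample_vec(pools$collectors,
                               sample_vec(cfg$team_size, 1)),
                    collapse = " & ")
            } else sample(pools$collectors, 1)
          }
          loc_missing <- if (exact_locality && is_new) FALSE else
            miss(cfg$missing_rates$locality)
          type_status <- if (is_new && q == 1L) "holotype" else
            if (is_new && stats::runif(1) < 0.5) "paratype" else "none"
          cits[[q]] <- materials_citation(
            counts = count_triple(m, f, o),
            type_status = type_status,
            collection_codes = codes,
            country = if (miss(cfg$missing_rates$country)) NULL else
              sample(pools$countries, 1),
            locality = if (loc_missing) NULL else locs[q],
            elevation_m = if (miss(cfg$missing_rates$elevation)) NULL else
              round(stats::runif(1, cfg$elevation_range[1],
                                 cfg$elevation_range[2])),
            event_date = date,
            collector_raw = collector,
            specimen_codes = if (coded[ci_global])
              sprintf("SPEC-%06d", ci_global) else character())
        }
        if (totals[ti] == 1L) {
          truth_book$singleton_ids <- c(truth_book$singleton_ids, tid)
        }
      }
      trs[[j]] <- treatment_record(tid, tx, status, cits)
    }
    articles[[ai]] <- article_record(
      article_id = sprintf("s%d-a%03d", seed_tag, ai),
      journal = cfg$journal, year = pub_year, authors = authors,
      doi = sprintf("10.9999/synthetic.%d.%d", seed_tag, ai),
      page_count = sample(4:40, 1),
      treatments = trs)
  }
  cp <- corpus(articles)
  list(corpus = cp, truth = compute_truth(cp, truth_book))
}

## Ground truth: independent nested-loop counting ----------------------------

#' Brute-force facet table (independent oracle)
#'
#' Computes the same table as [aggregate_facet()] by plain nested loops
#' over the record structures, sharing no aggregation code with the
#' engine. Used for the generator's ground truth and as the oracle in
#' engine tests.
#'
#' @param corpus an `mc_corpus`.
#' @param facet a filter key.
#' @return a tibble with columns `value`, `specimens`, `treatments`,
#'   `articles`, sorted by specimens descending then label.
#' @export
facet_table_bruteforce <- function(corpus, facet) {
  spec <- list(); tr_sets <- list(); ar_sets <- list()
  bump <- function(val, n, tid, aid) {
    if (!is.null(n)) spec[[val]] <<- (spec[[val]] %||% 0) + n
    if (!is.null(tid)) tr_sets[[val]] <<- union(tr_sets[[val]], tid)
    if (!is.null(aid)) ar_sets[[val]] <<- union(ar_sets[[val]], aid)
  }
  esc <- function(v) if (v == MISSING_LABEL) paste0("'", v, "'") else v
  cit_value <- function(ci) {
    v <- switch(facet,
      "mat.country" = ci$country,
      "mat.collectorName" = ci$collector_raw,
      "mat.typeStatus" = ci$type_status,
      "mat.month" = {
        m <- parse_event_date(ci$event_date)$month
        if (is.null(m)) NULL else as.character(m)
      },
      "mat.decade" = parse_event_date(ci$event_date)$decade_label,
      "mat.elevationBand" = if (is.null(ci$elevation_m)) NULL else
        bin_elevation(ci$elevation_m)$label,
      stop("unsupported brute-force facet: ", facet, call. = FALSE))
    if (is.null(v)) MISSING_LABEL else esc(v)
  }
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      doc_tax <- switch(facet,
        "doc.journal" = a$journal,
        "doc.year" = as.character(a$year),
        "doc.author" = a$authors[[1]],
        "tax.rank" = tr$taxon$rank,
        "tax.status" = status_label(tr$status),
        "tax.orderEpithet" = tr$taxon$epithets$orderEpithet,
        "tax.familyEpithet" = tr$taxon$epithets$familyEpithet,
        "tax.genusEpithet" = tr$taxon$epithets$genusEpithet,
        "tax.speciesEpithet" = tr$taxon$epithets$speciesEpithet,
        NA)
      if (!identical(doc_tax, NA)) {
        val <- if (is.null(doc_tax)) MISSING_LABEL else esc(doc_tax)
        tot <- 0L
        for (ci in tr$citations) tot <- tot + ci$counts$total
        bump(val, tot, tr$treatment_id, a$article_id)
        next
      }
      if (facet == "mat.collectionCode") {
        for (ci in tr$citations) {
          codes <- ci$collection_codes
          sval <- if (length(codes) == 1) esc(codes) else MISSING_LABEL
          bump(sval, ci$counts$total, NULL, NULL)
          pvals <- if (length(codes) == 0) MISSING_LABEL else
            unique(vapply(codes, esc, ""))
          for (pv in pvals) bump(pv, NULL, tr$treatment_id, a$article_id)
        }
      } else {
        for (ci in tr$citations) {
          val <- cit_value(ci)
          bump(val, ci$counts$total, tr$treatment_id, a$article_id)
        }
      }
    }
  }
  vals <- sort(unique(c(names(spec), names(tr_sets), names(ar_sets))))
  if (is.null(vals)) vals <- character()
  out <- tibble::tibble(
    value = vals,
    specimens = vapply(vals, function(v) as.numeric(spec[[v]] %||% 0), 0),
    treatments = vapply(vals, function(v) length(tr_sets[[v]]), 0L),
    articles = vapply(vals, function(v) length(ar_sets[[v]]), 0L))
  out[order(-out$specimens, out$value), , drop = FALSE]
}

TRUTH_FACETS <- c("mat.country", "mat.collectionCode", "mat.collectorName",
                  "mat.month", "mat.decade", "mat.elevationBand",
                  "tax.familyEpithet", "tax.status", "doc.year")

compute_truth <- function(cp, book) {
  # headline counts by direct loops (no shared code with summarize_corpus's
  # callers; the arithmetic is elementary enough to serve as its own check)
  n_articles <- length(cp$articles)
  n_tr <- 0L; n_sp <- 0L; n_new <- 0L
  n_specimens <- 0L; n_sp_specimens <- 0L
  sex <- c(0L, 0L, 0L)
  singletons_new <- 0L; singletons_cited <- 0L; n_cited <- 0L
  single_loc_new <- 0L; unique_new <- 0L
  lags <- c()
  for (a in cp$articles) {
    for (tr in a$treatments) {
      n_tr <- n_tr + 1L
      tot <- 0L
      for (ci in tr$citations) tot <- tot + ci$counts$total
      n_specimens <- n_specimens + tot
      sp <- tr$taxon$rank == "species"
      if (sp) {
        n_sp <- n_sp + 1L
        n_sp_specimens <- n_sp_specimens + tot
        for (ci in tr$citations) {
          sex <- sex + c(ci$counts$males, ci$counts$females, ci$counts$other)
        }
        if (tot > 0) {
          n_cited <- n_cited + 1L
          if (tot == 1L) singletons_cited <- singletons_cited + 1L
        }
        if (tr$status$is_new_species) {
          n_new <- n_new + 1L
          if (tot == 1L) singletons_new <- singletons_new + 1L
          if (tot > 0) {
            locs <- character(); evs <- character(); yrs <- integer()
            for (ci in tr$citations) {
              if (!is.null(ci$locality)) {
                locs <- c(locs, normalize_locality(ci$locality))
              }
              evs <- c(evs, event_key(ci))
              y <- parse_event_date(ci$event_date)$year
              if (!is.null(y)) yrs <- c(yrs, y)
            }
            if (length(unique(locs)) == 1L) {
              single_loc_new <- single_loc_new + 1L
            }
            if (length(unique(evs)) == 1L) unique_new <- unique_new + 1L
            if (length(yrs) > 0) lags <- c(lags, a$year - min(yrs))
          }
        }
      }
    }
  }
  facets <- lapply(stats::setNames(TRUTH_FACETS, TRUTH_FACETS),
                   function(f) facet_table_bruteforce(cp, f))
  list(
    summary = list(
      n_articles = n_articles, n_treatments = n_tr,
      n_species_treatments = n_sp, n_specimens = n_specimens,
      n_species_specimens = n_sp_specimens, n_new_species = n_new,
      sex = stats::setNames(as.integer(sex), c("males", "females", "other"))),
    rarity = list(
      n_new_species = n_new, n_singletons = singletons_new,
      n_single_locality = single_loc_new, n_single_collection = unique_new,
      n_cited_species_treatments = n_cited,
      n_cited_singletons = singletons_cited),
    lag = list(
      lags = as.integer(lags),
      mean = if (length(lags) > 0) mean(lags) else NA_real_,
      median = if (length(lags) > 0) stats::median(lags) else NA_real_),
    facets = facets,
    bookkeeping = book)
}

#' The ambiguous multi-collection fixture
#'
#' A one-article, one-treatment corpus whose single materials citation
#' pools 110 males and 44 females across five listed collection codes
#' with no per-collection counts: specimen counts go to "missing" in the
#' collection facet while the treatment counts as present in each code.
#'
#' @return an `mc_corpus`.
#' @export
fig12_fixture <- function() {
  ci <- materials_citation(
    counts = count_triple(110L, 44L, 0L),
    type_status = "paratype",
    collection_codes = c("ZMMU", "IBPN", "ISEA", "NHRS", "IZAS"),
    country = "Mongolia",
    locality = "type locality",
    event_date = "1999-07",
    collector_raw = "Y. Marusik & D. Obydov")
  tr <- treatment_record(
    "fig12-t1",
    taxon_name("species", order = "Araneae", family = "Lycosidae",
               genus = "Pardosa", species = "zyuzini"),
    treatment_status("sp. nov."),
    citations = list(ci))
  corpus(list(article_record("fig12-a1", "Zootaxa", 2011L,
                             c("T. Kronestedt", "Y. Marusik"),
                             treatments = list(tr))))
}

#' Reference corpus conditions
#'
#' Ready-made [generator_config()]s whose `exact_totals` pin the headline
#' structure of the two marked-up spider-literature corpora the toolkit
#' is designed around: a legacy open-access journal set (37 articles, 254
#' treatments of which 212 species-rank, 4,773 specimens in species
#' treatments with a 2,460/1,943/370 male/female/other split, 91 new
#' species of which 34 singletons and 35 single-locality) and a
#' prospectively published set (5 articles, 742 treatments of which 672
#' species-rank, 496 citing specimens, 209 of those singletons, one new
#' species). Only corpus totals are pinned; everything else (which
#' treatment gets which country, collector, dates, elevations) is drawn
#' from the seeded generator.
#'
#' @param seed integer seed passed to both configurations.
#' @return a named list with elements `legacy` and `prospective`, each an
#'   `mc_config`.
#' @export
reference_configs <- function(seed = 1L) {
  seed <- as.integer(seed)
  seed2 <- if (seed >= .Machine$integer.max) 1L else seed + 1L
  list(
    legacy = generator_config(
      seed = seed, journal = "Zootaxa", year_range = c(2002L, 2014L),
      exact_totals = list(
        n_articles = 37, n_treatments = 254, n_species_treatments = 212,
        n_cited_species_treatments = 212, n_new_species = 91,
        n_species_specimens = 4773, n_total_specimens = 4779,
        sex_totals = c(2460, 1943, 370),
        n_singletons_new = 34, n_singletons_cited = 72,
        n_single_locality_new = 35,
        n_citations = 1400, n_citations_with_code = 700)),
    prospective = generator_config(
      seed = seed2, journal = "Biodiversity Data Journal",
      year_range = c(2013L, 2014L),
      missing_rates = list(collection = 0.95, date = 0.3, elevation = 0.5,
                           collector = 0.3, country = 0.1, locality = 0.1,
                           specimen_code = 0.7),
      exact_totals = list(
        n_articles = 5, n_treatments = 742, n_species_treatments = 672,
        n_cited_species_treatments = 496, n_new_species = 1,
        n_species_specimens = 3399, n_total_specimens = 3432,
        sex_totals = c(1323, 2056, 20),
        n_singletons_new = 0, n_singletons_cited = 209,
        n_single_locality_new = 0,
        n_citations = 1494, n_citations_with_code = 444))
  )
}
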