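#' matcite: specimen data from taxonomic treatments
#'
#' Parse, normalise, aggregate and summarise the materials citations
#' (cited specimen lots) of taxonomic treatments. See the package
#' vignette `vignette("matcite-methods")` for the underlying model.
#'
#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Controlled vocabularies -------------------------------------------------

#' Type-status vocabulary
#'
#' The fixed seven-member vocabulary for the nomenclatural status of a
#' cited specimen lot. "Primary types" are the name-bearing categories:
#' holotype, syntype, lectotype and neotype.
#'
#' @export
TYPE_STATUS_LEVELS <- c(
  "holotype", "paratype", "syntype", "lectotype", "neotype", "allotype",
  "none"
)

#' @rdname TYPE_STATUS_LEVELS
#' @export
PRIMARY_TYPE_LEVELS <- c("holotype", "syntype", "lectotype", "neotype")

#' Taxonomic rank vocabulary used for treatments
#' @export
RANK_LEVELS <- c(
  "order", "family", "genus", "species", "species-group", "other-higher"
)

#' Is a type status a primary (name-bearing) type?
#'
#' @param status character vector of type-status tokens; each must be one
#'   of [TYPE_STATUS_LEVELS].
#' @return logical vector, `TRUE` exactly for holotype, syntype, lectotype
#'   and neotype.
#' @examples
#' is_primary_type(c("holotype", "paratype", "none"))
#' @export
is_primary_type <- function(status) {
  bad <- setdiff(unique(status), TYPE_STATUS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown type status token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  status %in% PRIMARY_TYPE_LEVELS
}

## Constructors -------------------------------------------------------------

#' Taxon name with rank-keyed epithets
#'
#' @param rank one of [RANK_LEVELS].
#' @param order,family,genus,species epithets for the named ranks (character
#'   or `NULL`). Epithets must be present for all known ranks at or above
#'   `rank`; the species epithet is present iff `rank == "species"`.
#' @param authority optional authority string.
#' @return an object of class `mc_taxon`.
#' @export
taxon_name <- function(rank, order = NULL, family = NULL, genus = NULL,
                       species = NULL, authority = NULL) {
  rank <- match.arg(rank, RANK_LEVELS)
  if (rank == "species" && is.null(species)) {
    stop("species-rank taxon requires a species epithet", call. = FALSE)
  }
  if (rank != "species" && !is.null(species)) {
    stop("species epithet given for non-species rank '", rank, "'",
         call. = FALSE)
  }
  structure(
    list(rank = rank,
         epithets = list(orderEpithet = order, familyEpithet = family,
                         genusEpithet = genus, speciesEpithet = species),
         authority = authority),
    class = "mc_taxon"
  )
}

#' Treatment status flags
#'
#' Flags are derived from `raw_status` when it is supplied (vocabulary:
#' "sp. nov."/"new species", "comb. nov."/"new combination",
#' "gen. nov."/"new genus"); otherwise they may be set directly.
#'
#' @param raw_status optional verbatim status string.
#' @param is_new_species,is_new_combination,is_new_higher_taxon logical
#'   flags; ignored when `raw_status` is given.
#' @return an object of class `mc_status`.
#' @export
treatment_status <- function(raw_status = NULL, is_new_species = FALSE,
                             is_new_combination = FALSE,
                             is_new_higher_taxon = FALSE) {
  if (!is.null(raw_status)) {
    flags <- status_flags_from_raw(raw_status)
    is_new_species <- flags$is_new_species
    is_new_combination <- flags$is_new_combination
    is_new_higher_taxon <- flags$is_new_higher_taxon
  }
  if (is_new_species && is_new_higher_taxon) {
    stop("a treatment cannot be both a new species and a new higher taxon",
         call. = FALSE)
  }
  # canonical token so that flag-built statuses serialize round-trip exactly
  if (is.null(raw_status)) {
    if (isTRUE(is_new_species)) raw_status <- "sp. nov."
    else if (isTRUE(is_new_combination)) raw_status <- "comb. nov."
    else if (isTRUE(is_new_higher_taxon)) raw_status <- "gen. nov."
  }
  structure(
    list(is_new_species = isTRUE(is_new_species),
         is_new_combination = isTRUE(is_new_combination),
         is_new_higher_taxon = isTRUE(is_new_higher_taxon),
         raw_status = raw_status),
    class = "mc_status"
  )
}

status_flags_from_raw <- function(raw) {
  key <- tolower(trimws(raw))
  list(
    is_new_species = key %in% c("sp. nov.", "new species"),
    is_new_combination = key %in% c("comb. nov.", "new combination"),
    is_new_higher_taxon = key %in% c("gen. nov.", "new genus")
  )
}

#' Reconciled male/female/other specimen counts
#'
#' The count triple always satisfies `total = males + females + other`;
#' use [reconcile_counts()] to build one from a verbatim sex field and an
#' individualCount.
#'
#' @param males,females,other non-negative integer counts.
#' @return an object of class `mc_counts` with fields `males`, `females`,
#'   `other`, `total`.
#' @export
count_triple <- function(males = 0L, females = 0L, other = 0L) {
  m <- as.integer(males); f <- as.integer(females); o <- as.integer(other)
  stopifnot(m >= 0, f >= 0, o >= 0)
  structure(list(males = m, females = f, other = o, total = m + f + o),
            class = "mc_counts")
}

#' One materials citation (cited specimen lot)
#'
#' @param counts an `mc_counts` object (see [count_triple()],
#'   [reconcile_counts()]).
#' @param type_status one of [TYPE_STATUS_LEVELS] (default "none").
#' @param collection_codes character vector of institutional collection
#'   codes (0, 1 or many; several codes with a single pooled count is the
#'   ambiguous-depository pattern).
#' @param country,locality optional verbatim strings.
#' @param elevation_m optional elevation in meters, within \[0, 9000\].
#' @param event_date optional ISO-8601 date at year, month or day precision
#'   ("1999", "1999-07", "1999-07-15").
#' @param collector_raw optional verbatim collector string.
#' @param specimen_codes character vector of specimen codes.
#' @return an object of class `mc_citation`. `collector_team` is derived
#'   from `collector_raw` via [split_collectors()].
#' @export
materials_citation <- function(counts = count_triple(),
                               type_status = "none",
                               collection_codes = character(),
                               country = NULL, locality = NULL,
                               elevation_m = NULL, event_date = NULL,
                               collector_raw = NULL,
                               specimen_codes = character()) {
  stopifnot(inherits(counts, "mc_counts"))
  type_status <- match.arg(type_status, TYPE_STATUS_LEVELS)
  if (!is.null(elevation_m)) {
    elevation_m <- as.numeric(elevation_m)
    if (is.na(elevation_m) || elevation_m < 0 || elevation_m > 9000) {
      stop("elevation_m must be within [0, 9000]", call. = FALSE)
    }
  }
  team <- if (is.null(collector_raw)) character() else
    split_collectors(collector_raw)
  structure(
    list(counts = counts, type_status = type_status,
         collection_codes = as.character(collection_codes),
         country = country, locality = locality,
         elevation_m = elevation_m, event_date = event_date,
         collector_raw = collector_raw, collector_team = team,
         specimen_codes = as.character(specimen_codes)),
    class = "mc_citation"
  )
}

#' One taxonomic treatment
#'
#' @param treatment_id identifier, unique within a corpus.
#' @param taxon an `mc_taxon`.
#' @param status an `mc_status`.
#' @param citations list of `mc_citation` objects.
#' @return an object of class `mc_treatment`.
#' @export
treatment_record <- function(treatment_id, taxon,
                             status = treatment_status(),
                             citations = list()) {
  stopifnot(is.character(treatment_id), length(treatment_id) == 1,
            inherits(taxon, "mc_taxon"), inherits(status, "mc_status"))
  for (ci in citations) stopifnot(inherits(ci, "mc_citation"))
  structure(
    list(treatment_id = treatment_id, taxon = taxon, status = status,
         citations = citations),
    class = "mc_treatment"
  )
}

#' One publication
#'
#' @param article_id identifier, unique within a corpus.
#' @param journal journal name.
#' @param year publication year in \[1750, 2100\].
#' @param authors non-empty ordered character vector; the first element is
#'   the lead author.
#' @param doi,lsid optional identifiers.
#' @param page_count optional integer.
#' @param treatments list of `mc_treatment` objects.
#' @return an object of class `mc_article`.
#' @export
article_record <- function(article_id, journal, year, authors,
                           doi = NULL, lsid = NULL, page_count = NULL,
                           treatments = list()) {
  year <- as.integer(year)
  if (is.na(year) || year < 1750L || year > 2100L) {
    stop("article year must lie in [1750, 2100]", call. = FALSE)
  }
  authors <- as.character(authors)
  if (length(authors) == 0) stop("authors must be non-empty", call. = FALSE)
  for (tr in treatments) stopifnot(inherits(tr, "mc_treatment"))
  structure(
    list(article_id = as.character(article_id), journal = journal,
         year = year, authors = authors, doi = doi, lsid = lsid,
         page_count = if (is.null(page_count)) NULL else
           as.integer(page_count),
         treatments = treatments),
    class = "mc_article"
  )
}

#' A corpus of articles
#'
#' @param articles list of `mc_article` objects with unique ids.
#' @return an object of class `mc_corpus`.
#' @export
corpus <- function(articles = list()) {
  for (a in articles) stopifnot(inherits(a, "mc_article"))
  structure(list(articles = articles), class = "mc_corpus")
}

#' Merge corpora
#'
#' @param ... `mc_corpus` objects.
#' @return a single `mc_corpus` with the articles of all inputs.
#' @export
merge_corpora <- function(...) {
  parts <- list(...)
  arts <- list()
  for (p in parts) {
    stopifnot(inherits(p, "mc_corpus"))
    arts <- c(arts, p$articles)
  }
  corpus(arts)
}

## Validation ---------------------------------------------------------------

finding <- function(severity, record_id, message) {
  tibble::tibble(severity = severity, record_id = record_id,
                 message = message)
}

#' Validate a corpus against the model invariants
#'
#' Checks, without mutating its input: unique article and treatment ids,
#' count-triple consistency, collector-team/raw coherence, elevation range,
#' year range, species-epithet/rank coherence, known type-status tokens and
#' parseable event dates. Violations are returned as findings, never
#' raised.
#'
#' @param x an `mc_corpus`.
#' @return a tibble with columns `severity` ("error" or "warning"),
#'   `record_id` and `message`; zero rows for a valid corpus.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "mc_corpus"))
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f

  aids <- vapply(x$articles, `[[`, "", "article_id")
  for (d in unique(aids[duplicated(aids)])) {
    add(finding("error", d, "duplicate article_id"))
  }
  tids <- character()
  for (a in x$articles) {
    if (a$year < 1750L || a$year > 2100L) {
      add(finding("error", a$article_id, "article year outside [1750, 2100]"))
    }
    if (length(a$authors) == 0) {
      add(finding("error", a$article_id, "article has no authors"))
    }
    for (tr in a$treatments) {
      if (tr$treatment_id %in% tids) {
        add(finding("error", tr$treatment_id, "duplicate treatment_id"))
      }
      tids <- c(tids, tr$treatment_id)
      tx <- tr$taxon
      if (tx$rank == "species" && is.null(tx$epithets$speciesEpithet)) {
        add(finding("error", tr$treatment_id,
                    "species-rank treatment without species epithet"))
      }
      if (tx$rank != "species" && !is.null(tx$epithets$speciesEpithet)) {
        add(finding("error", tr$treatment_id,
                    "species epithet on non-species rank"))
      }
      if (tr$status$is_new_species && tr$status$is_new_higher_taxon) {
        add(finding("error", tr$treatment_id,
                    "treatment flagged both new species and new higher taxon"))
      }
      for (ci in tr$citations) {
        cid <- tr$treatment_id
        cc <- ci$counts
        if (cc$total != cc$males + cc$females + cc$other) {
          add(finding("error", cid, "count triple total != males+females+other"))
        }
        if (length(ci$collector_team) > 0 && is.null(ci$collector_raw)) {
          add(finding("error", cid,
                      "collector_team non-empty but collector_raw absent"))
        }
        if (length(ci$collector_team) == 0 && !is.null(ci$collector_raw)) {
          add(finding("error", cid,
                      "collector_raw present but collector_team empty"))
        }
        if (!is.null(ci$elevation_m) &&
            (ci$elevation_m < 0 || ci$elevation_m > 9000)) {
          add(finding("error", cid, "elevation_m outside [0, 9000]"))
        }
        if (!ci$type_status %in% TYPE_STATUS_LEVELS) {
          add(finding("error", cid,
                      paste0("unknown type status token: ", ci$type_status)))
        }
        if (!is.null(ci$event_date) &&
            is.null(parse_event_date(ci$event_date)$year)) {
          add(finding("warning", cid,
                      paste0("unparseable event date: ", ci$event_date)))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(severity = character(), record_id = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}

## Show methods and small helpers -------------------------------------------

#' @export
print.mc_corpus <- function(x, ...) {
  n_tr <- sum(vapply(x$articles, function(a) length(a$treatments), 0L))
  n_ci <- sum(vapply(x$articles, function(a) {
    sum(vapply(a$treatments, function(tr) length(tr$citations), 0L))
  }, 0L))
  cat(sprintf("<mc_corpus> %d article(s), %d treatment(s), %d materials citation(s)\n",
              length(x$articles), n_tr, n_ci))
  invisible(x)
}

#' @export
print.mc_citation <- function(x, ...) {
  cat(sprintf("<mc_citation> %dm/%df/%do (total %d)%s%s\n",
              x$counts$males, x$counts$females, x$counts$other,
              x$counts$total,
              if (!is.null(x$country)) paste0(", ", x$country) else "",
              if (length(x$collection_codes) > 0)
                paste0(" [", paste(x$collection_codes, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' @export
print.mc_taxon <- function(x, ...) {
  ep <- Filter(Negate(is.null), x$epithets)
  cat(sprintf("<mc_taxon> rank=%s %s\n", x$rank,
              paste(unlist(ep), collapse = " ")))
  invisible(x)
}

## Internal iteration helpers used across modules
for_each_citation <- function(corpus, fn) {
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      for (ci in tr$citations) fn(a, tr, ci)
    }
  }
  invisible(NULL)
}

n_citations <- function(corpus) {
  n <- 0L
  for (a in corpus$articles) {
    for (tr in a$treatments) n <- n + length(tr$citations)
  }
  n
}
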