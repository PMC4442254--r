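## Filterable faceted aggregation over a corpus.

FILTER_KEYS <- c(
  "doc.journal", "doc.year", "doc.author",
  "tax.rank", "tax.status", "tax.orderEpithet", "tax.familyEpithet",
  "tax.genusEpithet", "tax.speciesEpithet",
  "mat.country", "mat.collectionCode", "mat.collectorName",
  "mat.typeStatus", "mat.month", "mat.decade", "mat.elevationBand"
)

MISSING_LABEL <- "missing"

#' Construct a filter query
#'
#' @param ... named clauses, e.g. `tax.orderEpithet = "Araneae"`; valid
#'   keys are `r paste(FILTER_KEYS, collapse = ", ")`. Clauses combine by
#'   conjunction (logical AND).
#' @param clauses alternatively, a named list of clauses.
#' @return an object of class `mc_query`.
#' @export
filter_query <- function(..., clauses = NULL) {
  cl <- c(list(...), as.list(clauses))
  if (length(cl) > 0 && (is.null(names(cl)) || any(!nzchar(names(cl))))) {
    stop("filter clauses must be named", call. = FALSE)
  }
  bad <- setdiff(names(cl), FILTER_KEYS)
  if (length(bad) > 0) {
    stop("unknown filter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(clauses = lapply(cl, as.character)), class = "mc_query")
}

#' Parse a query string into a filter query
#'
#' The syntax mirrors the dashboard URLs: `FILTER_<key>=<value>` pairs
#' joined by `&`, e.g. `"FILTER_tax.orderEpithet=Araneae"`.
#'
#' @param s query string (empty or `NULL` gives the identity query).
#' @return an `mc_query`.
#' @export
parse_filter_string <- function(s) {
  if (is.null(s) || !nzchar(trimws(s))) return(filter_query())
  parts <- strsplit(trimws(s), "&", fixed = TRUE)[[1]]
  cl <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^FILTER_([^=]+)=(.*)$", p))[[1]]
    if (length(m) != 3) {
      stop("malformed filter clause: '", p,
           "' (expected FILTER_<key>=<value>)", call. = FALSE)
    }
    cl[[m[2]]] <- m[3]
  }
  filter_query(clauses = cl)
}

#' @export
print.mc_query <- function(x, ...) {
  if (length(x$clauses) == 0) {
    cat("<mc_query> (identity)\n")
  } else {
    cat("<mc_query>",
        paste0("FILTER_", names(x$clauses), "=", unlist(x$clauses),
               collapse = " & "), "\n")
  }
  invisible(x)
}

as_mc_corpus <- function(x) {
  stopifnot(inherits(x, "mc_corpus"))
  x
}

status_label <- function(status) {
  if (status$is_new_species) "new species"
  else if (status$is_new_higher_taxon) "new higher taxon"
  else if (status$is_new_combination) "new combination"
  else "none"
}

normalize_band <- function(x) gsub(",", "", gsub("[-—]", "–", x))

normalize_decade <- function(x) sub("s$", "", x)

citation_matches <- function(ci, key, value) {
  switch(key,
    "mat.country" = identical(ci$country, value),
    "mat.collectionCode" = value %in% ci$collection_codes,
    "mat.collectorName" = identical(ci$collector_raw, value),
    "mat.typeStatus" = identical(ci$type_status, value),
    "mat.month" = {
      m <- parse_event_date(ci$event_date)$month
      !is.null(m) && as.character(m) == value
    },
    "mat.decade" = {
      d <- parse_event_date(ci$event_date)$decade
      !is.null(d) && as.character(d) == normalize_decade(value)
    },
    "mat.elevationBand" = {
      if (is.null(ci$elevation_m)) return(FALSE)
      normalize_band(bin_elevation(ci$elevation_m)$label) ==
        normalize_band(value)
    },
    stop("not a citation-level key: ", key, call. = FALSE)
  )
}

treatment_matches <- function(tr, key, value) {
  ep <- tr$taxon$epithets
  switch(key,
    "tax.rank" = identical(tr$taxon$rank, value),
    "tax.status" = {
      want <- value
      fl <- status_flags_from_raw(value)
      if (fl$is_new_species) want <- "new species"
      if (fl$is_new_combination) want <- "new combination"
      if (fl$is_new_higher_taxon) want <- "new higher taxon"
      identical(status_label(tr$status), want)
    },
    "tax.orderEpithet" = identical(ep$orderEpithet, value),
    "tax.familyEpithet" = identical(ep$familyEpithet, value),
    "tax.genusEpithet" = identical(ep$genusEpithet, value),
    "tax.speciesEpithet" = identical(ep$speciesEpithet, value),
    stop("not a treatment-level key: ", key, call. = FALSE)
  )
}

article_matches <- function(a, key, value, author_scope) {
  switch(key,
    "doc.journal" = identical(a$journal, value),
    "doc.year" = as.character(a$year) == value,
    "doc.author" = if (author_scope == "any") value %in% a$authors
                   else identical(a$authors[[1]], value),
    stop("not a document-level key: ", key, call. = FALSE)
  )
}

#' Filter a corpus
#'
#' Document-level clauses (`doc.*`) select articles — `doc.author`
#' matches the lead (first) author unless `author_scope = "any"`;
#' taxon clauses (`tax.*`) select treatments; materials clauses (`mat.*`)
#' select citations within surviving treatments. Clauses combine by
#' conjunction; the empty query is the identity. When materials clauses
#' are present, treatments left without qualifying citations are dropped;
#' when taxon or materials clauses are present, articles left without
#' treatments are dropped.
#'
#' @param corpus an `mc_corpus`.
#' @param query an `mc_query` (see [filter_query()],
#'   [parse_filter_string()]).
#' @param author_scope `"first"` (default, lead author) or `"any"`.
#' @return the filtered `mc_corpus`.
#' @export
apply_filter <- function(corpus, query = filter_query(),
                         author_scope = c("first", "any")) {
  corpus <- as_mc_corpus(corpus)
  author_scope <- match.arg(author_scope)
  if (is.character(query)) query <- parse_filter_string(query)
  stopifnot(inherits(query, "mc_query"))
  cl <- query$clauses
  keys <- names(cl) %||% character()
  doc_keys <- keys[startsWith(keys, "doc.")]
  tax_keys <- keys[startsWith(keys, "tax.")]
  mat_keys <- keys[startsWith(keys, "mat.")]

  out <- list()
  for (a in corpus$articles) {
    ok <- TRUE
    for (k in doc_keys) {
      if (!article_matches(a, k, cl[[k]], author_scope)) { ok <- FALSE; break }
    }
    if (!ok) next
    kept_tr <- list()
    for (tr in a$treatments) {
      tok <- TRUE
      for (k in tax_keys) {
        if (!treatment_matches(tr, k, cl[[k]])) { tok <- FALSE; break }
      }
      if (!tok) next
      if (length(mat_keys) > 0) {
        kept_ci <- Filter(function(ci) {
          all(vapply(mat_keys, function(k) citation_matches(ci, k, cl[[k]]),
                     TRUE))
        }, tr$citations)
        if (length(kept_ci) == 0) next
        tr$citations <- kept_ci
      }
      kept_tr[[length(kept_tr) + 1L]] <- tr
    }
    if (length(kept_tr) == 0 && (length(tax_keys) > 0 || length(mat_keys) > 0)) {
      next
    }
    a$treatments <- kept_tr
    out[[length(out) + 1L]] <- a
  }
  corpus(out)
}

## Flattened citation table ---------------------------------------------------

#' Flatten a corpus to one row per materials citation
#'
#' Treatments without citations contribute one row with
#' `has_citation = FALSE` and zero counts, so that document- and
#' taxon-level facets still see them.
#'
#' @param corpus an `mc_corpus`.
#' @return a tibble used by the aggregation engine.
#' @keywords internal
#' @export
citation_table <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  rows <- list()
  for (a in corpus$articles) {
    first_author <- a$authors[[1]]
    for (tr in a$treatments) {
      ep <- tr$taxon$epithets
      base <- list(
        article_id = a$article_id, journal = a$journal, year = a$year,
        first_author = first_author, treatment_id = tr$treatment_id,
        rank = tr$taxon$rank, status = status_label(tr$status),
        is_new_species = tr$status$is_new_species,
        orderEpithet = ep$orderEpithet %||% NA_character_,
        familyEpithet = ep$familyEpithet %||% NA_character_,
        genusEpithet = ep$genusEpithet %||% NA_character_,
        speciesEpithet = ep$speciesEpithet %||% NA_character_
      )
      if (length(tr$citations) == 0) {
        rows[[length(rows) + 1L]] <- c(base, list(
          has_citation = FALSE, males = 0L, females = 0L, other = 0L,
          total = 0L, type_status = NA_character_,
          collection_codes = list(character()), n_codes = 0L,
          country = NA_character_, locality = NA_character_,
          elevation_m = NA_real_, elev_band = NA_character_,
          event_date = NA_character_, month = NA_integer_,
          decade = NA_integer_, collector_raw = NA_character_,
          collector_team = list(character()),
          specimen_codes = list(character())))
        next
      }
      for (ci in tr$citations) {
        pd <- parse_event_date(ci$event_date)
        rows[[length(rows) + 1L]] <- c(base, list(
          has_citation = TRUE,
          males = ci$counts$males, females = ci$counts$females,
          other = ci$counts$other, total = ci$counts$total,
          type_status = ci$type_status,
          collection_codes = list(ci$collection_codes),
          n_codes = length(ci$collection_codes),
          country = ci$country %||% NA_character_,
          locality = ci$locality %||% NA_character_,
          elevation_m = ci$elevation_m %||% NA_real_,
          elev_band = if (is.null(ci$elevation_m)) NA_character_ else
            bin_elevation(ci$elevation_m)$label,
          event_date = ci$event_date %||% NA_character_,
          month = pd$month %||% NA_integer_,
          decade = pd$decade %||% NA_integer_,
          collector_raw = ci$collector_raw %||% NA_character_,
          collector_team = list(ci$collector_team),
          specimen_codes = list(ci$specimen_codes)))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      article_id = character(), journal = character(), year = integer(),
      first_author = character(), treatment_id = character(),
      rank = character(), status = character(), is_new_species = logical(),
      orderEpithet = character(), familyEpithet = character(),
      genusEpithet = character(), speciesEpithet = character(),
      has_citation = logical(), males = integer(), females = integer(),
      other = integer(), total = integer(), type_status = character(),
      collection_codes = list(), n_codes = integer(), country = character(),
      locality = character(), elevation_m = double(),
      elev_band = character(), event_date = character(), month = integer(),
      decade = integer(), collector_raw = character(),
      collector_team = list(), specimen_codes = list()))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# label shown for a genuine facet value that collides with the reserved row
escape_missing <- function(x) {
  ifelse(!is.na(x) & x == MISSING_LABEL, paste0("'", MISSING_LABEL, "'"), x)
}

facet_value_column <- function(tab, facet) {
  v <- switch(facet,
    "doc.journal" = tab$journal,
    "doc.year" = as.character(tab$year),
    "doc.author" = tab$first_author,
    "tax.rank" = tab$rank,
    "tax.status" = tab$status,
    "tax.orderEpithet" = tab$orderEpithet,
    "tax.familyEpithet" = tab$familyEpithet,
    "tax.genusEpithet" = tab$genusEpithet,
    "tax.speciesEpithet" = tab$speciesEpithet,
    "mat.country" = tab$country,
    "mat.collectorName" = tab$collector_raw,
    "mat.typeStatus" = tab$type_status,
    "mat.month" = as.character(tab$month),
    "mat.decade" = ifelse(is.na(tab$decade), NA_character_,
                          paste0(tab$decade, "s")),
    "mat.elevationBand" = tab$elev_band,
    stop("unknown facet: ", facet, call. = FALSE)
  )
  escape_missing(v)
}

#' Faceted aggregation
#'
#' Counts specimens, distinct treatments and distinct articles per value
#' of one facet, with an explicit reserved `"missing"` row for records
#' lacking the facet field. For the collection-code facet, a citation
#' listing several collection codes with a single pooled count (the
#' ambiguous-depository pattern) contributes its whole specimen total to
#' `"missing"` — the per-institution split is unknown — while its
#' treatment and article count as present in *each* listed code.
#'
#' @param corpus an `mc_corpus` (typically the output of [apply_filter()]).
#' @param facet one of the filter keys (see [filter_query()]).
#' @param measure which measure orders the table: `"specimens"` (default),
#'   `"treatments"` or `"articles"`. All three columns are always
#'   returned; rows sort by the chosen measure descending, ties broken by
#'   label ascending.
#' @return an `mc_facet_table`: a tibble with columns `value`,
#'   `specimens`, `treatments`, `articles`.
#' @export
aggregate_facet <- function(corpus, facet,
                            measure = c("specimens", "treatments",
                                        "articles")) {
  measure <- match.arg(measure)
  if (!facet %in% FILTER_KEYS) {
    stop("unknown facet: ", facet, call. = FALSE)
  }
  tab <- if (inherits(corpus, "data.frame")) corpus else
    citation_table(corpus)

  if (facet == "mat.collectionCode") {
    spec_val <- vapply(seq_len(nrow(tab)), function(i) {
      if (!tab$has_citation[i]) return(NA_character_)
      codes <- tab$collection_codes[[i]]
      if (length(codes) == 1) escape_missing(codes) else MISSING_LABEL
    }, "")
    pres <- lapply(seq_len(nrow(tab)), function(i) {
      if (!tab$has_citation[i]) return(character())
      codes <- tab$collection_codes[[i]]
      if (length(codes) == 0) MISSING_LABEL else unique(escape_missing(codes))
    })
  } else {
    v <- facet_value_column(tab, facet)
    keep <- tab$has_citation | startsWith(facet, "doc.") |
      startsWith(facet, "tax.")
    spec_val <- ifelse(tab$has_citation,
                       ifelse(is.na(v), MISSING_LABEL, v), NA_character_)
    pres <- lapply(seq_len(nrow(tab)), function(i) {
      if (!keep[i]) return(character())
      if (is.na(v[i])) MISSING_LABEL else v[i]
    })
  }

  has_val <- !is.na(spec_val)
  spec <- if (any(has_val)) {
    stats::aggregate(list(specimens = tab$total[has_val]),
                     by = list(value = spec_val[has_val]), FUN = sum)
  } else {
    data.frame(value = character(), specimens = integer())
  }

  pres_rows <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i) {
    vals <- pres[[i]]
    if (length(vals) == 0) return(NULL)
    tibble::tibble(value = vals, treatment_id = tab$treatment_id[i],
                   article_id = tab$article_id[i])
  }))
  if (is.null(pres_rows) || nrow(pres_rows) == 0) {
    pres_counts <- tibble::tibble(value = character(), treatments = integer(),
                                  articles = integer())
  } else {
    pres_counts <- dplyr::summarise(
      dplyr::group_by(pres_rows, .data$value),
      treatments = dplyr::n_distinct(.data$treatment_id),
      articles = dplyr::n_distinct(.data$article_id),
      .groups = "drop")
  }

  out <- dplyr::full_join(tibble::as_tibble(spec), pres_counts, by = "value")
  out$specimens[is.na(out$specimens)] <- 0
  out$treatments[is.na(out$treatments)] <- 0L
  out$articles[is.na(out$articles)] <- 0L
  out <- out[order(-out[[measure]], out$value), , drop = FALSE]
  structure(tibble::as_tibble(out),
            facet = facet, measure = measure,
            class = c("mc_facet_table", class(tibble::tibble())))
}

#' @export
print.mc_facet_table <- function(x, ...) {
  cat(sprintf("<mc_facet_table> facet=%s (ordered by %s)\n",
              attr(x, "facet"), attr(x, "measure")))
  NextMethod()
}

#' Attribute specimens to individual collectors
#'
#' Three attribution modes for team-collected lots: `"raw"` keeps the
#' verbatim collector string as the facet value (differently ordered
#' teams stay distinct); `"fractional"` gives each member of a k-person
#' team `total/k` specimens (conserves the corpus total); `"full_credit"`
#' gives each member the full total (column may exceed the corpus total).
#' Citations without a collector fall under `"missing"`.
#'
#' @param corpus an `mc_corpus`.
#' @param mode `"raw"`, `"fractional"` or `"full_credit"`.
#' @return an `mc_facet_table` over collectors; the `specimens` column is
#'   fractional in `"fractional"` mode.
#' @export
attribute_collectors <- function(corpus,
                                 mode = c("raw", "fractional",
                                          "full_credit")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(aggregate_facet(corpus, "mat.collectorName"))
  tab <- citation_table(corpus)
  tab <- tab[tab$has_citation, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    team <- tab$collector_team[[i]]
    if (length(team) == 0) {
      return(tibble::tibble(value = MISSING_LABEL,
                            specimens = as.numeric(tab$total[i]),
                            treatment_id = tab$treatment_id[i],
                            article_id = tab$article_id[i]))
    }
    w <- if (mode == "fractional") tab$total[i] / length(team) else
      as.numeric(tab$total[i])
    tibble::tibble(value = escape_missing(unique(team)), specimens = w,
                   treatment_id = tab$treatment_id[i],
                   article_id = tab$article_id[i])
  })
  df <- dplyr::bind_rows(rows)
  if (is.null(df) || nrow(df) == 0) {
    out <- tibble::tibble(value = character(), specimens = double(),
                          treatments = integer(), articles = integer())
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$value),
      specimens = sum(.data$specimens),
      treatments = dplyr::n_distinct(.data$treatment_id),
      articles = dplyr::n_distinct(.data$article_id),
      .groups = "drop")
    out <- out[order(-out$specimens, out$value), , drop = FALSE]
  }
  structure(tibble::as_tibble(out),
            facet = paste0("collector:", mode), measure = "specimens",
            class = c("mc_facet_table", class(tibble::tibble())))
}
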