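## Reader/writer for the treatment XML dialect and Darwin Core CSV export.
##
## Dialect grammar (one document per article):
##   article[id, journal, year, doi?, lsid?, pageCount?]
##     meta > author+
##     treatment[id, rank, status?]
##       taxon[orderEpithet?, familyEpithet?, genusEpithet?, speciesEpithet?,
##             authority?]
##       materialsCitation[country?, locality?, elevation?, date?,
##                         collectorName?, typeStatus?]
##         collectionCode*  specimenCount[type, count]*  specimenCode*
## Attributes are always written in the order above; serialization is
## UTF-8 with 2-space indentation and is byte-stable.

DWC_COLUMNS <- c(
  "occurrenceID", "scientificName", "taxonRank", "order", "family",
  "genus", "specificEpithet", "typeStatus", "individualCount", "sex",
  "institutionCode", "country", "locality", "minimumElevationInMeters",
  "eventDate", "year", "month", "recordedBy", "catalogNumber",
  "basisOfRecord"
)

attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

#' Read one article from dialect XML
#'
#' @param x XML text, a file path, or an `xml2` document.
#' @return an `mc_article`. Specimen counts are reconciled through
#'   [reconcile_counts()] (the `total` specimenCount acts as
#'   individualCount). Unknown elements and attributes are ignored with a
#'   warning; a treatment without a `rank` attribute is a schema error.
#' @export
read_article <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "article") {
    stop("dialect error: root element must be <article>, found <",
         xml2::xml_name(root), ">", call. = FALSE)
  }
  known_article_attrs <- c("id", "journal", "year", "doi", "lsid", "pageCount")
  warn_unknown_attrs(root, known_article_attrs)

  meta <- xml2::xml_find_all(root, "./meta")
  if (length(meta) != 1) {
    stop("dialect error: <article> must contain exactly one <meta>",
         call. = FALSE)
  }
  authors <- xml2::xml_text(xml2::xml_find_all(meta[[1]], "./author"))

  treatments <- list()
  for (node in xml2::xml_children(root)) {
    nm <- xml2::xml_name(node)
    if (nm == "meta") next
    if (nm != "treatment") {
      warning("ignoring unknown element <", nm, ">", call. = FALSE)
      next
    }
    treatments[[length(treatments) + 1L]] <- read_treatment_node(node)
  }

  article_record(
    article_id = attr_or_null(root, "id") %||% stop(
      "schema error: <article> missing required attribute 'id'",
      call. = FALSE),
    journal = attr_or_null(root, "journal") %||% "",
    year = attr_or_null(root, "year"),
    authors = authors,
    doi = attr_or_null(root, "doi"),
    lsid = attr_or_null(root, "lsid"),
    page_count = attr_or_null(root, "pageCount"),
    treatments = treatments
  )
}

warn_unknown_attrs <- function(node, known) {
  extra <- setdiff(names(xml2::xml_attrs(node)), known)
  for (a in extra) {
    warning("ignoring unknown attribute '", a, "' on <",
            xml2::xml_name(node), ">", call. = FALSE)
  }
}

read_treatment_node <- function(node) {
  warn_unknown_attrs(node, c("id", "rank", "status"))
  rank <- attr_or_null(node, "rank")
  if (is.null(rank)) {
    stop("schema error: <treatment> missing required attribute 'rank'",
         call. = FALSE)
  }
  taxon_nodes <- xml2::xml_find_all(node, "./taxon")
  tx <- if (length(taxon_nodes) >= 1) {
    tn <- taxon_nodes[[1]]
    warn_unknown_attrs(tn, c("orderEpithet", "familyEpithet", "genusEpithet",
                             "speciesEpithet", "authority"))
    taxon_name(rank,
               order = attr_or_null(tn, "orderEpithet"),
               family = attr_or_null(tn, "familyEpithet"),
               genus = attr_or_null(tn, "genusEpithet"),
               species = attr_or_null(tn, "speciesEpithet"),
               authority = attr_or_null(tn, "authority"))
  } else {
    taxon_name(rank)
  }
  citations <- list()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "taxon") next
    if (nm != "materialsCitation") {
      warning("ignoring unknown element <", nm, ">", call. = FALSE)
      next
    }
    citations[[length(citations) + 1L]] <- read_citation_node(child)
  }
  treatment_record(
    treatment_id = attr_or_null(node, "id") %||% stop(
      "schema error: <treatment> missing required attribute 'id'",
      call. = FALSE),
    taxon = tx,
    status = treatment_status(raw_status = attr_or_null(node, "status")),
    citations = citations
  )
}

read_citation_node <- function(node) {
  warn_unknown_attrs(node, c("country", "locality", "elevation", "date",
                             "collectorName", "typeStatus"))
  males <- females <- other <- 0L
  total <- NULL
  codes <- character()
  specimen_codes <- character()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "collectionCode") {
      codes <- c(codes, xml2::xml_text(child))
    } else if (nm == "specimenCode") {
      specimen_codes <- c(specimen_codes, xml2::xml_text(child))
    } else if (nm == "specimenCount") {
      type <- xml2::xml_attr(child, "type")
      count <- as.integer(xml2::xml_attr(child, "count"))
      if (is.na(count) || count < 0) {
        stop("schema error: <specimenCount> needs a non-negative 'count'",
             call. = FALSE)
      }
      switch(type,
             male = { males <- males + count },
             female = { females <- females + count },
             other = { other <- other + count },
             total = { total <- count },
             stop("schema error: unknown specimenCount type '", type, "'",
                  call. = FALSE))
    } else {
      warning("ignoring unknown element <", nm, ">", call. = FALSE)
    }
  }
  counts <- reconcile_counts(
    list(males = males, females = females, stated_other = other), total)
  elev <- attr_or_null(node, "elevation")
  materials_citation(
    counts = counts,
    type_status = attr_or_null(node, "typeStatus") %||% "none",
    collection_codes = codes,
    country = attr_or_null(node, "country"),
    locality = attr_or_null(node, "locality"),
    elevation_m = if (is.null(elev)) NULL else as.numeric(elev),
    event_date = attr_or_null(node, "date"),
    collector_raw = attr_or_null(node, "collectorName"),
    specimen_codes = specimen_codes
  )
}

## Writer --------------------------------------------------------------------

set_attrs <- function(node, attrs) {
  # attrs: named list; NULL entries are omitted (never written as empty)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (!is.null(v)) xml2::xml_set_attr(node, nm, as.character(v))
  }
}

num_chr <- function(x) {
  if (is.null(x)) NULL else format(x, scientific = FALSE, trim = TRUE)
}

#' Serialize one article to canonical dialect XML
#'
#' Writing is canonical and byte-stable: fixed attribute order, UTF-8,
#' 2-space indentation, absent optional fields omitted entirely.
#' `read_article(write_article(a))` reproduces `a` field for field.
#'
#' @param article an `mc_article`.
#' @return a single character string of XML text (with trailing newline).
#' @export
write_article <- function(article) {
  stopifnot(inherits(article, "mc_article"))
  doc <- xml2::xml_new_root("article")
  set_attrs(doc, list(id = article$article_id, journal = article$journal,
                      year = article$year, doi = article$doi,
                      lsid = article$lsid, pageCount = article$page_count))
  meta <- xml2::xml_add_child(doc, "meta")
  for (au in article$authors) xml2::xml_add_child(meta, "author", au)
  for (tr in article$treatments) {
    tn <- xml2::xml_add_child(doc, "treatment")
    set_attrs(tn, list(id = tr$treatment_id, rank = tr$taxon$rank,
                       status = tr$status$raw_status))
    ep <- tr$taxon$epithets
    if (any(!vapply(ep, is.null, TRUE)) || !is.null(tr$taxon$authority)) {
      tx <- xml2::xml_add_child(tn, "taxon")
      set_attrs(tx, list(orderEpithet = ep$orderEpithet,
                         familyEpithet = ep$familyEpithet,
                         genusEpithet = ep$genusEpithet,
                         speciesEpithet = ep$speciesEpithet,
                         authority = tr$taxon$authority))
    }
    for (ci in tr$citations) {
      mc <- xml2::xml_add_child(tn, "materialsCitation")
      set_attrs(mc, list(
        country = ci$country, locality = ci$locality,
        elevation = num_chr(ci$elevation_m), date = ci$event_date,
        collectorName = ci$collector_raw,
        typeStatus = if (ci$type_status == "none") NULL else ci$type_status))
      for (code in ci$collection_codes) {
        xml2::xml_add_child(mc, "collectionCode", code)
      }
      cc <- ci$counts
      if (cc$males > 0) xml2::xml_add_child(mc, "specimenCount",
                                            type = "male",
                                            count = as.character(cc$males))
      if (cc$females > 0) xml2::xml_add_child(mc, "specimenCount",
                                              type = "female",
                                              count = as.character(cc$females))
      if (cc$other > 0) xml2::xml_add_child(mc, "specimenCount",
                                            type = "other",
                                            count = as.character(cc$other))
      xml2::xml_add_child(mc, "specimenCount", type = "total",
                          count = as.character(cc$total))
      for (sc in ci$specimen_codes) {
        xml2::xml_add_child(mc, "specimenCode", sc)
      }
    }
  }
  as.character(doc, options = "format")
}

#' Read a corpus from dialect XML files or strings
#'
#' @param paths character vector of file paths (or XML strings).
#' @return an `mc_corpus` with one article per input, in input order.
#' @export
read_corpus <- function(paths) {
  corpus(lapply(paths, read_article))
}

#' Write a corpus as one dialect XML file per article
#'
#' @param corpus an `mc_corpus`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`<article_id>.xml`).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "mc_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (a in corpus$articles) {
    p <- file.path(dir, paste0(a$article_id, ".xml"))
    writeLines(sub("\n$", "", write_article(a)), p, useBytes = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

## Darwin Core export ---------------------------------------------------------

#' Export a corpus as a Darwin Core occurrence table
#'
#' One row per materials citation. `individualCount` is the reconciled
#' total; `sex` is the composed text "N male(s), M female(s)" omitting
#' zero classes; `institutionCode` joins multiple collection codes with
#' "|" (the dialect's collectionCode is equivalent to Darwin Core
#' institutionCode); `basisOfRecord` is the constant "PreservedSpecimen".
#'
#' @param corpus an `mc_corpus` (or `mc_view`).
#' @return a tibble with exactly the columns
#'   `r paste(DWC_COLUMNS, collapse = ", ")`. Absent values are `""`.
#' @export
export_dwc <- function(corpus) {
  corpus <- as_mc_corpus(corpus)
  rows <- list()
  chr <- function(x) if (is.null(x)) "" else as.character(x)
  for (a in corpus$articles) {
    for (tr in a$treatments) {
      i <- 0L
      for (ci in tr$citations) {
        i <- i + 1L
        ep <- tr$taxon$epithets
        sci <- paste(c(ep$genusEpithet, ep$speciesEpithet), collapse = " ")
        if (!nzchar(sci)) {
          sci <- chr(ep$familyEpithet %||% ep$orderEpithet)
        }
        pd <- parse_event_date(ci$event_date)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          occurrenceID = paste0(tr$treatment_id, ".", i),
          scientificName = sci,
          taxonRank = tr$taxon$rank,
          order = chr(ep$orderEpithet),
          family = chr(ep$familyEpithet),
          genus = chr(ep$genusEpithet),
          specificEpithet = chr(ep$speciesEpithet),
          typeStatus = if (ci$type_status == "none") "" else ci$type_status,
          individualCount = as.character(ci$counts$total),
          sex = render_sex_field(ci$counts$males, ci$counts$females),
          institutionCode = paste(ci$collection_codes, collapse = "|"),
          country = chr(ci$country),
          locality = chr(ci$locality),
          minimumElevationInMeters = chr(num_chr(ci$elevation_m)),
          eventDate = chr(ci$event_date),
          year = chr(pd$year),
          month = chr(pd$month),
          recordedBy = chr(ci$collector_raw),
          catalogNumber = paste(ci$specimen_codes, collapse = "|"),
          basisOfRecord = "PreservedSpecimen"
        )
      }
    }
  }
  if (length(rows) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      lapply(DWC_COLUMNS, function(x) character()), DWC_COLUMNS))
    return(out)
  }
  dplyr::bind_rows(rows)
}

#' Ingest a flat Darwin Core occurrence table
#'
#' The inverse ingest path for occurrence CSVs: `sex` text is parsed with
#' [parse_sex_field()] and reconciled against `individualCount` with
#' [reconcile_counts()]; rows are grouped into one treatment per
#' scientific name under a single synthetic article.
#'
#' @param x a data frame with (a subset of) the Darwin Core columns of
#'   [export_dwc()], or a path to such a CSV file.
#' @param article_id,journal,year,authors metadata for the containing
#'   synthetic article (flat occurrence tables carry none).
#' @return an `mc_corpus`.
#' @export
read_dwc <- function(x, article_id = "dwc-import", journal = "",
                     year = 2000L, authors = "unknown") {
  df <- if (is.character(x)) {
    utils::read.csv(x, colClasses = "character", check.names = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  col <- function(row, nm) {
    v <- if (nm %in% names(df)) row[[nm]] else ""
    if (is.null(v) || is.na(v) || !nzchar(v)) NULL else v
  }
  groups <- split(seq_len(nrow(df)),
                  if ("scientificName" %in% names(df)) df$scientificName
                  else seq_len(nrow(df)))
  treatments <- list()
  k <- 0L
  for (g in names(groups)) {
    k <- k + 1L
    idx <- groups[[g]]
    first <- df[idx[1], , drop = FALSE]
    rank <- col(first, "taxonRank") %||% "species"
    if (!rank %in% RANK_LEVELS) rank <- "other-higher"
    sp <- col(first, "specificEpithet")
    if (rank == "species" && is.null(sp)) sp <- g
    tx <- taxon_name(rank,
                     order = col(first, "order"),
                     family = col(first, "family"),
                     genus = col(first, "genus"),
                     species = if (rank == "species") sp else NULL)
    cits <- lapply(idx, function(i) {
      row <- df[i, , drop = FALSE]
      ic <- col(row, "individualCount")
      counts <- reconcile_counts(parse_sex_field(col(row, "sex") %||% ""),
                                 if (is.null(ic)) NULL else as.integer(ic))
      codes <- col(row, "institutionCode")
      scodes <- col(row, "catalogNumber")
      ts <- col(row, "typeStatus") %||% "none"
      materials_citation(
        counts = counts,
        type_status = if (ts %in% TYPE_STATUS_LEVELS) ts else "none",
        collection_codes = if (is.null(codes)) character() else
          strsplit(codes, "|", fixed = TRUE)[[1]],
        country = col(row, "country"),
        locality = col(row, "locality"),
        elevation_m = {
          e <- col(row, "minimumElevationInMeters")
          if (is.null(e)) NULL else as.numeric(e)
        },
        event_date = {
          d <- parse_event_date(col(row, "eventDate"))
          d$iso
        },
        collector_raw = col(row, "recordedBy"),
        specimen_codes = if (is.null(scodes)) character() else
          strsplit(scodes, "|", fixed = TRUE)[[1]]
      )
    })
    treatments[[k]] <- treatment_record(
      treatment_id = paste0(article_id, "-t", k), taxon = tx,
      citations = cits)
  }
  corpus(list(article_record(article_id, journal, year, authors,
                             treatments = treatments)))
}
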