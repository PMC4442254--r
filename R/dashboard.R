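## Dashboard chart data: named series derived from facet tables.

chart_series <- function(chart_id, kind, x_labels, series, title) {
  series <- lapply(series, as.numeric)
  for (s in series) stopifnot(length(s) == length(x_labels))
  structure(list(chart_id = chart_id, kind = kind,
                 x_labels = as.character(x_labels), series = series,
                 title = title),
            class = "mc_chart")
}

facet_chart <- function(corpus, chart_id, kind, facet, measure, title,
                        order = c("measure", "label", "chronological")) {
  order <- match.arg(order)
  ft <- aggregate_facet(corpus, facet, measure = measure)
  if (order != "measure" && nrow(ft) > 0) {
    is_missing <- ft$value == MISSING_LABEL
    body <- ft[!is_missing, , drop = FALSE]
    key <- if (order == "chronological") {
      suppressWarnings(as.numeric(gsub("[^0-9].*$", "", gsub(",", "", body$value))))
    } else {
      body$value
    }
    ft <- rbind(body[order(key), , drop = FALSE],
                ft[is_missing, , drop = FALSE])
  }
  chart_series(chart_id, kind, ft$value,
               stats::setNames(list(as.numeric(ft[[measure]])), measure), title)
}

#' Build a dashboard page
#'
#' Assembles the canonical 16-chart page from one (optionally filtered)
#' corpus: sex composition (pie); specimens by collecting month split by
#' sex (stacked bar over months 1-12 plus a "missing" column for
#' citations without month precision); specimens by collecting decade;
#' specimens by 500 m elevation band; specimens, treatments and
#' primary-type specimens by collection code; specimens and treatments by
#' collecting country; specimens and treatments by collector (verbatim
#' collector strings); treatments by family; treatments by status;
#' specimens and treatments by publication year; treatments per article.
#' Charts are views of the corresponding facet tables, never independent
#' recomputations. An empty filtered corpus yields a page of all-zero
#' charts.
#'
#' @param corpus an `mc_corpus`.
#' @param query an `mc_query` or query string (see
#'   [parse_filter_string()]); default: no filtering.
#' @param profile `"all-treatments"` or `"species-rank"` (which first
#'   restricts to `tax.rank = species`).
#' @param extra_charts optional named list of functions
#'   `function(corpus) -> chart` appended after the canonical set.
#' @return an object of class `mc_page` with fields `page_id`, `filter`,
#'   `profile` and `charts`.
#' @export
build_dashboard <- function(corpus, query = filter_query(),
                            profile = c("all-treatments", "species-rank"),
                            extra_charts = list()) {
  profile <- match.arg(profile)
  if (is.character(query)) query <- parse_filter_string(query)
  view <- apply_filter(corpus, query)
  if (profile == "species-rank") {
    view <- apply_filter(view, filter_query(tax.rank = "species"))
  }
  tab <- citation_table(view)

  charts <- list()
  add <- function(ch) charts[[length(charts) + 1L]] <<- ch

  # 1. sex composition pie (fixed slice order male, female, other)
  add(chart_series("specimens_by_sex", "pie", c("male", "female", "other"),
                   list(specimens = c(sum(tab$males), sum(tab$females),
                                      sum(tab$other))),
                   "Specimens by sex"))

  # 2. month x sex stacked bar; months 1..12 plus "missing"
  xl <- c(as.character(1:12), MISSING_LABEL)
  mkey <- ifelse(is.na(tab$month), MISSING_LABEL, as.character(tab$month))
  mkey[!tab$has_citation] <- NA
  sum_by <- function(w) {
    vapply(xl, function(m) sum(w[!is.na(mkey) & mkey == m]), 0)
  }
  add(chart_series("specimens_by_month_sex", "stacked-bar", xl,
                   list(male = sum_by(tab$males),
                        female = sum_by(tab$females),
                        other = sum_by(tab$other)),
                   "Specimens by collecting month and sex"))

  add(facet_chart(view, "specimens_by_decade", "bar", "mat.decade",
                  "specimens", "Specimens by collecting decade",
                  order = "chronological"))
  add(facet_chart(view, "specimens_by_elevation", "histogram",
                  "mat.elevationBand", "specimens",
                  "Specimens by elevation band", order = "chronological"))
  add(facet_chart(view, "specimens_by_collection", "bar",
                  "mat.collectionCode", "specimens",
                  "Specimens by collection code"))
  add(facet_chart(view, "treatments_by_collection", "bar",
                  "mat.collectionCode", "treatments",
                  "Treatments by collection code"))

  # primary-type specimens by collection: view restricted to primary types
  ptypes <- lapply(PRIMARY_TYPE_LEVELS, function(ts) {
    aggregate_facet(apply_filter(view, filter_query(mat.typeStatus = ts)),
                    "mat.collectionCode")
  })
  pt <- dplyr::bind_rows(ptypes)
  pt <- if (nrow(pt) == 0) {
    tibble::tibble(value = character(), specimens = numeric())
  } else {
    dplyr::summarise(dplyr::group_by(pt, .data$value),
                     specimens = sum(.data$specimens), .groups = "drop")
  }
  pt <- pt[order(-pt$specimens, pt$value), , drop = FALSE]
  add(chart_series("primary_types_by_collection", "bar", pt$value,
                   list(specimens = as.numeric(pt$specimens)),
                   "Primary type specimens by collection code"))

  add(facet_chart(view, "specimens_by_country", "bar", "mat.country",
                  "specimens", "Specimens by collecting country"))
  add(facet_chart(view, "treatments_by_country", "bar", "mat.country",
                  "treatments", "Treatments by collecting country"))
  add(facet_chart(view, "specimens_by_collector", "bar",
                  "mat.collectorName", "specimens",
                  "Specimens by collector name"))
  add(facet_chart(view, "treatments_by_collector", "bar",
                  "mat.collectorName", "treatments",
                  "Treatments by collector name"))
  add(facet_chart(view, "treatments_by_family", "bar", "tax.familyEpithet",
                  "treatments", "Treatments by family"))
  add(facet_chart(view, "treatments_by_status", "bar", "tax.status",
                  "treatments", "Treatments by taxonomic status"))
  add(facet_chart(view, "specimens_by_pub_year", "line", "doc.year",
                  "specimens", "Specimens by year of publication",
                  order = "chronological"))
  add(facet_chart(view, "treatments_by_pub_year", "line", "doc.year",
                  "treatments", "Treatments by year of publication",
                  order = "chronological"))

  # treatments per article
  arts <- vapply(view$articles, `[[`, "", "article_id")
  ntr <- vapply(view$articles, function(a) length(a$treatments), 0L)
  ord <- order(-ntr, arts)
  add(chart_series("treatments_per_article", "bar", arts[ord],
                   list(treatments = as.numeric(ntr[ord])),
                   "Treatments per article"))

  for (nm in names(extra_charts)) {
    ch <- extra_charts[[nm]](view)
    stopifnot(inherits(ch, "mc_chart"))
    add(ch)
  }

  ids <- vapply(charts, `[[`, "", "chart_id")
  if (anyDuplicated(ids)) {
    stop("duplicate chart ids on page: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(page_id = paste0("dashboard-", profile),
         filter = if (length(query$clauses) == 0) "" else
           paste0("FILTER_", names(query$clauses), "=",
                  unlist(query$clauses), collapse = "&"),
         profile = profile, charts = charts),
    class = "mc_page"
  )
}

#' @export
print.mc_page <- function(x, ...) {
  cat(sprintf("<mc_page> %s, %d chart(s)%s\n", x$page_id, length(x$charts),
              if (nzchar(x$filter)) paste0(", filter: ", x$filter) else ""))
  invisible(x)
}

#' Serialize a dashboard page to JSON
#'
#' Deterministic serialization: fixed key order (`page_id`, `filter`,
#' `profile`, `charts`; within a chart: `chart_id`, `kind`, `title`,
#' `x_labels`, `series`), numbers without locale separators. Rendering
#' the same page twice yields identical bytes.
#'
#' @param page an `mc_page`.
#' @param pretty pretty-print (default `TRUE`).
#' @return a single JSON string.
#' @export
render_json <- function(page, pretty = TRUE) {
  stopifnot(inherits(page, "mc_page"))
  charts <- lapply(page$charts, function(ch) {
    list(chart_id = jsonlite::unbox(ch$chart_id),
         kind = jsonlite::unbox(ch$kind),
         title = jsonlite::unbox(ch$title),
         x_labels = ch$x_labels,
         series = lapply(ch$series, as.numeric))
  })
  obj <- list(page_id = jsonlite::unbox(page$page_id),
              filter = jsonlite::unbox(page$filter),
              profile = jsonlite::unbox(page$profile),
              charts = charts)
  as.character(jsonlite::toJSON(obj, pretty = pretty, digits = NA,
                                null = "null"))
}
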