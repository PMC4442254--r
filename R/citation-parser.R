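## Normalisation of verbatim materials-citation fields.

SEX_CLASSWORDS <- list(
  males = c("male", "males", "m", "\u2642"),
  females = c("female", "females", "f", "\u2640"),
  other = c("juvenile", "juveniles", "juv", "juvs", "imm", "imms",
            "immature", "immatures", "subadult", "subadults", "other",
            "others")
)

#' Parse a verbatim Darwin Core "sex" field
#'
#' Grammar: tokens separated by commas, semicolons, "and" or "&"; each
#' token is `<count> <classword>` or a bare classword (implying count 1).
#' Classwords (case-insensitive, singular or plural, trailing period
#' allowed): male/\u2642; female/\u2640; juvenile, juv, imm, immature,
#' subadult, other (all counted as "other"). Unrecognised tokens are kept
#' verbatim in `unparsed_tokens`, never guessed at.
#'
#' @param text a single character string (or `NULL`/`NA` for absent).
#' @return a list of class `mc_sexparse` with fields `males`, `females`,
#'   `stated_other` (integers) and `unparsed_tokens` (character).
#' @examples
#' parse_sex_field("1 male, 4 females")
#' parse_sex_field("2 \u2642, 1 juv., 1 sp.")
#' @export
parse_sex_field <- function(text) {
  res <- list(males = 0L, females = 0L, stated_other = 0L,
              unparsed_tokens = character())
  class(res) <- "mc_sexparse"
  if (is.null(text) || length(text) == 0 || is.na(text)) return(res)
  stopifnot(is.character(text), length(text) == 1)
  s <- trimws(text)
  if (!nzchar(s)) return(res)
  tokens <- strsplit(s, "\\s*(,|;|&|\\band\\b)\\s*", perl = TRUE)[[1]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([0-9]+)?\\s*(\\S+?)\\.?$", tok))[[1]]
    hit <- FALSE
    if (length(m) == 3) {
      count <- if (nzchar(m[2])) as.integer(m[2]) else 1L
      word <- tolower(m[3])
      for (cls in names(SEX_CLASSWORDS)) {
        if (word %in% SEX_CLASSWORDS[[cls]]) {
          slot <- if (cls == "other") "stated_other" else cls
          res[[slot]] <- res[[slot]] + count
          hit <- TRUE
          break
        }
      }
    }
    if (!hit) res$unparsed_tokens <- c(res$unparsed_tokens, tok)
  }
  res
}

#' Render a sex parse back to text
#'
#' Produces the composed `"N male(s), M female(s), K other(s)"` form used
#' by the Darwin Core export, omitting zero classes.
#'
#' @param males,females,other non-negative integer counts.
#' @return a single string; empty when all classes are zero.
#' @export
render_sex_field <- function(males, females, other = 0L) {
  parts <- character()
  plural <- function(n, w) paste0(n, " ", w, if (n == 1) "" else "s")
  if (males > 0) parts <- c(parts, plural(males, "male"))
  if (females > 0) parts <- c(parts, plural(females, "female"))
  if (other > 0) parts <- c(parts, plural(other, "other"))
  paste(parts, collapse = ", ")
}

#' Reconcile a sex-field parse with an individualCount
#'
#' Implements the reconciliation convention for heterogeneous specimen
#' lots: when `individual_count` exceeds the sum of the sexed counts, the
#' difference is added to the "other" category (non-adults etc.); when it
#' is absent, the sexed counts are summed; when it is smaller than the
#' sexed sum, the larger sexed sum wins and a reconciliation warning is
#' attached.
#'
#' @param parse an `mc_sexparse` (see [parse_sex_field()]) or a list with
#'   fields `males`, `females`, `stated_other`.
#' @param individual_count optional non-negative integer.
#' @return an `mc_counts` triple satisfying
#'   `total == males + females + other`; when the individualCount was
#'   inconsistent the attribute `"reconciliation_warning"` carries a
#'   message.
#' @examples
#' reconcile_counts(parse_sex_field("1 male, 4 females"), 7) # 2 "other"
#' @export
reconcile_counts <- function(parse, individual_count = NULL) {
  m <- as.integer(parse$males)
  f <- as.integer(parse$females)
  o <- as.integer(parse$stated_other %||% parse$other %||% 0L)
  s <- m + f + o
  warning_msg <- NULL
  if (is.null(individual_count) || is.na(individual_count)) {
    out <- count_triple(m, f, o)
  } else {
    ic <- as.integer(individual_count)
    if (is.na(ic) || ic < 0) {
      stop("individual_count must be a non-negative integer", call. = FALSE)
    }
    if (ic >= s) {
      out <- count_triple(m, f, o + (ic - s))
    } else {
      out <- count_triple(m, f, o)
      warning_msg <- sprintf(
        "individualCount %d smaller than sexed sum %d; kept the sum", ic, s)
    }
  }
  if (!is.null(warning_msg)) {
    attr(out, "reconciliation_warning") <- warning_msg
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a verbatim collector string into an ordered team
#'
#' Splits on "&", " and ", "," and ";", trims whitespace and preserves
#' order (the order of names is meaningful: differently ordered teams are
#' distinct verbatim collector strings).
#'
#' @param raw a single character string (or `NULL`).
#' @return ordered character vector of collector names (empty for `NULL`).
#' @examples
#' split_collectors("Y. M. Marusik & D. V. Obydov")
#' @export
split_collectors <- function(raw) {
  if (is.null(raw) || length(raw) == 0 || is.na(raw)) return(character())
  stopifnot(is.character(raw), length(raw) == 1)
  parts <- strsplit(raw, "\\s*(&|,|;|\\band\\b)\\s*", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

MONTH_NAMES <- c("january", "february", "march", "april", "may", "june",
                 "july", "august", "september", "october", "november",
                 "december")
MONTH_ABBR <- substr(MONTH_NAMES, 1, 3)

match_month_name <- function(word) {
  w <- tolower(sub("\\.$", "", word))
  i <- match(w, MONTH_NAMES)
  if (is.na(i)) i <- match(substr(w, 1, 3), MONTH_ABBR)
  i
}

#' Parse a collecting-event date
#'
#' Accepts ISO-8601 with reduced precision ("1999", "1999-07",
#' "1999-07-15"), "DD.MM.YYYY", "D Month YYYY" (English month names or
#' three-letter abbreviations) and day ranges such as "12-15 Jul 1999" (en dashes equally accepted)
#' (the start date is used). Precision below what the text states is never
#' invented: a year-only date has no month.
#'
#' @param text a single character string (or `NULL`).
#' @return a list with fields `iso` (normalised reduced-precision ISO
#'   string), `year`, `month` (1–12 or `NULL`), `day`, `decade`
#'   (e.g. 1990) and `decade_label` (e.g. "1990s"); all fields `NULL` when
#'   the text cannot be parsed.
#' @examples
#' parse_event_date("12-15 Jul 1999")$month
#' @export
parse_event_date <- function(text) {
  empty <- list(iso = NULL, year = NULL, month = NULL, day = NULL,
                decade = NULL, decade_label = NULL)
  if (is.null(text) || length(text) == 0 || is.na(text)) return(empty)
  s <- trimws(text)
  if (!nzchar(s)) return(empty)
  year <- month <- day <- NULL

  if (grepl("^[0-9]{4}$", s)) {
    year <- as.integer(s)
  } else if (grepl("^[0-9]{4}-[0-9]{2}$", s)) {
    year <- as.integer(substr(s, 1, 4)); month <- as.integer(substr(s, 6, 7))
  } else if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s)) {
    year <- as.integer(substr(s, 1, 4)); month <- as.integer(substr(s, 6, 7))
    day <- as.integer(substr(s, 9, 10))
  } else if (grepl("^[0-9]{1,2}\\.[0-9]{1,2}\\.[0-9]{4}$", s)) {
    p <- as.integer(strsplit(s, ".", fixed = TRUE)[[1]])
    day <- p[1]; month <- p[2]; year <- p[3]
  } else {
    # "D Month YYYY" with an optional leading day range "D-D"
    m <- regmatches(
      s, regexec(paste0("^([0-9]{1,2})\\s*(?:[-\u2013\u2014]\\s*[0-9]{1,2})?",
                        "\\s+([A-Za-z]+\\.?)\\s+([0-9]{4})$"), s, perl = TRUE)
    )[[1]]
    if (length(m) == 4) {
      mo <- match_month_name(m[3])
      if (!is.na(mo)) {
        day <- as.integer(m[2]); month <- mo; year <- as.integer(m[4])
      }
    } else {
      # "Month YYYY"
      m2 <- regmatches(s, regexec("^([A-Za-z]+\\.?)\\s+([0-9]{4})$", s))[[1]]
      if (length(m2) == 3) {
        mo <- match_month_name(m2[2])
        if (!is.na(mo)) { month <- mo; year <- as.integer(m2[3]) }
      }
    }
  }
  if (is.null(year)) return(empty)
  if (!is.null(month) && (month < 1 || month > 12)) return(empty)
  iso <- sprintf("%04d", year)
  if (!is.null(month)) iso <- paste0(iso, sprintf("-%02d", month))
  if (!is.null(day)) iso <- paste0(iso, sprintf("-%02d", day))
  decade <- (year %/% 10L) * 10L
  list(iso = iso, year = year, month = month, day = day, decade = decade,
       decade_label = paste0(decade, "s"))
}

#' Assign an elevation to its 500 m band
#'
#' Bands are the half-open intervals (k*500, (k+1)*500] meters; an
#' elevation of exactly 0 falls in the lowest band. Labels use thousands
#' separators and an en dash: "1-500" style with an en dash: "1\u2013500", "4,001\u20134,500".
#'
#' @param elevation_m a single number in \[0, 9000\].
#' @return a list of class `mc_elevband` with integer `lower_m`, `upper_m`
#'   (`upper_m == lower_m + 500`) and the `label`.
#' @examples
#' bin_elevation(4200)$label
#' @export
bin_elevation <- function(elevation_m) {
  e <- as.numeric(elevation_m)
  if (length(e) != 1 || is.na(e) || e < 0 || e > 9000) {
    stop("elevation must be a single value in [0, 9000]", call. = FALSE)
  }
  k <- if (e <= 0) 0L else as.integer(ceiling(e / 500) - 1L)
  lower <- k * 500L
  upper <- lower + 500L
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE)
  structure(
    list(lower_m = lower, upper_m = upper,
         label = paste0(fmt(lower + 1L), "\u2013", fmt(upper))),
    class = "mc_elevband"
  )
}

#' Parse a verbatim elevation field
#'
#' Accepts a plain number ("1200", "1200 m") or a range ("1200-1400 m"),
#' which is binned by its midpoint.
#'
#' @param text a single character string (or `NULL`).
#' @return elevation in meters (numeric) or `NULL` when absent/unparseable.
#' @export
parse_elevation <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  s <- gsub(",", "", trimws(text))
  m <- regmatches(
    s, regexec("^([0-9]+(?:\\.[0-9]+)?)\\s*(?:[-\u2013\u2014]\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*m?\\.?$",
               s, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  lo <- as.numeric(m[2])
  if (nzchar(m[3])) (lo + as.numeric(m[3])) / 2 else lo
}
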