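test_that("sex-field grammar parses counts, symbols and bare classwords", {
  cases <- list(
    list("1 male, 4 females", 1L, 4L, 0L, character()),
    list("", 0L, 0L, 0L, character()),
    list("110 males, 44 females", 110L, 44L, 0L, character()),
    list("2 ♂, 1 juv., 1 sp.", 2L, 0L, 1L, "1 sp."),
    list("male and 2 females", 1L, 2L, 0L, character()),
    list("3 subadults; 1 female", 0L, 1L, 3L, character()),
    list("5 IMMATURES", 0L, 0L, 5L, character()),
    list("one male", 0L, 0L, 0L, "one male")
  )
  for (cs in cases) {
    p <- parse_sex_field(cs[[1]])
    expect_identical(p$males, cs[[2]], label = cs[[1]])
    expect_identical(p$females, cs[[3]], label = cs[[1]])
    expect_identical(p$stated_other, cs[[4]], label = cs[[1]])
    expect_identical(p$unparsed_tokens, cs[[5]], label = cs[[1]])
  }
})

test_that("parsing a re-rendered sex field recovers the same counts", {
  set.seed(7)
  for (i in 1:50) {
    m <- sample(0:20, 1); f <- sample(0:20, 1); o <- sample(0:5, 1)
    text <- render_sex_field(m, f, o)
    p <- parse_sex_field(text)
    expect_identical(c(p$males, p$females, p$stated_other), c(m, f, o))
    expect_identical(p$unparsed_tokens, character())
  }
})

test_that("individualCount reconciliation follows the SRS convention", {
  p <- function(m, f, o) list(males = m, females = f, stated_other = o)
  # consistent
  ct <- reconcile_counts(p(1, 4, 0), 5)
  expect_identical(unclass(ct)[c("males", "females", "other", "total")],
                   list(males = 1L, females = 4L, other = 0L, total = 5L))
  # surplus goes to "other"
  ct <- reconcile_counts(p(1, 4, 0), 7)
  expect_identical(ct$other, 2L)
  expect_identical(ct$total, 7L)
  expect_null(attr(ct, "reconciliation_warning"))
  # absent individualCount: sum the sexed counts
  ct <- reconcile_counts(p(1, 4, 0), NULL)
  expect_identical(ct$total, 5L)
  # inconsistent: the larger sexed sum wins, with a warning attached
  ct <- reconcile_counts(p(2, 2, 1), 3)
  expect_identical(ct$total, 5L)
  expect_identical(ct$other, 1L)
  expect_match(attr(ct, "reconciliation_warning"), "smaller")
  expect_error(reconcile_counts(p(1, 0, 0), -2), "non-negative")
})

test_that("reconciled totals never fall below the sexed sum", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(0:10, 1); f <- sample(0:10, 1); o <- sample(0:4, 1)
    ic <- if (runif(1) < 0.3) NULL else sample(0:30, 1)
    ct <- reconcile_counts(list(males = m, females = f, stated_other = o), ic)
    expect_gte(ct$total, m + f)
    expect_gte(ct$other, 0L)
    expect_identical(ct$total, ct$males + ct$females + ct$other)
  }
})

test_that("collector strings split in order, preserving team order", {
  expect_identical(split_collectors("Y. M. Marusik & D. V. Obydov"),
                   c("Y. M. Marusik", "D. V. Obydov"))
  expect_identical(split_collectors("D. V. Obydov & Y. M. Marusik"),
                   c("D. V. Obydov", "Y. M. Marusik"))
  expect_identical(split_collectors("Y. M. Marusik"), "Y. M. Marusik")
  expect_identical(split_collectors("Kuntner, Gregoric, Candek"),
                   c("Kuntner", "Gregoric", "Candek"))
  expect_identical(split_collectors("A and B; C"), c("A", "B", "C"))
  expect_identical(split_collectors(NULL), character())
})

test_that("event dates parse at stated precision, ranges use the start", {
  d <- parse_event_date("1999-07-15")
  expect_identical(c(d$year, d$month, d$day), c(1999L, 7L, 15L))
  expect_identical(d$decade, 1990L)
  expect_identical(d$decade_label, "1990s")

  expect_identical(parse_event_date("12–15 Jul 1999")$month, 7L)
  expect_identical(parse_event_date("12-15 Jul 1999")$day, 12L)
  d <- parse_event_date("2014")
  expect_null(d$month)
  expect_identical(d$decade, 2010L)
  expect_identical(parse_event_date("15.07.1999")$month, 7L)
  expect_identical(parse_event_date("3 August 2005")$month, 8L)
  expect_identical(parse_event_date("July 1988")$iso, "1988-07")
  expect_null(parse_event_date("summer, long ago")$year)
  expect_null(parse_event_date(NULL)$year)
})

test_that("elevation bands tile (0, 9000] without gaps or overlap", {
  expect_identical(bin_elevation(4200)$label, "4,001–4,500")
  expect_identical(bin_elevation(1500)$label, "1,001–1,500")  # upper incl.
  expect_identical(bin_elevation(1)$label, "1–500")
  expect_identical(bin_elevation(0)$label, "1–500")
  expect_error(bin_elevation(9500), "9000")

  set.seed(3)
  for (e in c(runif(200, 0, 9000), 1:18 * 500, 1:18 * 500 + 1)) {
    e <- min(e, 9000)
    b <- bin_elevation(e)
    expect_identical(b$upper_m, b$lower_m + 500L)
    # the value lies in exactly this half-open band (0 belongs to band 1)
    expect_true(e > b$lower_m || (e == 0 && b$lower_m == 0L))
    expect_lte(e, b$upper_m)
  }
})

test_that("verbatim elevation ranges are binned by their midpoint", {
  expect_identical(parse_elevation("1200 m"), 1200)
  expect_identical(parse_elevation("1200-1400 m"), 1300)
  expect_identical(parse_elevation("1,200–1,400 m"), 1300)
  expect_null(parse_elevation("near the river"))
})
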