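test_that("the reference portfolio realises every printed count", {
  p <- paper_fixture()
  tb <- tibble::as_tibble(p)

  # 264 reports: 166 single-, 87 double-, 11 multi-recommendation
  per_report <- table(table(tb$report_id))
  expect_identical(length(unique(tb$report_id)), 264L)
  expect_identical(unname(per_report[["1"]]), 166L)
  expect_identical(unname(per_report[["2"]]), 87L)
  expect_identical(sum(table(tb$report_id) >= 3), 11L)

  # per-level record totals
  counts <- table(tb$recommendation)
  expect_identical(unname(counts[["STRONGLY_AGAINST"]]), 166L)
  expect_identical(unname(counts[["MODERATELY_AGAINST"]]), 83L)
  expect_identical(unname(counts[["UNCERTAIN"]]), 77L)
  expect_identical(unname(counts[["MODERATELY_IN_FAVOR"]]), 49L)
  expect_identical(unname(counts[["FULLY_IN_FAVOR"]]), 3L)
  expect_identical(nrow(tb), 378L)
  expect_identical(attr(p, "denominator_override"), 375L)

  # each documented pattern appears with its printed count and level
  tab <- tabulate_combinations(p)
  lookup <- function(e, b, ec) {
    tab$n[tab$evidence == e & tab$benefit == b & tab$economics == ec]
  }
  expect_identical(lookup("VERY_LOW_NULL", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN"), 55L)
  expect_identical(lookup("LOW", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN"), 23L)
  expect_identical(lookup("MODERATE", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN"), 17L)
  expect_identical(lookup("LOW", "MINOR", "UNCERTAIN"), 29L)
  expect_identical(lookup("MODERATE", "MINOR", "UNCERTAIN"), 30L)
  expect_identical(lookup("LOW", "CONSIDERABLE", "UNCERTAIN"), 20L)
  expect_identical(lookup("HIGH", "MINOR", "UNCERTAIN"), 13L)
  expect_identical(lookup("VERY_LOW_NULL", "MINOR", "UNCERTAIN"), 17L)
  expect_identical(lookup("MODERATE", "MAJOR", "UNCERTAIN"), 18L)
  expect_identical(lookup("MODERATE", "CONSIDERABLE", "FAVORABLE"), 3L)

  # named patterns carry the level the record assigns them, fillers are
  # sentinel (missing domains) and excluded from the tabulation
  named <- sum(fixture_spec()$named_patterns$n)
  expect_identical(sum(tab$n), named)
  expect_identical(attr(tab, "unclassifiable"), nrow(tb) - named)
  spec <- fixture_spec()$named_patterns
  for (i in seq_len(nrow(spec))) {
    rows <- tb[!is.na(tb$evidence) &
      tb$evidence == spec$evidence[i] & tb$benefit == spec$benefit[i] &
      tb$economics == spec$economics[i], ]
    expect_true(all(rows$recommendation == spec$recommendation[i]))
  }

  # the anomalous very-low/minor pattern is flagged as deliberatively adjusted
  adj <- tb[!is.na(tb$evidence) & tb$evidence == "VERY_LOW_NULL" &
    tb$benefit == "MINOR", ]
  expect_true(all(adj$adjusted))
  expect_identical(sum(tb$adjusted), 17L)
})

test_that("the packaged CSV is the exact serialisation of the in-code fixture", {
  # the fixture's extra `adjusted` flag column is preserved with a warning
  expect_warning(
    from_csv <- read_portfolio(fixture_csv_path(), denominator_override = 375),
    "adjusted"
  )
  built <- paper_fixture()
  a <- as.data.frame(from_csv)
  a$adjusted <- as.logical(a$adjusted)
  b <- as.data.frame(built)
  for (at in setdiff(names(attributes(b)), c("names", "row.names", "class"))) {
    attr(b, at) <- NULL
    attr(a, at) <- NULL
  }
  expect_identical(a[names(b)], b)
  expect_identical(attr(from_csv, "denominator_override"), 375L)
})

test_that("fixture metadata records the source's internal discrepancies verbatim", {
  notes <- attr(paper_fixture(), "fixture_notes")
  expect_true(any(grepl("378", notes) & grepl("375", notes)))
  expect_true(any(grepl("22.1", notes, fixed = TRUE)))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_reports = 40, seed = 99)
  p1 <- generate_portfolio(cfg)
  p2 <- generate_portfolio(cfg)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  p3 <- generate_portfolio(generator_config(n_reports = 40, seed = 100))
  expect_false(identical(tibble::as_tibble(p1), tibble::as_tibble(p3)))
  # byte-identical serialisations
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_portfolio(p1, f1)
  write_portfolio(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the generator leaves the global RNG state alone
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_portfolio(cfg))
  expect_identical(runif(1), before)
})

test_that("generated portfolios are valid, empty at n = 0, and matrix-consistent", {
  expect_identical(nrow(generate_portfolio(generator_config(0, seed = 1))), 0L)
  p <- generate_portfolio(generator_config(n_reports = 60, seed = 7))
  tb <- tibble::as_tibble(p)
  expect_true(all(!is.na(tb$evidence)))
  m <- default_matrix()
  idx <- match(
    paste(tb$evidence, tb$benefit, tb$economics),
    paste(m$cells$evidence, m$cells$benefit, m$cells$economics)
  )
  expect_identical(
    as.character(tb$recommendation),
    as.character(m$cells$recommendation[idx])
  )
  expect_true(all(tb$request_date <= tb$assignment_date))
  expect_true(all(tb$assignment_date <= tb$publication_date))
})

test_that("category frequencies converge to the configured probabilities", {
  cfg <- generator_config(
    n_reports = 10000, seed = 12,
    evidence_probs = c(VERY_LOW_NULL = 0.25, LOW = 0.25, MODERATE = 0.25, HIGH = 0.25)
  )
  p <- generate_portfolio(cfg)
  n <- nrow(p)
  obs <- mean(p$evidence == "HIGH")
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(obs - 0.25), 3 * se)
  # report-count buckets follow their distribution too
  sizes <- table(table(p$report_id))
  expect_lt(abs(sizes[["1"]] / 10000 - 166 / 264), 3 * sqrt((166 / 264) * (98 / 264) / 10000))
})

test_that("generator configs validate probabilities and demand a seed", {
  expect_error(generator_config(10, seed = 1, evidence_probs = c(
    VERY_LOW_NULL = 0.5, LOW = 0.5, MODERATE = 0.2, HIGH = -0.2
  )), "sum to 1|non-negative")
  expect_error(
    generator_config(10, seed = 1, economics_probs = c(bad = 1)),
    "named over"
  )
  expect_error(generator_config(10), "seed")
})
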