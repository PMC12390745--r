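# the documented combination -> recommendation mappings, written literally
# from the implementation record; independent of the package's own tables
documented_mappings <- tibble::tribble(
  ~evidence, ~benefit, ~economics, ~expected,
  "VERY_LOW_NULL", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
  "LOW", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
  "MODERATE", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
  "LOW", "MINOR", "UNCERTAIN", "STRONGLY_AGAINST",
  "MODERATE", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST",
  "LOW", "CONSIDERABLE", "UNCERTAIN", "MODERATELY_AGAINST",
  "HIGH", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST",
  "MODERATE", "CONSIDERABLE", "UNCERTAIN", "UNCERTAIN",
  "MODERATE", "MAJOR", "UNCERTAIN", "MODERATELY_IN_FAVOR",
  "MODERATE", "CONSIDERABLE", "FAVORABLE", "FULLY_IN_FAVOR"
)

test_that("the cell score is the stated additive formula", {
  expect_identical(
    score_cell("VERY_LOW_NULL", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN"),
    1L
  )
  expect_identical(score_cell("MODERATE", "CONSIDERABLE", "FAVORABLE"), 10L)
  expect_identical(score_cell("HIGH", "MAJOR", "FAVORABLE"), 13L)
  # brute-force oracle over the whole grid: rank sums with econ points 0/1/4
  for (e in 0:3) {
    for (b in 0:3) {
      for (ec in 0:2) {
        expect_identical(
          score_cell(e, b, ec),
          as.integer(e + 2 * b + c(0, 1, 4)[ec + 1])
        )
      }
    }
  }
})

test_that("the default matrix is total and reproduces every documented mapping", {
  m <- default_matrix()
  cells <- tidy(m)
  expect_identical(nrow(cells), 48L)
  expect_identical(
    anyDuplicated(cells[c("evidence", "benefit", "economics")]), 0L
  )
  for (i in seq_len(nrow(documented_mappings))) {
    row <- documented_mappings[i, ]
    cell <- matrix_cell(m, row$evidence, row$benefit, row$economics)
    expect_identical(
      as.character(cell$recommendation), row$expected,
      label = paste(row$evidence, row$benefit, row$economics)
    )
    expect_identical(cell$provenance, "paper_anchored")
  }
  expect_identical(sum(cells$provenance == "paper_anchored"), 10L)
  expect_identical(
    as.character(matrix_cell(m, "HIGH", "MAJOR", "FAVORABLE")$recommendation),
    "FULLY_IN_FAVOR"
  )
})

test_that("the default matrix is monotone and gates full approval", {
  m <- default_matrix()
  expect_identical(nrow(validate_matrix(m)), 0L)
  expect_identical(nrow(m$monotonicity_report), 0L)
  # no cell without favorable economics is fully in favor
  cells <- tidy(m)
  fully <- cells[cells$recommendation == "FULLY_IN_FAVOR", ]
  expect_true(all(fully$economics == "FAVORABLE"))
  expect_true(all(fully$evidence >= "MODERATE"))
})

test_that("validate_matrix finds constructed inversions and localises them", {
  m <- default_matrix()
  # push one mid cell above a dominating cell's level
  i <- which(
    m$cells$evidence == "LOW" & m$cells$benefit == "MINOR" &
      m$cells$economics == "UNCERTAIN"
  )
  broken <- m
  broken$cells$recommendation[i] <- recommendation_level("MODERATELY_IN_FAVOR")
  report <- validate_matrix(broken)
  expect_gt(nrow(report), 0)
  involves_changed <- (report$lower_evidence == "LOW" &
    report$lower_benefit == "MINOR" & report$lower_economics == "UNCERTAIN") |
    (report$higher_evidence == "LOW" &
      report$higher_benefit == "MINOR" & report$higher_economics == "UNCERTAIN")
  expect_true(all(involves_changed))
  # the specific inversion against the dominating moderate-evidence cell
  expect_true(any(
    report$higher_evidence == "MODERATE" & report$higher_benefit == "MINOR" &
      report$higher_economics == "UNCERTAIN"
  ))
})

test_that("matrix CSV round-trips, fills missing cells with a warning, rejects duplicates", {
  m <- default_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  loaded <- load_matrix(path)
  expect_identical(nrow(loaded$cells), 48L)
  expect_identical(
    as.character(loaded$cells$recommendation),
    as.character(m$cells$recommendation)
  )
  expect_true(all(loaded$cells$provenance == "configured"))
  expect_identical(nrow(loaded$monotonicity_report), 0L)

  # partial file: the rest is filled from the default with provenance default_rule
  partial <- readr::read_csv(path, col_types = readr::cols())[1:10, ]
  ppath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(partial, ppath)
  expect_warning(pm <- load_matrix(ppath), "10 of 48")
  expect_identical(sum(pm$cells$provenance == "configured"), 10L)
  expect_identical(sum(pm$cells$provenance == "default_rule"), 38L)

  # duplicated combination is an error
  dup <- dplyr::bind_rows(
    readr::read_csv(path, col_types = readr::cols()),
    tibble::tibble(
      evidence = "HIGH", benefit = "MAJOR", economics = "FAVORABLE",
      recommendation = "UNCERTAIN"
    )
  )
  dpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, dpath)
  expect_error(load_matrix(dpath), "duplicate")

  # unknown scale member is a format error
  bad <- readr::read_csv(path, col_types = readr::cols())
  bad$evidence[1] <- "SUPERB"
  bpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, bpath)
  expect_error(load_matrix(bpath), "unknown evidence")
})

test_that("the packaged default-matrix CSV equals the in-code default", {
  csv <- system.file("extdata", "default_matrix.csv", package = "htavalue")
  loaded <- load_matrix(csv)
  expect_identical(
    as.character(loaded$cells$recommendation),
    as.character(default_matrix()$cells$recommendation)
  )
})
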