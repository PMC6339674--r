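test_that("response CSV round-trips and validates codes", {
  # small matrix with covariates
  X <- matrix(c(1L, 3L, 5L, 2L, 4L, 1L), nrow = 3)
  rm <- response_matrix(X, item_ids = c("a", "b"),
                        covariates = data.frame(gender = c("m", "f", "f")))
  expect_equal(dim(rm), c(3L, 2L))

  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, f)
  back <- read_responses(
    f, schema = list(person_id = "person_id", items = c("a", "b"),
                     covariates = "gender"))
  expect_identical(back$responses, rm$responses)
  expect_identical(back$covariates$gender, rm$covariates$gender)

  # out-of-range code names the offending cell
  expect_error(response_matrix(matrix(c(1L, 6L), 1)), "out of range")
  # non-integer entries in a file are a validation error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,a", "p1,2.5"), f2)
  expect_error(read_responses(f2), "non-integer")
})

test_that("a large synthetic matrix survives a write/read cycle unchanged", {
  sim <- ability_like_sim(n_persons = 1002, n_items = 35, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(sim$rm, f)
  back <- read_responses(
    f, schema = list(person_id = "person_id", items = sim$rm$item_ids,
                     covariates = names(sim$rm$covariates)))
  expect_identical(back$responses, sim$rm$responses)
})

test_that("item banks round-trip through CSV and JSON", {
  bank <- toy_bank()
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_item_bank(bank, f)
    back <- read_item_bank(f)
    expect_equal(back$slope, bank$slope)
    expect_equal(back$thresholds, bank$thresholds)
    expect_identical(back$item_id, bank$item_id)
  }
})

test_that("the shipped example bank loads with its reverse-coding flags", {
  bank <- read_item_bank(
    system.file("extdata", "example_bank.csv", package = "irtvalid"))
  expect_equal(n_items(bank), 4L)
  expect_identical(bank$reverse_coded, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(vapply(bank$thresholds, function(b) all(diff(b) > 0), TRUE)))
})

test_that("item bank construction enforces its invariants", {
  expect_error(item_bank("a", -1, list(c(0, 1))), "> 0")
  expect_error(item_bank("a", 2, list(c(1, 0))), "strictly increasing")
  expect_error(item_bank(c("a", "a"), c(1, 1), list(0, 0)), "unique")
})

test_that("reverse coding maps c to m+1-c, fixes the centre, refuses reapplication", {
  X <- matrix(c(1L, 3L, 5L, 2L), nrow = 1)
  rm <- response_matrix(X, item_ids = paste0("i", 1:4))
  bank <- item_bank(paste0("i", 1:4), rep(2, 4),
                    replicate(4, c(-1, 0, 1, 2), simplify = FALSE),
                    reverse_coded = c(TRUE, TRUE, TRUE, FALSE))
  out <- apply_reverse_coding(rm, bank)
  expect_identical(as.integer(out$responses), c(5L, 3L, 1L, 2L))
  expect_error(apply_reverse_coding(out, bank), "already been applied")

  # value-level involution on a full 5-category permutation
  perm <- matrix(1:5, nrow = 1)
  rm5 <- response_matrix(perm, item_ids = paste0("j", 1:5))
  bank5 <- item_bank(paste0("j", 1:5), rep(2, 5),
                     replicate(5, c(-1, 0, 1, 2), simplify = FALSE),
                     reverse_coded = TRUE)
  once <- apply_reverse_coding(rm5, bank5)
  expect_identical(as.integer(once$responses), 5:1)
})

test_that("complete_cases drops exactly the rows with missing responses", {
  X <- matrix(c(1L, NA, 3L, 2L, 2L, 4L), nrow = 3)
  rm <- response_matrix(X, covariates = data.frame(age = c(30, 40, 50)),
                        n_categories = 5L)
  cc <- complete_cases(rm)
  expect_equal(nrow(cc$responses), 2L)
  expect_equal(cc$covariates$age, c(30, 50))
  expect_error(scalability(rm), "complete cases")
})

test_that("validation reports round-trip through JSON", {
  sim <- ability_like_sim(n_persons = 400, n_items = 6, seed = 9)
  report <- suppressWarnings(
    run_pipeline(sim$rm, bank = sim$bank,
                 config = pipeline_config(dif_groupings = "gender"))
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_report(report, f)
  back <- read_report(f)
  expect_equal(back$fit_indices$cfi, report$fit_indices$cfi)
  expect_equal(back$scalability$H_scale, report$scalability$H_scale)
  expect_equal(back$cat_summaries$standard$mean_items,
               report$cat_summaries$standard$mean_items)
  # CSV export writes one table per section
  d <- withr::local_tempdir()
  write_report(report, d, format = "csv")
  expect_true(file.exists(file.path(d, "scalability.csv")))
})
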