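test_that("column dictionary declares the canonical layout", {
  dict <- cohort_columns()
  expect_true(all(c("id", "donor_age", "donor_sex", "cause_of_death",
                    "donor_bmi", "donor_cmv", "htn_duration",
                    "dm_duration", "donor_creatinine", "proteinuria",
                    "dcd", "en_bloc", "recip_age", "hla_mismatch",
                    "cpra", "cold_ischemia_hours") %in% dict$name))
  expect_false(dict$required[dict$name == "kdpi"])
  expect_false(dict$required[dict$name == "time"])
  # the first declared enum level is the encoding reference
  lev1 <- function(nm) strsplit(dict$levels[dict$name == nm], ",")[[1]][1]
  expect_identical(lev1("donor_sex"), "female")
  expect_identical(lev1("cause_of_death"), "anoxia")
  expect_identical(lev1("htn_duration"), "none")
  expect_identical(lev1("proteinuria"), "no")
})

test_that("write -> read -> write is byte-identical", {
  cohort <- simulate_cohort(sim_config(n = 60, seed = 42))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, f1)
  back <- read_cohort(f1)
  expect_equal(nrow(back), nrow(cohort))
  write_cohort(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(back$donor_age, cohort$donor_age, tolerance = 1e-12)
  expect_identical(back$dcd, cohort$dcd)
})

test_that("invalid rows are dropped with row-indexed diagnostics", {
  good <- donor_row(id = "a")
  bad_enum <- donor_row(id = "b", cause_of_death = "unknown_cause")
  bad_range <- donor_row(id = "c", donor_age = 150)
  bad_event <- donor_row(id = "d")
  good$time <- 3; good$event <- 1L
  bad_enum$time <- 2; bad_enum$event <- 0L
  bad_range$time <- 1; bad_range$event <- 2L
  bad_event$time <- 4; bad_event$event <- 5L
  raw <- rbind(good, bad_enum, bad_range, bad_event)
  expect_message(co <- as_cohort(raw), "3 of 4")
  expect_equal(nrow(co), 1L)
  expect_identical(co$id, "a")
  diag <- attr(co, "diagnostics")
  expect_setequal(diag$row, c(2L, 3L, 4L))
  expect_true(any(diag$column == "cause_of_death" & diag$row == 2))
  expect_true(any(diag$column == "donor_age" & diag$row == 3))
  expect_true(any(diag$column == "event" & diag$row == 4))
  expect_equal(attr(co, "n_dropped"), 3L)
})

test_that("time and event must be set together", {
  r1 <- donor_row(id = "a"); r1$time <- 3; r1$event <- NA_integer_
  r2 <- donor_row(id = "b"); r2$time <- NA_real_; r2$event <- NA_integer_
  expect_message(co <- as_cohort(rbind(r1, r2)))
  expect_identical(co$id, "b")  # both-unset is allowed, half-set is not
})

test_that("duplicate and empty identifiers are rejected", {
  raw <- rbind(donor_row(id = "x"), donor_row(id = "x"), donor_row(id = ""))
  expect_message(co <- as_cohort(raw), "2 of 3")
  expect_equal(nrow(co), 1L)
})

test_that("missing mandatory column is a schema error", {
  f <- tempfile(fileext = ".csv")
  df <- donor_row()
  df$donor_bmi <- NULL
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(f), "donor_bmi")
})

test_that("header matching is case-insensitive and enums normalize", {
  f <- tempfile(fileext = ".csv")
  df <- donor_row(donor_sex = "Male", cause_of_death = "STROKE")
  names(df)[names(df) == "donor_age"] <- "Donor_Age"
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  co <- read_cohort(f)
  expect_equal(co$donor_age, 40)
  expect_identical(co$donor_sex, "male")
  expect_identical(co$cause_of_death, "stroke")
})

test_that("alternative dialects parse decimals and separators", {
  f <- tempfile(fileext = ".csv")
  d <- cohort_dialect(sep = ";", dec = ",")
  co0 <- as_cohort(donor_row(donor_bmi = 25.5))
  write_cohort(co0, f, dialect = d)
  expect_true(any(grepl(";", readLines(f)[1], fixed = TRUE)))
  co <- as_cohort(utils::read.csv(f, sep = ";", colClasses = "character"),
                  dialect = d)
  expect_equal(co$donor_bmi, 25.5)
})

test_that("encode_design dummy codes against the declared references", {
  co <- as_cohort(rbind(
    donor_row(id = "a", cause_of_death = "stroke", donor_sex = "male"),
    donor_row(id = "b", cause_of_death = "anoxia", htn_duration = "gt10"),
    donor_row(id = "c", proteinuria = "yes", dcd = TRUE)))
  dm <- encode_design(co, c("donor_age", "donor_sex", "cause_of_death",
                            "htn_duration", "proteinuria", "dcd"))
  X <- dm$X
  expect_equal(nrow(X), 3L)
  expect_equal(unname(X[, "cause_of_death_stroke"]), c(1, 0, 0))
  expect_equal(unname(X[, "htn_duration_gt10"]), c(0, 1, 0))
  expect_equal(unname(X[, "proteinuria_yes"]), c(0, 0, 1))
  expect_equal(unname(X[, "dcd_true"]), c(0, 0, 1))
  expect_equal(unname(X[, "donor_age"]), c(40, 40, 40))
  # no dummy for any reference level
  expect_false("cause_of_death_anoxia" %in% colnames(X))
  expect_false("donor_sex_female" %in% colnames(X))
  expect_identical(dm$ref$cause_of_death, "anoxia")
  # group labels tie dummies to their parent factor
  expect_identical(unname(dm$groups[c("cause_of_death_stroke",
                                      "cause_of_death_trauma")]),
                   c("cause_of_death", "cause_of_death"))
  expect_identical(unname(dm$groups["donor_age"]), "donor_age")
})

test_that("encode_design drop_empty removes unoccupied level columns", {
  co <- as_cohort(rbind(donor_row(id = "a"), donor_row(id = "b")))
  full <- encode_design(co, "donor_cmv")
  lean <- encode_design(co, "donor_cmv", drop_empty = TRUE)
  expect_true("donor_cmv_positive" %in% colnames(full$X))
  expect_equal(ncol(lean$X), 0L)  # both donors are CMV negative
})

test_that("encode_design rejects bad inputs", {
  co <- as_cohort(donor_row())
  expect_error(encode_design(co, "nonexistent_term"), "unknown term")
  co2 <- co; co2$donor_age <- NA_real_
  expect_error(encode_design(co2, "donor_age"), "missing values")
})
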