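test_that("labeled series tables round-trip and report per-class counts", {
  tab <- generate_synthetic_cohorts(
    spec = list(cohort_spec("A", count = 2, length = 12),
                cohort_spec("B", count = 1, length = 12)),
    seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_labeled_series(tab, f)
  back <- read_labeled_series(f)
  expect_identical(back$label, c("A", "A", "B"))
  expect_equal(back$values, tab$values, tolerance = 1e-15)
  expect_equal(unname(table(back$label)["A"]), 2, ignore_attr = TRUE)
  # tab-delimited dialect auto-detects too
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_series(tab, ft, delimiter = "\t")
  expect_equal(read_labeled_series(ft)$values, tab$values, tolerance = 1e-15)
})

test_that("the series reader rejects ragged, non-numeric and unknown-label rows with line numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,1,2,3", "A,4,5", "B,6,7,8"), f)
  expect_error(read_labeled_series(f), "line 2.*ragged")
  writeLines(c("A,1,2,3", "B,4,x,6"), f)
  expect_error(read_labeled_series(f), "line 2.*non-numeric")
  writeLines(c("A,1,2,3", "Z,4,5,6"), f)
  expect_error(read_labeled_series(f, classes = c("A", "B")),
               "line 2.*unknown class")
  expect_error(read_labeled_series("no/such/file.csv"), "not found")
})

test_that("gait records parse whitespace columns and infer cohorts", {
  f <- file.path(withr::local_tempdir(), "control7.ts")
  n <- 130
  d <- data.frame(t = seq_len(n), ls = 1, rs = 1,
                  lsi = rep(0.4, n), rsi = rep(0.38, n))
  utils::write.table(d, f, row.names = FALSE, col.names = FALSE)
  rec <- read_gait_record(f)
  expect_identical(rec$cohort, "HC")
  expect_identical(rec$subject, "control7.ts")
  expect_equal(preprocess_gait(rec$lsi, id = rec$subject), rep(0.4, 120))
  expect_error(read_gait_record(f, column_map = list(lsi = 4, rsi = 9)),
               "outside")
  # manifest overrides filename inference
  man <- data.frame(file = "control7.ts", cohort = "PD")
  expect_identical(read_gait_record(f, manifest = man)$cohort, "PD")
  f2 <- file.path(dirname(f), "subjectX.ts")
  file.copy(f, f2)
  expect_error(read_gait_record(f2), "cannot infer cohort")
  expect_identical(read_gait_record(f2, cohort = "ALS")$cohort, "ALS")
})

test_that("synthetic cohorts are a pure function of spec and seed", {
  t1 <- generate_synthetic_cohorts(seed = 7)
  t2 <- generate_synthetic_cohorts(seed = 7)
  expect_identical(t1$values, t2$values)
  expect_identical(t1$label, t2$label)
  expect_identical(length(t1$values), 60L)
  expect_identical(length(t1$values[[1]]), 900L)
  t3 <- generate_synthetic_cohorts(seed = 8)
  expect_false(identical(t1$values, t3$values))
  # zero noise: pure sinusoid of unit amplitude
  pure <- generate_synthetic_cohorts(
    spec = list(cohort_spec("s", noise_sd = 0, count = 1, length = 200)),
    seed = 1)
  expect_lte(max(abs(pure$values[[1]])), 1)
  x <- pure$values[[1]]
  expect_equal(x[26], -x[1], tolerance = 1e-9)   # half period: 25 samples
  # the other families run and honour their parameter checks
  ar <- generate_synthetic_cohorts(
    spec = list(cohort_spec("ar", "ar1", count = 1, length = 100, noise_sd = 1)),
    seed = 2)
  expect_identical(length(ar$values[[1]]), 100L)
  lg <- generate_synthetic_cohorts(
    spec = list(cohort_spec("lg", "logistic", count = 1, length = 100)),
    seed = 2)
  expect_true(all(lg$values[[1]] > 0 & lg$values[[1]] < 1))
  expect_error(cohort_spec("x", "ar1", ar = 1.5), "AR")
  expect_error(cohort_spec("x", "logistic", rate = 5), "rate")
  expect_error(cohort_spec("x", count = 0), "count")
})

test_that("result writing round-trips values and records provenance", {
  out <- withr::local_tempdir()
  rec <- data.frame(id = c("s1", "s2"), label = c("A", "B"),
                    lambda_max = c(1.23456789012345, 2.5),
                    sampen = c(0.5, Inf))
  sm <- list(summarize_cohort(c(1, 2, 3), "A"))
  tr <- list(demo = upgma(matrix(c(0, 2, 2, 0), 2,
                                 dimnames = list(c("a", "b"), c("a", "b")))))
  files <- write_results(rec, sm, tr, out_dir = out,
                         config = list(kernel = "sharpen3x3"), seed = 99L)
  got <- utils::read.csv(file.path(out, "series_results.csv"))
  expect_equal(got$lambda_max, rec$lambda_max, tolerance = 1e-12)
  expect_identical(got$sampen[2], Inf)
  raw <- readLines(file.path(out, "series_results.csv"))
  expect_true(any(grepl(",inf$", raw)))               # sentinel serialization
  smdf <- utils::read.csv(file.path(out, "cohort_summaries.csv"))
  expect_identical(names(smdf), c("label", "n", "mean", "sd", "p_value",
                                  "ci95_lower", "ci95_upper",
                                  "ci99_lower", "ci99_upper"))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 99)
  expect_identical(man$config$kernel, "sharpen3x3")
  expect_true(file.exists(file.path(out, "demo.nwk")))
  # empty record set still yields a parseable header-only CSV
  write_results(records = data.frame(), out_dir = out)
  empty <- utils::read.csv(file.path(out, "series_results.csv"))
  expect_identical(nrow(empty), 0L)
})
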