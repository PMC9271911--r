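test_that("bundled datasets carry the published study counts and totals", {
  ds4 <- load_bundled_dataset("4b/a")
  dsg <- load_bundled_dataset("G894T")
  dst <- load_bundled_dataset("T786C")
  expect_equal(n_studies(ds4), 36)
  expect_equal(n_studies(dsg), 44)
  expect_equal(n_studies(dst), 13)
  expect_equal(sum(ds4$studies$n_cases), 8553)
  expect_equal(sum(ds4$studies$n_controls), 6613)
  expect_equal(sum(dsg$studies$n_cases), 10722)
  expect_equal(sum(dsg$studies$n_controls), 21256)
  expect_equal(sum(dst$studies$n_cases), 4676)
  expect_equal(sum(dst$studies$n_controls), 3842)
})

test_that("ethnicity strata match the published subgroup sizes", {
  ds4 <- load_bundled_dataset("4b/a")
  asian <- subset_studies(ds4, ethnicity == "asian")
  cauc <- subset_studies(ds4, ethnicity == "caucasian")
  expect_equal(n_studies(asian), 22)
  expect_equal(sum(asian$studies$n_cases), 4287)
  expect_equal(sum(asian$studies$n_controls), 3053)
  expect_equal(n_studies(cauc), 8)
  expect_equal(n_studies(subset_studies(load_bundled_dataset("G894T"),
                                        ethnicity == "asian")), 20)
  expect_equal(n_studies(subset_studies(load_bundled_dataset("T786C"),
                                        ethnicity == "indian")), 3)
})

test_that("write/read round-trips a dataset exactly", {
  for (ds in list(toy_dataset(), load_bundled_dataset("T786C"))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_study_table(ds, path)
    back <- read_study_table(path, ds$polymorphism, strict = FALSE)
    expect_identical(back$studies, ds$studies)
    expect_identical(back$polymorphism, ds$polymorphism)
    # header + one line per study
    expect_length(readLines(path), n_studies(ds) + 1L)
  }
})

test_that("validation rejects malformed tables with named row/column", {
  good <- toy_studies()
  poly <- polymorphism("toy marker", "A", "B")

  bad <- good; bad$n_cases[2] <- bad$n_cases[2] + 1L
  expect_error(study_dataset(bad, poly), "row 2.*genotype counts")

  bad <- good; bad$ethnicity[3] <- "martian"
  expect_error(study_dataset(bad, poly), "ethnicity.*row 3.*martian")

  bad <- good; bad$study_id[2] <- bad$study_id[1]
  expect_error(study_dataset(bad, poly), "duplicate study_id")

  bad <- good; bad$case_het[1] <- -1L
  expect_error(study_dataset(bad, poly), "nonnegative")

  bad <- good[, setdiff(names(good), "nos_score")]
  expect_error(study_dataset(bad, poly), "missing column.*nos_score")

  expect_error(study_dataset(good[0, ], poly), "at least one study")

  path <- withr::local_tempfile(fileext = ".csv")
  bad <- good; bad$case_het <- as.character(bad$case_het)
  bad$case_het[2] <- "many"
  utils::write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_study_table(path, poly), "row 2.*case_het.*many")
})

test_that("polymorphism alleles must be distinct and nonempty", {
  expect_error(polymorphism("x", "A", "A"), "differ")
  expect_error(polymorphism("x", "", "B"), "nonempty")
  p <- polymorphism("eNOS G894T", "G", "T")
  expect_s3_class(p, "polymorphism")
})

test_that("subsetting preserves order, is idempotent and intersects", {
  ds <- load_bundled_dataset("4b/a")
  all_true <- subset_studies(ds, rep(TRUE, n_studies(ds)))
  expect_identical(all_true$studies, ds$studies)

  a <- subset_studies(ds, ethnicity == "asian")
  aa <- subset_studies(a, ethnicity == "asian")
  expect_identical(a$studies, aa$studies)

  # intersection of predicates commutes with sequential application
  s1 <- subset_studies(subset_studies(ds, ethnicity == "asian"),
                       control_type == "healthy")
  s2 <- subset_studies(ds, ethnicity == "asian" &
                         control_type == "healthy")
  expect_identical(s1$studies, s2$studies)
  # order preserved relative to the parent
  expect_true(all(diff(match(s1$studies$study_id,
                             ds$studies$study_id)) > 0))

  expect_message(subset_studies(ds, ethnicity == "martian"), "empty")
})
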