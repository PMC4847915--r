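test_that("table reader validates schema and normalises enumerations", {
  p <- write_csv_fixture(c("case_id,gender,age,weight,extra",
                           "c1,female,20代,60kg,x",
                           "c2,男性,,,y",
                           "c3,hermaphrodite,80代,,z"))
  demo <- read_jader_table(p, "DEMO")
  expect_equal(nrow(demo), 3)               # one record per data row
  expect_identical(demo$case_id, c("c1", "c2", "c3"))  # row order preserved
  expect_identical(demo$gender, c("female", "male", "unknown"))
  expect_false("extra" %in% names(demo))

  miss <- write_csv_fixture(c("case_id,age,weight", "c1,20代,"))
  expect_error(read_jader_table(miss, "DEMO"), "gender")

  bad <- write_csv_fixture(c("case_id,adr_term,outcome",
                             "c1,Nausea,", "c2,  ,", "c3,Rash,"))
  expect_error(read_jader_table(bad, "REAC"), "row\\(s\\) 2")

  expect_error(read_jader_table(tempfile(), "DEMO"), "not found")
})

test_that("column-name mapping accepts JADER-style headers", {
  p <- write_csv_fixture(c("識別番号,性別,年齢,体重",
                           "j1,女性,30代,"))
  demo <- read_jader_table(p, "DEMO",
                           col_map = c(case_id = "識別番号", gender = "性別",
                                       age = "年齢", weight = "体重"))
  expect_identical(demo$gender, "female")
  expect_identical(demo$age, "30代")
})

test_that("drug causality roles map onto the enumeration with unknown fallback", {
  p <- write_csv_fixture(c("case_id,drug_name,causality",
                           "c1,パロキセチン塩酸塩,被疑薬",
                           "c1,某薬,併用薬",
                           "c2,ミルタザピン,???"))
  drug <- read_jader_table(p, "DRUG")
  expect_identical(drug$causality, c("suspected", "concomitant", "unknown"))
})

test_that("case assembly joins on DEMO, deduplicates ADRs, drops orphan rows", {
  demo <- read_jader_table(write_csv_fixture(
    c("case_id,gender,age,weight", "c1,female,20代,", "c2,male,,")), "DEMO")
  reac <- read_jader_table(write_csv_fixture(
    c("case_id,adr_term,outcome",
      "c1,Nausea,", "c1,Nausea,", "c3,Rash,")), "REAC")
  expect_message(cases <- assemble_cases(demo, reac),
                 "dropped 1 REAC row")
  expect_equal(length(cases), 2)
  expect_identical(cases$adr_terms[[1]], "Nausea")   # deduplicated
  expect_identical(cases$adr_terms[[2]], character(0))  # kept, empty ADR set

  dup <- read_jader_table(write_csv_fixture(
    c("case_id,gender,age,weight", "c1,female,,", "c1,male,,")), "DEMO")
  expect_error(assemble_cases(dup, reac, quiet = TRUE), "duplicate case_id")
})

test_that("assembly is idempotent through its own output tables", {
  g <- generate_jader(default_generator_spec(n_cases = 300, seed = 21),
                      out_dir = tempfile("synth"))
  demo <- read_jader_table(g$paths["demo"], "DEMO")
  reac <- read_jader_table(g$paths["reac"], "REAC")
  drug <- read_jader_table(g$paths["drug"], "DRUG")
  cases <- assemble_cases(demo, reac, drug, quiet = TRUE)
  # write the assembled cases back out as tables and assemble again
  demo2 <- demo
  reac2 <- data.frame(case_id = rep(cases$case_id, lengths(cases$adr_terms)),
                      adr_term = unlist(cases$adr_terms),
                      outcome = "", stringsAsFactors = FALSE)
  class(reac2) <- class(reac)
  drug2 <- data.frame(case_id = rep(cases$case_id, lengths(cases$drug_names)),
                      drug_name = unlist(cases$drug_names),
                      causality = unlist(cases$drug_causality),
                      stringsAsFactors = FALSE)
  class(drug2) <- class(drug)
  cases2 <- assemble_cases(demo2, reac2, drug2, quiet = TRUE)
  expect_identical(unclass(cases), unclass(cases2))
})

test_that("generator round-trip recovers the ground-truth manifest exactly", {
  g <- generate_jader(default_generator_spec(n_cases = 100, seed = 5),
                      out_dir = tempfile("synth"))
  demo <- read_jader_table(g$paths["demo"], "DEMO")
  reac <- read_jader_table(g$paths["reac"], "REAC")
  drug <- read_jader_table(g$paths["drug"], "DRUG")
  cases <- assemble_cases(demo, reac, drug, quiet = TRUE)
  m <- g$manifest$cases
  expect_equal(length(cases), nrow(m))
  expect_identical(cases$case_id, m$case_id)
  expect_identical(cases$gender, m$gender)
  expect_identical(cases$age_raw, m$age_raw)
  expect_identical(cases$adr_terms, m$adr_terms)
  expect_identical(unlist(cases$drug_names), m$drug)
})

test_that("cohort selection honours match mode and causality filter", {
  cases <- make_cases(
    c("c1", "c2", "c3", "c4"),
    gender = rep("female", 4), age_raw = rep("", 4),
    adr_terms = rep(list(character(0)), 4),
    drug_names = list("パロキセチン塩酸塩水和物", "セルトラリン塩酸塩",
                      "パロキセチン塩酸塩水和物", "ミルタザピン"),
    causality = list("suspected", "suspected", "concomitant", "suspected"))
  ssri <- drug_class_config("SSRI", c("パロキセチン", "セルトラリン"))
  got <- filter_cohort(cases, ssri)
  expect_identical(got$case_id, c("c1", "c2"))  # c3 fails causality filter

  lax <- drug_class_config("SSRI", c("パロキセチン", "セルトラリン"),
                           causality_filter = c("suspected", "concomitant"))
  expect_identical(filter_cohort(cases, lax)$case_id, c("c1", "c2", "c3"))

  exact <- drug_class_config("SSRI", "パロキセチン", match_mode = "exact")
  expect_equal(length(filter_cohort(cases, exact)), 0)  # salt suffix blocks exact

  expect_error(drug_class_config("SSRI", character(0)), "non-empty")
})

test_that("cohort sizes match the planted class split", {
  g <- generate_jader(default_generator_spec(n_cases = 400, seed = 13),
                      out_dir = tempfile("synth"))
  demo <- read_jader_table(g$paths["demo"], "DEMO")
  reac <- read_jader_table(g$paths["reac"], "REAC")
  drug <- read_jader_table(g$paths["drug"], "DRUG")
  cases <- assemble_cases(demo, reac, drug, quiet = TRUE)
  cls <- default_drug_classes()
  for (cl in names(cls)) {
    cfg <- drug_class_config(cl, cls[[cl]]$drugs, match_mode = "exact")
    expect_equal(length(filter_cohort(cases, cfg)),
                 as.integer(g$manifest$class_sizes[[cl]]))
  }
  # disjoint single-drug classes give disjoint cohorts covering all cases
  tot <- sum(vapply(names(cls), function(cl)
    length(filter_cohort(cases, drug_class_config(cl, cls[[cl]]$drugs))),
    numeric(1)))
  expect_equal(tot, length(cases))
})

test_that("CP932-encoded tables read back identically to UTF-8 ones", {
  spec_u <- default_generator_spec(n_cases = 50, seed = 9)
  g_u <- generate_jader(spec_u, out_dir = tempfile("u8"))
  spec_c <- default_generator_spec(n_cases = 50, seed = 9)
  spec_c$encoding <- "CP932"
  g_c <- generate_jader(spec_c, out_dir = tempfile("cp"))
  expect_false(identical(readBin(g_u$paths[["drug"]], "raw", 200),
                         readBin(g_c$paths[["drug"]], "raw", 200)))
  d_u <- read_jader_table(g_u$paths["drug"], "DRUG", encoding = "UTF-8")
  d_c <- read_jader_table(g_c$paths["drug"], "DRUG", encoding = "CP932")
  expect_identical(d_u$drug_name, d_c$drug_name)
})
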