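test_that("fixture asset loads, validates margins, and is tamper-evident", {
  fx <- load_fixture_tables()
  t6 <- fx$table6$rows
  expect_equal(t6$ischemic[t6$key == "vertigo"], 18)
  expect_equal(t6$hemorrhagic[t6$key == "vertigo"], 1)
  expect_equal(fx$table1$women[fx$table1$bands == "30-44"], 16)
  expect_equal(fx$table2$sections$relative$men,
               c(15, 5, 18))

  tampered <- withr::local_tempfile(fileext = ".json")
  raw <- readLines(system.file("extdata", "study_tables.json",
                               package = "strokestory"))
  writeLines(sub('"women": \\[52, 48\\]', '"women": [53, 47]', raw), tampered)
  expect_error(load_fixture_tables(tampered), "checksum")
})

test_that("reproduced tables recompute the printed percentages", {
  rep <- reproduce_tables()
  t5 <- rep$table5
  expect_equal(t5$women_pct[t5$section == "first" & t5$row == "ge1"], 45.8)
  expect_equal(t5$men_pct[t5$section == "third" & t5$row == "ge1"], 23.1)
  it <- rep$in_text
  expect_equal(it$value[it$name == "nontrad_first_person"], 44.6)
  expect_equal(it$cell[it$name == "nontrad_first_person"], "41/92")
  # every first-level symptom percentage in table 3 matches the printed one
  t3 <- rep$table3
  printed_women <- c(74.7, 64.8, 12.1, 17.6, 14.3, 7.7, 5.5, 42.9, 17.6,
                     5.5, 14.3, 4.4)
  expect_equal(t3$women_pct[t3$class != "subtype"], printed_women)
})

test_that("degenerate percentage cells render as zero", {
  rep <- reproduce_tables()
  t6 <- rep$table6
  expect_equal(t6$hemorrhagic_pct[t6$key == "lightheadedness"], 0)
})

test_that("corpus files round-trip byte-identically", {
  co <- small_corpus(401, 20, 40, 40)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(co, f1)
  write_corpus(read_corpus(f1), f2)
  expect_identical(file_bytes(f1), file_bytes(f2))
})

test_that("corpus reader errors name the offending line", {
  f <- withr::local_tempfile()
  writeLines(c('{"id":"a","date":"2010-01-01","text":"fine"}',
               '{"id":"b","date":"2010-01-02"}'), f)
  expect_error(read_corpus(f), "line 2.*text")

  writeLines(c('{"id":"a","date":"2010-01-01","text":"fine"}',
               'not json at all {{'), f)
  expect_error(read_corpus(f), "malformed JSON at line 2")

  writeLines(rep('{"id":"a","date":"2010-01-01","text":"x"}', 2), f)
  expect_error(read_corpus(f), "duplicate post id")

  writeLines(character(), f)
  expect_warning(empty <- read_corpus(f), "empty corpus")
  expect_equal(nrow(empty), 0L)
})

test_that("pipeline configs read from YAML and JSON with validation", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7",
               "corpus:",
               "  n_stroke_stories: 12",
               "  n_other_stories: 20",
               "  n_nonstory_posts: 20",
               "filter:",
               "  recall_target: 0.8"), yml)
  cfg <- read_pipeline_config(yml)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$corpus$n_stroke_stories, 12L)
  expect_equal(cfg$corpus$seed, 7L)  # root seed propagates
  expect_equal(cfg$filter$recall_target, 0.8)
  expect_equal(cfg$filter$precision_target, 0.66)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"corpus": {"female_fraction": 1.5}}', bad)
  expect_error(read_pipeline_config(bad), "proportions")
})

test_that("pipeline runs are reproducible and their report is populated", {
  cfg <- pipeline_config(
    corpus = corpus_config(n_stroke_stories = 120, n_other_stories = 300,
                           n_nonstory_posts = 300),
    retrieval = list(batch = 25, rounds = 4, alpha = 1, beta = 0.75,
                     gamma = 0.15),
    seed = 19
  )
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- run_pipeline(cfg, d1)
  m2 <- run_pipeline(cfg, d2)
  expect_identical(m1$checksums, m2$checksums)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_true(all(file.exists(file.path(d1, names(m1$checksums)))))
  tabs <- list.files(file.path(d1, "report"), pattern = "csv$")
  expect_true(all(c("narrator_by_sex.csv", "msc_by_sex_first.csv",
                    "nontrad_by_stroke_type.csv") %in% tabs))
  nb <- read.csv(file.path(d1, "report", "narrator_by_sex.csv"))
  expect_true(all(nb$female + nb$male > 0))
})

test_that("a pipeline without planted stories aborts in a named stage", {
  cfg <- pipeline_config(
    corpus = corpus_config(n_stroke_stories = 0, n_other_stories = 60,
                           n_nonstory_posts = 60),
    seed = 23
  )
  d <- withr::local_tempdir()
  expect_error(run_pipeline(cfg, d), "empty selection")
})
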