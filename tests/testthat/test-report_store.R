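test_that("write/read round-trip is the identity on valid report sets", {
  rs <- random_rs(40, seed = 101)
  for (dialect in c("tsv", "dollar")) {
    paths <- file.path(withr::local_tempdir(),
                       c("demo.txt", "drug.txt", "reac.txt"))
    write_reports(rs, paths[1], paths[2], paths[3], dialect = dialect)
    back <- read_reports(paths[1], paths[2], paths[3], dialect = dialect)
    expect_equal(as.data.frame(back$demo), as.data.frame(rs$demo))
    expect_equal(
      as.data.frame(back$drugs[order(report_id, drug_seq, drug_name)]),
      as.data.frame(rs$drugs[order(report_id, drug_seq, drug_name)])
    )
    expect_equal(as.data.frame(back$reactions), as.data.frame(rs$reactions))
  }
})

test_that("flat dialect round-trips reports with one drug role each", {
  rs <- make_rs(data.frame(
    report_id = c("r1", "r2"),
    sex = c("female", "male"),
    age = c(60.5, NA),
    year = c(2010L, NA),
    drugs = c("anastrozole", "rofecoxib:SS;tafamidis"),
    pts = c("carpal tunnel syndrome", "headache;nausea")
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reports_flat(rs, path)
  back <- read_reports_flat(path)
  expect_equal(n_reports(back), 2L)
  expect_equal(as.data.frame(back$demo), as.data.frame(rs$demo))
  expect_setequal(back$reactions$pt, rs$reactions$pt)
  expect_equal(
    back$drugs[order(report_id, drug_name), .(report_id, drug_name, role)],
    rs$drugs[order(report_id, drug_name), .(report_id, drug_name, role)]
  )
})

test_that("writing the same set twice is byte-stable", {
  rs <- random_rs(25, seed = 7)
  d <- withr::local_tempdir()
  p1 <- file.path(d, c("a1", "b1", "c1"))
  p2 <- file.path(d, c("a2", "b2", "c2"))
  write_reports(rs, p1[1], p1[2], p1[3])
  write_reports(rs, p2[1], p2[2], p2[3])
  for (i in 1:3) {
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  }
})

test_that("an empty report set writes header-only files", {
  rs <- report_set(
    demo = data.frame(report_id = character(), sex = character(),
                      age_years = double(), country = character(),
                      year = integer()),
    drugs = data.frame(report_id = character(), drug_seq = integer(),
                       drug_name = character(), role = character()),
    reactions = data.frame(report_id = character(), pt = character())
  )
  paths <- file.path(withr::local_tempdir(), c("d", "g", "r"))
  write_reports(rs, paths[1], paths[2], paths[3])
  for (p in paths) expect_length(readLines(p), 1L)
})

test_that("normalization trims, case-folds, collapses spaces, and is idempotent", {
  x <- c("  Carpal  Tunnel   SYNDROME ", "Idursulfase", "a\tb")
  norm <- normalize_term(x)
  expect_equal(norm, c("carpal tunnel syndrome", "idursulfase", "a b"))
  expect_equal(normalize_term(norm), norm)
  # applied on construction
  rs <- make_rs(data.frame(report_id = "r1", drugs = "  IDURsulfase ",
                           pts = "Carpal  Tunnel Syndrome"))
  expect_equal(rs$drugs$drug_name, "idursulfase")
  expect_equal(rs$reactions$pt, "carpal tunnel syndrome")
})

test_that("orphan DRUG/REAC rows are dropped with a warning", {
  d <- withr::local_tempdir()
  writeLines(c("report_id\tsex\tage\tage_unit\tcountry\tevent_year",
               "r1\tF\t60\tYR\tus\t2019"), file.path(d, "demo"))
  writeLines(c("report_id\tdrug_seq\tdrug_name\trole_cod",
               "r1\t1\taspirin\tPS",
               "r9\t1\tghost drug\tPS"), file.path(d, "drug"))
  writeLines(c("report_id\tpt", "r1\theadache", "r9\tnausea"),
             file.path(d, "reac"))
  expect_warning(
    expect_warning(
      rs <- read_reports(file.path(d, "demo"), file.path(d, "drug"),
                         file.path(d, "reac")),
      "DRUG row"
    ),
    "REAC row"
  )
  expect_equal(n_reports(rs), 1L)
  expect_false("ghost drug" %in% rs$drugs$drug_name)
})

test_that("missing mandatory columns fail naming the column", {
  d <- withr::local_tempdir()
  writeLines(c("report_id\tsex\tage\tage_unit\tcountry",
               "r1\tF\t60\tYR\tus"), file.path(d, "demo"))
  writeLines(c("report_id\tdrug_seq\tdrug_name\trole_cod",
               "r1\t1\taspirin\tPS"), file.path(d, "drug"))
  writeLines(c("report_id\tpt", "r1\theadache"), file.path(d, "reac"))
  expect_error(
    read_reports(file.path(d, "demo"), file.path(d, "drug"),
                 file.path(d, "reac")),
    "event_year"
  )
})

test_that("conflicting duplicate demographics are rejected, identical ones collapsed", {
  d <- withr::local_tempdir()
  writeLines(c("report_id\tsex\tage\tage_unit\tcountry\tevent_year",
               "r1\tF\t60\tYR\tus\t2019",
               "r1\tM\t61\tYR\tus\t2019"), file.path(d, "demo"))
  writeLines(c("report_id\tdrug_seq\tdrug_name\trole_cod",
               "r1\t1\taspirin\tPS"), file.path(d, "drug"))
  writeLines(c("report_id\tpt", "r1\theadache"), file.path(d, "reac"))
  expect_error(
    read_reports(file.path(d, "demo"), file.path(d, "drug"),
                 file.path(d, "reac")),
    "conflicting demographics.*r1"
  )
  writeLines(c("report_id\tsex\tage\tage_unit\tcountry\tevent_year",
               "r1\tF\t60\tYR\tus\t2019",
               "r1\tF\t60\tYR\tus\t2019"), file.path(d, "demo"))
  rs <- read_reports(file.path(d, "demo"), file.path(d, "drug"),
                     file.path(d, "reac"))
  expect_equal(n_reports(rs), 1L)
})

test_that("ages in months and days are converted to years on read", {
  d <- withr::local_tempdir()
  writeLines(c("report_id\tsex\tage\tage_unit\tcountry\tevent_year",
               "r1\tF\t24\tMON\tus\t2019",
               "r2\tM\t730.5\tDY\tus\t2019",
               "r3\tUNK\t\t\t\t"), file.path(d, "demo"))
  writeLines(c("report_id\tdrug_seq\tdrug_name\trole_cod",
               "r1\t1\ta\tPS", "r2\t1\ta\tPS", "r3\t1\ta\tPS"),
             file.path(d, "drug"))
  writeLines(c("report_id\tpt", "r1\tx", "r2\tx", "r3\tx"),
             file.path(d, "reac"))
  rs <- read_reports(file.path(d, "demo"), file.path(d, "drug"),
                     file.path(d, "reac"))
  ages <- rs$demo[order(report_id)]$age_years
  expect_equal(ages, c(2, 2, NA_real_))
  expect_equal(rs$demo[order(report_id)]$sex,
               c("female", "male", "unknown"))
})

test_that("report_set enforces its invariants", {
  demo <- data.frame(report_id = "r1", sex = "female", age_years = 50,
                     country = NA, year = 2020L)
  drugs <- data.frame(report_id = "r1", drug_seq = 1L, drug_name = "a",
                      role = "primary_suspect")
  reac <- data.frame(report_id = "r1", pt = "x")
  expect_error(report_set(rbind(demo, demo), rbind(drugs, drugs),
                          rbind(reac, reac)), "duplicate report_id")
  expect_error(report_set(transform(demo, age_years = 150), drugs, reac),
               "age_years")
  expect_error(report_set(demo, drugs[0, ], reac), "without any drug")
  expect_error(report_set(demo, drugs, reac[0, ]), "without any reaction")
  expect_error(
    report_set(demo, transform(drugs, report_id = "zz"), reac),
    "unknown report_id|without any drug"
  )
})
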