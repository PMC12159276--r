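test_that("a minimal one-report spec reconstructs a single report", {
  spec <- margin_spec("event e", n_total = 1, n_event = 1,
                      drugs = data.frame(drug = "drug x", a = 1, n_drug = 1))
  rs <- reconstruct_from_margins(spec, seed = 1)
  expect_equal(n_reports(rs), 1L)
  expect_equal(rs$drugs$drug_name, "drug x")
  expect_equal(rs$reactions$pt, "event e")
})

test_that("reconstruction satisfies every listed margin cell-for-cell", {
  spec <- margin_spec(
    "event e", n_total = 5000, n_event = 120,
    drugs = data.frame(drug = c("drug x", "drug y", "drug z"),
                       a = c(30, 0, 11), n_drug = c(40, 25, 700)),
    demographics = list(n_female = 70, n_male = 40, n_unknown = 10,
                        age_mean = 57, age_sd = 14.9,
                        countries = c("united states" = 80),
                        year_start = 2004, year_end = 2024)
  )
  rs <- reconstruct_from_margins(spec, seed = 42)
  pairs <- count_event_pairs(rs, "event e")
  expect_equal(pairs$n_event, 120L)
  expect_equal(pairs$n_total, 5000L)
  m <- pairs$margins
  for (i in seq_len(nrow(spec$drugs))) {
    row <- m[m$drug == spec$drugs$drug[i], ]
    expect_equal(row$a, spec$drugs$a[i])
    expect_equal(row$n_drug, spec$drugs$n_drug[i])
    t <- build_table(row$a, row$n_drug, pairs$n_event, pairs$n_total)
    expect_equal(t$a + t$b, spec$drugs$n_drug[i])
    expect_equal(t$a + t$c, 120)
  }
  # demographics met exactly on the event reports
  ds <- summarize_reports(rs, "event e")
  expect_equal(ds$sex$n, c(70L, 40L, 10L))
  expect_equal(ds$top_countries$n, 80L)
  expect_true(abs(ds$age_mean - 57) < 3)
  expect_true(all(ds$yearly_counts$year %in% 2004:2024))
})

test_that("margins survive a write/read round-trip, per the brute-force oracle", {
  spec <- margin_spec(
    "event e", n_total = 400, n_event = 25,
    drugs = data.frame(drug = c("drug x", "drug y"),
                       a = c(12, 4), n_drug = c(20, 100))
  )
  rs <- reconstruct_from_margins(spec, seed = 9)
  paths <- file.path(withr::local_tempdir(), c("d", "g", "r"))
  write_reports(rs, paths[1], paths[2], paths[3])
  back <- read_reports(paths[1], paths[2], paths[3])
  slow <- brute_count(back, "event e")
  expect_equal(slow$n_event, 25L)
  expect_equal(slow$margins$a[slow$margins$drug == "drug x"], 12L)
  expect_equal(slow$margins$n_drug[slow$margins$drug == "drug y"], 100L)
})

test_that("reconstruction is deterministic in the seed", {
  spec <- margin_spec(
    "event e", n_total = 300, n_event = 30,
    drugs = data.frame(drug = "drug x", a = 10, n_drug = 50),
    demographics = list(n_female = 20, n_male = 8, n_unknown = 2,
                        age_mean = 60, age_sd = 10,
                        year_start = 2010, year_end = 2020)
  )
  a <- reconstruct_from_margins(spec, seed = 5)
  b <- reconstruct_from_margins(spec, seed = 5)
  c <- reconstruct_from_margins(spec, seed = 6)
  expect_identical(a$demo, b$demo)
  expect_identical(a$drugs, b$drugs)
  expect_false(identical(a$demo, c$demo))
})

test_that("infeasible margin specs are rejected, citing the inequality", {
  d1 <- data.frame(drug = "x", a = 10, n_drug = 5)
  expect_error(margin_spec("e", 100, 20, d1), "a > n_drug")
  d2 <- data.frame(drug = "x", a = 5, n_drug = 200)
  expect_error(margin_spec("e", 100, 20, d2), "n_drug.*n_total")
  d3 <- data.frame(drug = "x", a = 30, n_drug = 50)
  expect_error(margin_spec("e", 100, 20, d3), "sum\\(a\\) > n_event")
  expect_error(margin_spec("e", 100, 200, d1), "a > n_drug|n_event > n_total")
  expect_error(
    margin_spec("e", 100, 20,
                data.frame(drug = "x", a = 5, n_drug = 95)),
    "n_total - sum"
  )
})

test_that("down-scaling preserves margin consistency via largest remainders", {
  spec <- scale_margin_spec(cts_margin_spec(), 1000)
  expect_equal(spec$n_total, 12930)
  expect_lte(sum(spec$drugs$n_drug), spec$n_total)
  expect_lte(sum(spec$drugs$a), spec$n_event)
  expect_true(all(spec$drugs$a <= spec$drugs$n_drug))
  d <- spec$demographics
  expect_equal(d$n_female + d$n_male + d$n_unknown, spec$n_event)
  # reconstruction of the scaled spec verifies end to end
  rs <- reconstruct_from_margins(spec, seed = 2)
  pairs <- count_event_pairs(rs, spec$event_pt)
  expect_equal(pairs$n_total, spec$n_total)
  expect_equal(pairs$n_event, spec$n_event)
})

test_that("margin and simulation specs round-trip through their config files", {
  spec <- cts_margin_spec()
  path <- withr::local_tempfile(fileext = ".txt")
  write_margin_spec(spec, path)
  back <- read_margin_spec(path)
  expect_equal(back$drugs, spec$drugs)
  expect_equal(back$n_total, spec$n_total)
  expect_equal(back$demographics$n_female, spec$demographics$n_female)
  expect_equal(back$demographics$countries, spec$demographics$countries)

  sim <- simulation_spec(5000, injected = data.frame(drug = "drug a",
                                                     target_ror = 8),
                         seed = 77)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_simulation_spec(sim, path2)
  back2 <- read_simulation_spec(path2)
  expect_equal(back2$drugs, sim$drugs)
  expect_equal(back2$injected, sim$injected)
  expect_equal(back2$seed, 77L)
  expect_identical(simulate_reports(back2)$demo, simulate_reports(sim)$demo)
})

test_that("null simulations give RORs clustered near 1", {
  spec <- simulation_spec(n_reports = 60000, background_prob = 0.05,
                          seed = 123)
  rs <- simulate_reports(spec)
  st <- detect_signals(rs, "carpal tunnel syndrome",
                       criteria = signal_criteria(min_cases_custom = 0,
                                                  min_ror = 0))
  expect_true(all(abs(log(st$ror)) < log(1.5)))
  expect_false(any(st$is_signal & st$ror >= 10))
})

test_that("simulation is reproducible from its seed and leaves the RNG alone", {
  spec <- simulation_spec(n_reports = 2000, seed = 31)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- simulate_reports(spec)
  after <- runif(1)
  expect_equal(before, after)  # caller RNG stream untouched
  b <- simulate_reports(spec)
  expect_identical(a$demo, b$demo)
  expect_identical(a$reactions, b$reactions)
})

test_that("an injected association is recovered near its target ROR", {
  spec <- simulation_spec(n_reports = 100000,
                          injected = data.frame(drug = "drug c",
                                                target_ror = 15),
                          seed = 202)
  rs <- simulate_reports(spec)
  pairs <- count_event_pairs(rs, "carpal tunnel syndrome")
  m <- pairs$margins[pairs$margins$drug == "drug c", ]
  est <- ror(build_table(m$a, m$n_drug, pairs$n_event, pairs$n_total))
  expect_true(est$ci_low < 15 && 15 < est$ci_high)
})
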