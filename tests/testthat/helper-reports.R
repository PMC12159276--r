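# Builders and independent oracles shared across the test files.

# Compact report-set builder: `rows` is a data.frame with one row per
# report; `drugs` / `pts` are ";"-separated strings, drugs optionally
# "name:role" with role defaulting to PS.
make_rs <- function(rows) {
  role_map <- c(PS = "primary_suspect", SS = "secondary_suspect",
                C = "concomitant", I = "interacting")
  demo <- data.frame(
    report_id = rows$report_id,
    sex = if ("sex" %in% names(rows)) rows$sex else "unknown",
    age_years = if ("age" %in% names(rows)) rows$age else NA_real_,
    country = if ("country" %in% names(rows)) rows$country else NA_character_,
    year = if ("year" %in% names(rows)) rows$year else NA_integer_
  )
  drugs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    specs <- strsplit(rows$drugs[i], ";", fixed = TRUE)[[1]]
    parts <- strsplit(specs, ":", fixed = TRUE)
    data.frame(
      report_id = rows$report_id[i],
      drug_seq = seq_along(specs),
      drug_name = vapply(parts, `[`, "", 1),
      role = unname(role_map[vapply(parts, function(p) {
        if (length(p) > 1) p[2] else "PS"
      }, "")])
    )
  }))
  reacs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    pts <- strsplit(rows$pts[i], ";", fixed = TRUE)[[1]]
    data.frame(report_id = rows$report_id[i], pt = pts)
  }))
  report_set(demo, drugs, reacs, provenance = "test fixture")
}

# Random small report set for property tests.
random_rs <- function(n_reports, seed) {
  set.seed(seed)
  drugs_pool <- paste("drug", letters[1:6])
  pts_pool <- c("carpal tunnel syndrome", "headache", "nausea", "rash")
  roles <- c("", ":PS", ":SS", ":C", ":I")
  rows <- data.frame(
    report_id = sprintf("r%03d", seq_len(n_reports)),
    sex = sample(c("female", "male", "unknown"), n_reports, TRUE),
    age = ifelse(runif(n_reports) < 0.8,
                 round(runif(n_reports, 1, 95), 1), NA_real_),
    year = sample(2004:2024, n_reports, TRUE),
    drugs = vapply(seq_len(n_reports), function(i) {
      k <- sample(1:3, 1)
      paste0(sample(drugs_pool, k),
             sample(roles, k, TRUE), collapse = ";")
    }, ""),
    pts = vapply(seq_len(n_reports), function(i) {
      paste(sample(pts_pool, sample(1:2, 1)), collapse = ";")
    }, "")
  )
  make_rs(rows)
}

# Independent brute-force contingency oracle: per-report double loop over
# plain R structures, no data.table involvement.
brute_count <- function(rs, event_pt) {
  event_pt <- tolower(trimws(event_pt))
  ids <- rs$demo$report_id
  drugs_by_report <- split(
    rs$drugs[rs$drugs$role == "primary_suspect", ],
    rs$drugs$report_id[rs$drugs$role == "primary_suspect"]
  )
  pts_by_report <- split(rs$reactions$pt, rs$reactions$report_id)
  all_drugs <- sort(unique(
    rs$drugs$drug_name[rs$drugs$role == "primary_suspect"]))
  a <- setNames(integer(length(all_drugs)), all_drugs)
  n_drug <- setNames(integer(length(all_drugs)), all_drugs)
  n_event <- 0L
  for (id in ids) {
    has_event <- event_pt %in% pts_by_report[[id]]
    if (has_event) n_event <- n_event + 1L
    ps <- unique(drugs_by_report[[id]]$drug_name)
    for (d in ps) {
      n_drug[d] <- n_drug[d] + 1L
      if (has_event) a[d] <- a[d] + 1L
    }
  }
  list(margins = data.frame(drug = all_drugs, a = unname(a),
                            n_drug = unname(n_drug)),
       n_event = n_event, n_total = length(ids))
}

# Margins printed in the published CTS screen (drug, a, n_drug), with the
# database totals; used by several files.
cts_printed_margins <- function() {
  data.frame(
    drug = c("idursulfase", "galsulfase", "laronidase", "tesamorelin",
             "anastrozole", "alendronic acid", "gamma-hydroxybutyric acid",
             "rofecoxib", "alendronate", "tafamidis"),
    a = c(54L, 20L, 28L, 23L, 109L, 151L, 14L, 268L, 157L, 55L),
    n_drug = c(2064L, 1435L, 2577L, 2130L, 10273L, 17251L, 1640L,
               32890L, 23592L, 8770L),
    stringsAsFactors = FALSE
  )
}
CTS_N_EVENT <- 6837L
CTS_N_TOTAL <- 12929504
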