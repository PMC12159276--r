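## Synthetic report-set generation: exact reconstruction of a specified
## set of 2x2 margins (so a whole published margin table can be turned
## back into a report database cell-for-cell), and seeded stochastic
## simulation with injected drug-event associations of known strength.

# Internal report_set builder for the generators, which guarantee the
# class invariants by construction (unique ids, normalized names,
# non-empty drug/reaction rows). Skips the constructor's O(N) validation
# scans and shares the report_id vector across the three tables, keeping
# database-scale materialization (tens of millions of rows) inside a
# couple of GB.
fast_report_set <- function(demo, drugs, reactions, provenance) {
  structure(
    list(demo = setDT(demo), drugs = setDT(drugs),
         reactions = setDT(reactions), provenance = provenance),
    class = "report_set"
  )
}

#' Exact-margin specification for synthetic report sets
#'
#' Describes a report database by its drug-event margins: the database
#' size `n_total`, the target-event total `n_event`, and for each listed
#' drug the pair `(a, n_drug)` — event reports with the drug as primary
#' suspect, and total primary-suspect reports. Reports not accounted for
#' by the listed drugs are assigned a filler drug, and non-event reports
#' a filler reaction term, so that [reconstruct_from_margins()] can emit
#' a report set reproducing every listed 2x2 table exactly.
#'
#' @param event_pt target preferred term.
#' @param n_total total number of reports.
#' @param n_event reports naming the event.
#' @param drugs data.frame with columns `drug`, `a`, `n_drug`.
#' @param filler_drug drug name for reports not covered by `drugs`.
#' @param filler_pt reaction term for non-event reports (must differ
#'   from `event_pt`).
#' @param demographics optional list describing the event reports'
#'   demographics: `n_female`, `n_male`, `n_unknown` (must sum to
#'   `n_event`), `age_mean`, `age_sd` (years), `countries` (named
#'   integer vector of counts, summing to at most `n_event`; the
#'   remainder gets no stated country), `year_start`, `year_end`.
#' @return An object of class `margin_spec`.
#' @seealso [reconstruct_from_margins()], [scale_margin_spec()],
#'   [read_margin_spec()], [cts_margin_spec()]
#' @export
margin_spec <- function(event_pt, n_total, n_event, drugs,
                        filler_drug = "other suspect drug",
                        filler_pt = "drug ineffective",
                        demographics = NULL) {
  stopifnot_scalar_string(event_pt, "event_pt")
  n_total <- stopifnot_count(n_total, "n_total", min = 1)
  n_event <- stopifnot_count(n_event, "n_event")
  stopifnot(is.data.frame(drugs),
            all(c("drug", "a", "n_drug") %in% names(drugs)))
  drugs <- data.frame(drug = normalize_term(drugs$drug),
                      a = as.integer(drugs$a),
                      n_drug = as.integer(drugs$n_drug),
                      stringsAsFactors = FALSE)
  event_pt <- normalize_term(event_pt)
  filler_drug <- normalize_term(filler_drug)
  filler_pt <- normalize_term(filler_pt)
  if (identical(filler_pt, event_pt)) {
    stop("filler_pt must differ from event_pt", call. = FALSE)
  }
  if (filler_drug %in% drugs$drug) {
    stop("filler_drug must not appear among the listed drugs",
         call. = FALSE)
  }
  if (anyDuplicated(drugs$drug)) {
    stop("duplicated drug names in margin spec", call. = FALSE)
  }
  bad <- drugs$a > drugs$n_drug
  if (any(bad)) {
    stop("infeasible margins: a > n_drug for drug(s) ",
         paste(drugs$drug[bad], collapse = ", "), call. = FALSE)
  }
  if (sum(drugs$n_drug) > n_total) {
    stop("infeasible margins: sum(n_drug) > n_total (",
         sum(drugs$n_drug), " > ", n_total, ")", call. = FALSE)
  }
  if (sum(drugs$a) > n_event) {
    stop("infeasible margins: sum(a) > n_event (", sum(drugs$a), " > ",
         n_event, ")", call. = FALSE)
  }
  if (n_event > n_total) {
    stop("infeasible margins: n_event > n_total", call. = FALSE)
  }
  # event reports not claimed by listed drugs need the filler drug as
  # their primary suspect; the filler must have room for them
  if (n_event - sum(drugs$a) > n_total - sum(drugs$n_drug)) {
    stop("infeasible margins: n_event - sum(a) > n_total - sum(n_drug)",
         call. = FALSE)
  }
  if (!is.null(demographics)) {
    d <- demographics
    need <- c("n_female", "n_male", "n_unknown")
    if (!all(need %in% names(d))) {
      stop("demographics must contain n_female, n_male, n_unknown",
           call. = FALSE)
    }
    if (d$n_female + d$n_male + d$n_unknown != n_event) {
      stop("demographics sex counts must sum to n_event (",
           d$n_female + d$n_male + d$n_unknown, " != ", n_event, ")",
           call. = FALSE)
    }
    if (!is.null(d$countries) && sum(d$countries) > n_event) {
      stop("demographics country counts exceed n_event", call. = FALSE)
    }
  }
  structure(
    list(event_pt = event_pt, n_total = n_total, n_event = n_event,
         drugs = drugs, filler_drug = filler_drug, filler_pt = filler_pt,
         demographics = demographics),
    class = "margin_spec"
  )
}

#' @export
print.margin_spec <- function(x, ...) {
  cat("<margin_spec> event: '", x$event_pt, "'\n", sep = "")
  cat("  n_total=", format(x$n_total, big.mark = ","),
      ", n_event=", format(x$n_event, big.mark = ","),
      ", ", nrow(x$drugs), " listed drug(s)",
      if (!is.null(x$demographics)) ", with demographics", "\n", sep = "")
  invisible(x)
}

# largest-remainder apportionment of `total` across `counts`
lr_apportion <- function(counts, total) {
  counts <- as.double(counts)
  if (sum(counts) == 0) return(integer(length(counts)))
  quota <- counts * total / sum(counts)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    pick <- order(-(quota - base), -counts, seq_along(counts))[seq_len(rem)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

#' Down-scale a margin specification
#'
#' Divides every count of a [margin_spec()] by `factor`, apportioning
#' with the largest-remainder method so that all totals remain mutually
#' consistent (cells still sum to margins, margins to the total). Useful
#' for materializing small report sets whose statistical structure
#' mirrors a database-scale specification.
#'
#' @param spec a [margin_spec()].
#' @param factor scale divisor (> 1).
#' @return A new, smaller `margin_spec`.
#' @export
scale_margin_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "margin_spec"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1) {
    stop("`factor` must be a scalar > 1", call. = FALSE)
  }
  n_total <- max(1L, as.integer(round(spec$n_total / factor)))
  n_event <- lr_apportion(c(spec$n_event, spec$n_total - spec$n_event),
                          n_total)[1L]
  filler_nd <- spec$n_total - sum(spec$drugs$n_drug)
  nd <- lr_apportion(c(spec$drugs$n_drug, filler_nd), n_total)
  nd_drugs <- nd[seq_len(nrow(spec$drugs))]
  a <- lr_apportion(c(spec$drugs$a, spec$n_event - sum(spec$drugs$a)),
                    n_event)
  a_drugs <- pmin(a[seq_len(nrow(spec$drugs))], nd_drugs)

  demo <- spec$demographics
  if (!is.null(demo)) {
    sexes <- lr_apportion(c(demo$n_female, demo$n_male, demo$n_unknown),
                          n_event)
    demo$n_female <- sexes[1L]
    demo$n_male <- sexes[2L]
    demo$n_unknown <- sexes[3L]
    if (!is.null(demo$countries)) {
      cc <- lr_apportion(c(demo$countries, spec$n_event - sum(demo$countries)),
                         n_event)
      demo$countries <- stats::setNames(cc[seq_along(demo$countries)],
                                        names(demo$countries))
    }
  }
  margin_spec(spec$event_pt, n_total, n_event,
              data.frame(drug = spec$drugs$drug, a = a_drugs,
                         n_drug = nd_drugs, stringsAsFactors = FALSE),
              filler_drug = spec$filler_drug, filler_pt = spec$filler_pt,
              demographics = demo)
}

#' Reconstruct a report set with exact drug-event margins
#'
#' Materializes a [report_set()] that satisfies a [margin_spec()]
#' cell-for-cell: for every listed drug, [count_event_pairs()] on the
#' result returns exactly `(a, n_drug)`, the overall event count is
#' `n_event`, and the set holds `n_total` reports. Each synthetic report
#' carries exactly one primary-suspect drug and one reaction (the event
#' or the filler term). When the spec includes demographics, the sex,
#' country and year requirements are met exactly on the event reports
#' (assignment order is shuffled under `seed`), and ages are drawn from
#' a normal distribution with the requested mean and standard deviation
#' (truncated to \[0, 130\], rounded to 0.1 years), so the realized age
#' moments match approximately. Non-event reports get unknown sex and no
#' stated age, country or year; published summaries constrain only the
#' event reports' demographics.
#'
#' @param spec a [margin_spec()].
#' @param seed integer seed for the demographic assignment.
#' @param scale optional divisor; when > 1 the spec is first reduced
#'   with [scale_margin_spec()].
#' @return A [report_set()].
#' @examples
#' spec <- margin_spec("carpal tunnel syndrome", n_total = 1000,
#'                     n_event = 40,
#'                     drugs = data.frame(drug = "anastrozole", a = 12,
#'                                        n_drug = 60))
#' rs <- reconstruct_from_margins(spec, seed = 1)
#' count_event_pairs(rs, "carpal tunnel syndrome")$margins
#' @export
reconstruct_from_margins <- function(spec, seed = 1L, scale = 1) {
  stopifnot(inherits(spec, "margin_spec"))
  if (scale > 1) spec <- scale_margin_spec(spec, scale)
  with_seed(seed, {
    k <- nrow(spec$drugs)
    ev_fill <- spec$n_event - sum(spec$drugs$a)
    non_ev <- spec$drugs$n_drug - spec$drugs$a
    non_fill <- spec$n_total - sum(spec$drugs$n_drug) - ev_fill

    drug_names <- c(spec$drugs$drug, spec$filler_drug)
    # event reports first (ids 1..n_event), then non-event reports
    drug_col <- c(rep(drug_names, c(spec$drugs$a, ev_fill)),
                  rep(drug_names, c(non_ev, non_fill)))
    pt_col <- rep(c(spec$event_pt, spec$filler_pt),
                  c(spec$n_event, spec$n_total - spec$n_event))
    ids <- paste0("R", seq_len(spec$n_total))

    sex <- rep("unknown", spec$n_total)
    age <- rep(NA_real_, spec$n_total)
    ctry <- rep(NA_character_, spec$n_total)
    yr <- rep(NA_integer_, spec$n_total)
    d <- spec$demographics
    if (!is.null(d) && spec$n_event > 0) {
      ev <- seq_len(spec$n_event)
      sex[ev] <- sample(rep(c("female", "male", "unknown"),
                            c(d$n_female, d$n_male, d$n_unknown)))
      if (!is.null(d$age_mean)) {
        draw <- rnorm(spec$n_event, d$age_mean, d$age_sd %||% 0)
        while (any(bad <- draw < 0 | draw > 130)) {
          draw[bad] <- rnorm(sum(bad), d$age_mean, d$age_sd %||% 0)
        }
        age[ev] <- round(draw, 1)
      }
      if (!is.null(d$countries)) {
        cvec <- rep(c(names(d$countries), NA_character_),
                    c(d$countries, spec$n_event - sum(d$countries)))
        ctry[ev] <- sample(cvec)
      }
      if (!is.null(d$year_start)) {
        yr[ev] <- sample(seq.int(d$year_start, d$year_end),
                         spec$n_event, replace = TRUE)
      }
    }
    n <- spec$n_total
    fast_report_set(
      demo = list(report_id = ids, sex = sex, age_years = age,
                  country = ctry, year = yr),
      drugs = list(report_id = ids, drug_seq = rep(1L, n),
                   drug_name = drug_col,
                   role = rep("primary_suspect", n)),
      reactions = list(report_id = ids, pt = pt_col),
      provenance = sprintf("reconstructed from margins (seed %d)",
                           as.integer(seed))
    )
  })
}

#' Stochastic simulation specification
#'
#' Parameters for [simulate_reports()]: a drug catalogue with marginal
#' probabilities, a background event probability, and a list of injected
#' drug-event associations expressed as target reporting odds ratios.
#' For an injected drug with target ROR `r`, the per-report event
#' probability is raised to `q = r o / (1 + r o)` where
#' `o = p/(1 - p)` is the background event odds, so the expected odds
#' ratio of the injected drug's 2x2 table against the (background)
#' comparator equals `r`.
#'
#' @param n_reports number of reports to simulate.
#' @param drugs drug catalogue: data.frame with columns `drug` and
#'   `prob` (marginal probability of being the report's primary
#'   suspect; normalized to sum to 1). Default: ten generic drugs with
#'   equal probability.
#' @param event_pt target preferred term.
#' @param background_prob event probability for non-injected drugs,
#'   in (0, 1).
#' @param injected data.frame with columns `drug` and `target_ror`
#'   (strictly positive), or `NULL` for a null database.
#' @param filler_pt reaction recorded when the event does not occur.
#' @param sex_probs named probabilities for `female`, `male`, `unknown`.
#' @param age_mean,age_sd age model for all reports (years).
#' @param year_range two calendar years bounding the report dates.
#' @param seed integer seed making generation fully reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_reports,
                            drugs = NULL,
                            event_pt = "carpal tunnel syndrome",
                            background_prob = 0.01,
                            injected = NULL,
                            filler_pt = "drug ineffective",
                            sex_probs = c(female = 0.45, male = 0.45,
                                          unknown = 0.10),
                            age_mean = 57, age_sd = 15,
                            year_range = c(2004L, 2024L),
                            seed = 1L) {
  n_reports <- stopifnot_count(n_reports, "n_reports", min = 1)
  if (is.null(drugs)) {
    drugs <- data.frame(drug = paste("drug", letters[1:10]),
                        prob = rep(0.1, 10), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(drugs), all(c("drug", "prob") %in% names(drugs)))
  drugs$drug <- normalize_term(drugs$drug)
  if (any(drugs$prob <= 0) || sum(drugs$prob) <= 0) {
    stop("drug catalogue probabilities must be positive", call. = FALSE)
  }
  drugs$prob <- drugs$prob / sum(drugs$prob)
  if (background_prob <= 0 || background_prob >= 1) {
    stop("background_prob must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(injected)) {
    stopifnot(is.data.frame(injected),
              all(c("drug", "target_ror") %in% names(injected)))
    injected$drug <- normalize_term(injected$drug)
    if (!all(injected$drug %in% drugs$drug)) {
      stop("injected drug(s) absent from catalogue: ",
           paste(setdiff(injected$drug, drugs$drug), collapse = ", "),
           call. = FALSE)
    }
    if (any(injected$target_ror <= 0)) {
      stop("target_ror must be strictly positive", call. = FALSE)
    }
  }
  event_pt <- normalize_term(event_pt)
  filler_pt <- normalize_term(filler_pt)
  if (identical(event_pt, filler_pt)) {
    stop("filler_pt must differ from event_pt", call. = FALSE)
  }
  structure(
    list(n_reports = n_reports, drugs = drugs, event_pt = event_pt,
         background_prob = background_prob, injected = injected,
         filler_pt = filler_pt,
         sex_probs = sex_probs / sum(sex_probs),
         age_mean = age_mean, age_sd = age_sd,
         year_range = as.integer(year_range), seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a report database with injected associations
#'
#' Draws each report's primary-suspect drug from the catalogue, then the
#' target event with the background probability — raised, for injected
#' drugs, so the expected odds ratio equals the requested `target_ror`
#' (see [simulation_spec()]). Demographics (sex, age, year) are drawn
#' from the spec's demographic model for every report. Generation is
#' fully reproducible from the spec's seed and leaves the caller's RNG
#' state untouched.
#'
#' @param spec a [simulation_spec()].
#' @return A [report_set()].
#' @examples
#' spec <- simulation_spec(
#'   n_reports = 20000,
#'   injected = data.frame(drug = "drug a", target_ror = 20),
#'   seed = 42
#' )
#' st <- detect_signals(simulate_reports(spec), "carpal tunnel syndrome")
#' head(st, 3)
#' @export
simulate_reports <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_reports
    k <- nrow(spec$drugs)
    idx <- sample.int(k, n, replace = TRUE, prob = spec$drugs$prob)

    p0 <- spec$background_prob
    odds0 <- p0 / (1 - p0)
    p_by_drug <- rep(p0, k)
    if (!is.null(spec$injected)) {
      j <- match(spec$injected$drug, spec$drugs$drug)
      p_by_drug[j] <- spec$injected$target_ror * odds0 /
        (1 + spec$injected$target_ror * odds0)
    }
    event <- rbinom(n, 1L, p_by_drug[idx]) == 1L

    ages <- rnorm(n, spec$age_mean, spec$age_sd)
    while (any(bad <- ages < 0 | ages > 130)) {
      ages[bad] <- rnorm(sum(bad), spec$age_mean, spec$age_sd)
    }
    ids <- paste0("S", seq_len(n))
    fast_report_set(
      demo = list(
        report_id = ids,
        sex = sample(names(spec$sex_probs), n, replace = TRUE,
                     prob = spec$sex_probs),
        age_years = round(ages, 1),
        country = rep(NA_character_, n),
        year = sample(seq.int(spec$year_range[1L], spec$year_range[2L]),
                      n, replace = TRUE)
      ),
      drugs = list(report_id = ids, drug_seq = rep(1L, n),
                   drug_name = spec$drugs$drug[idx],
                   role = rep("primary_suspect", n)),
      reactions = list(report_id = ids,
                       pt = ifelse(event, spec$event_pt, spec$filler_pt)),
      provenance = sprintf("simulated (seed %d)", spec$seed)
    )
  })
}
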