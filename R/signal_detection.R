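## Layered signal criteria: Evans thresholds (case floor, PRR, chi2),
## BCPNN validation (IC025 > 0), and conservative custom floors on case
## count and ROR, combined by conjunction into an overall signal flag.

#' Signal-detection criteria
#'
#' Thresholds for the three layers of the signal decision:
#' \itemize{
#'   \item Evans criteria: at least `min_cases_evans` reports of the pair
#'     (default 3), PRR at least `min_prr` (default 2), chi-squared at
#'     least `min_chi2` (default 4).
#'   \item BCPNN validation: IC025 strictly above 0 (switch with
#'     `require_ic025_positive`).
#'   \item Custom floors filtering low-count spurious associations: the
#'     drug must be primary suspect in at least `min_cases_custom` event
#'     reports (default 10) with an ROR of at least `min_ror`
#'     (default 10).
#' }
#'
#' @param min_cases_evans,min_prr,min_chi2 Evans thresholds.
#' @param require_ic025_positive require IC025 > 0.
#' @param min_cases_custom,min_ror custom floors.
#' @return An object of class `signal_criteria`.
#' @references Evans SJ, Waller PC, Davis S. Use of proportional
#'   reporting ratios (PRRs) in spontaneous reporting of adverse drug
#'   reactions. Pharmacoepidemiol Drug Saf. 2001;10(6):483-486.
#' @export
signal_criteria <- function(min_cases_evans = 3, min_prr = 2,
                            min_chi2 = 4, require_ic025_positive = TRUE,
                            min_cases_custom = 10, min_ror = 10) {
  thr <- list(min_cases_evans = min_cases_evans, min_prr = min_prr,
              min_chi2 = min_chi2,
              require_ic025_positive = isTRUE(require_ic025_positive),
              min_cases_custom = min_cases_custom, min_ror = min_ror)
  num <- thr[c("min_cases_evans", "min_prr", "min_chi2",
               "min_cases_custom", "min_ror")]
  if (any(vapply(num, function(v) !is.numeric(v) || length(v) != 1L ||
                   is.na(v) || v < 0, logical(1L)))) {
    stop("all thresholds must be non-negative scalars", call. = FALSE)
  }
  structure(thr, class = "signal_criteria")
}

#' Evaluate the signal criteria for one drug-event pair
#'
#' Applies a [signal_criteria()] object to one [disproportionality()]
#' result. `NA` statistics (e.g. an undefined ROR from a zero cell) fail
#' the corresponding check.
#'
#' @param r a `disprop_result` from [disproportionality()].
#' @param criteria a [signal_criteria()] object.
#' @return An object of class `signal_decision`: a list with `drug`,
#'   `result`, and booleans `evans_pass`, `bcpnn_pass`, `custom_pass`,
#'   `is_signal` (the conjunction of the three layers).
#' @export
evaluate_pair <- function(r, criteria = signal_criteria()) {
  stopifnot(inherits(r, "disprop_result"),
            inherits(criteria, "signal_criteria"))
  a <- r$table$a
  ge <- function(x, thr) !is.na(x) && x >= thr
  evans <- ge(a, criteria$min_cases_evans) &&
    ge(r$prr, criteria$min_prr) && ge(r$chi2, criteria$min_chi2)
  bcpnn <- if (criteria$require_ic025_positive) {
    !is.na(r$ic025) && r$ic025 > 0
  } else TRUE
  custom <- ge(a, criteria$min_cases_custom) && ge(r$ror, criteria$min_ror)
  structure(
    list(drug = r$table$drug, result = r, evans_pass = evans,
         bcpnn_pass = bcpnn, custom_pass = custom,
         is_signal = evans && bcpnn && custom),
    class = "signal_decision"
  )
}

#' @export
print.signal_decision <- function(x, ...) {
  cat("<signal_decision> ", x$drug, ": ",
      if (x$is_signal) "SIGNAL" else "no signal",
      " (evans=", x$evans_pass, ", bcpnn=", x$bcpnn_pass,
      ", custom=", x$custom_pass, ")\n", sep = "")
  invisible(x)
}

#' Screen a report set for disproportionality signals
#'
#' Full pipeline for one target event: computes per-drug margins with
#' [count_event_pairs()], builds each 2x2 table against all other drugs,
#' computes the disproportionality statistics, and applies the signal
#' criteria. Drugs never seen as primary suspect on an event report
#' (`a = 0`) are retained in the output for audit, with `NA` ROR/PRR,
#' but can never be signals.
#'
#' @param rs a [report_set()].
#' @param event_pt target preferred term.
#' @param criteria a [signal_criteria()] object.
#' @param priors a [bcpnn_priors()] object.
#' @param z normal quantile for the ROR confidence interval.
#' @param correction Haldane-Anscombe correction for ROR/PRR (see
#'   [ror()]).
#' @param yates Yates correction for the chi-squared statistic.
#' @return A `signal_table`: a data.frame with one row per drug and
#'   columns `drug, a, n_drug, pct_event, ror, ci_low, ci_high, prr,
#'   chi2, ic_expected, ic025, evans_pass, bcpnn_pass, custom_pass,
#'   is_signal`, sorted with signals first (by ROR descending), then
#'   non-signals by ROR descending (`NA` last), ties broken by drug name.
#'   Attributes `event_pt`, `n_event`, `n_total` and `n_pairs_tested`
#'   carry the screen's context. If the event never occurs in `rs`, an
#'   empty table is returned with a warning.
#' @seealso [detect_signals_from_margins()] for screening pre-computed
#'   margins without materialized reports.
#' @export
detect_signals <- function(rs, event_pt, criteria = signal_criteria(),
                           priors = bcpnn_priors(), z = 1.96,
                           correction = FALSE, yates = TRUE) {
  pairs <- count_event_pairs(rs, event_pt)
  if (pairs$n_event == 0L) {
    warning("event '", normalize_term(event_pt),
            "' does not occur in the report set", call. = FALSE)
    return(empty_signal_table(normalize_term(event_pt), 0L, pairs$n_total))
  }
  detect_signals_from_margins(pairs$margins, pairs$n_event, pairs$n_total,
                              event_pt = pairs$event_pt,
                              criteria = criteria, priors = priors, z = z,
                              correction = correction, yates = yates)
}

#' Screen pre-computed drug-event margins for signals
#'
#' Same decision pipeline as [detect_signals()], starting from per-drug
#' margins `(a, n_drug)` plus the event and database totals instead of a
#' materialized report set. Exact-margin verification at full database
#' scale (millions of reports) is cheap in this form, because every
#' statistic depends on the 2x2 table only.
#'
#' @param margins data.frame with columns `drug`, `a`, `n_drug` (as
#'   produced by [count_event_pairs()] or [margin_spec()]).
#' @param n_event reports with the event in the whole database.
#' @param n_total total reports in the database.
#' @param event_pt label for the target event.
#' @inheritParams detect_signals
#' @return A `signal_table` data.frame; see [detect_signals()].
#' @export
detect_signals_from_margins <- function(margins, n_event, n_total,
                                        event_pt = "",
                                        criteria = signal_criteria(),
                                        priors = bcpnn_priors(), z = 1.96,
                                        correction = FALSE, yates = TRUE) {
  stopifnot(is.data.frame(margins),
            all(c("drug", "a", "n_drug") %in% names(margins)),
            inherits(criteria, "signal_criteria"))
  n_event <- stopifnot_count(n_event, "n_event")
  n_total <- stopifnot_count(n_total, "n_total", min = 1)

  rows <- lapply(seq_len(nrow(margins)), function(i) {
    t <- build_table(margins$a[i], margins$n_drug[i], n_event, n_total,
                     drug = margins$drug[i], event_pt = event_pt)
    r <- disproportionality(t, z = z, correction = correction,
                            yates = yates, priors = priors)
    d <- evaluate_pair(r, criteria)
    data.frame(
      drug = margins$drug[i], a = t$a, n_drug = t$a + t$b,
      pct_event = 100 * t$a / (t$a + t$b),
      ror = r$ror, ci_low = r$ror_ci_low, ci_high = r$ror_ci_high,
      prr = r$prr, chi2 = r$chi2, ic_expected = r$ic_expected,
      ic025 = r$ic025, evans_pass = d$evans_pass,
      bcpnn_pass = d$bcpnn_pass, custom_pass = d$custom_pass,
      is_signal = d$is_signal, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(empty_signal_table(event_pt, n_event, n_total))
  }
  # signals first by ROR descending, then non-signals by ROR descending;
  # NA RORs sort last; ties broken by drug name ascending
  ror_key <- ifelse(is.na(out$ror), -Inf, out$ror)
  out <- out[order(-out$is_signal, -ror_key, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, event_pt = event_pt, n_event = as.integer(n_event),
            n_total = as.double(n_total), n_pairs_tested = nrow(out),
            class = c("signal_table", "data.frame"))
}

empty_signal_table <- function(event_pt, n_event, n_total) {
  out <- data.frame(
    drug = character(), a = integer(), n_drug = integer(),
    pct_event = double(), ror = double(), ci_low = double(),
    ci_high = double(), prr = double(), chi2 = double(),
    ic_expected = double(), ic025 = double(), evans_pass = logical(),
    bcpnn_pass = logical(), custom_pass = logical(), is_signal = logical(),
    stringsAsFactors = FALSE
  )
  structure(out, event_pt = event_pt, n_event = as.integer(n_event),
            n_total = as.double(n_total), n_pairs_tested = 0L,
            class = c("signal_table", "data.frame"))
}

#' @export
`[.signal_table` <- function(x, ...) {
  # a subset is no longer the full screen: hand back a plain data.frame
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.signal_table <- function(x, max_rows = 20L, ...) {
  cat("<signal_table> event: '", attr(x, "event_pt"), "' — ",
      format(attr(x, "n_event"), big.mark = ","), " of ",
      format(attr(x, "n_total"), big.mark = ","), " reports; ",
      attr(x, "n_pairs_tested"), " drug-event pairs tested, ",
      sum(x$is_signal), " signal(s)\n", sep = "")
  if (nrow(x)) {
    shown <- head(as.data.frame(x), max_rows)
    shown$pct_event <- round(shown$pct_event, 1)
    for (col in c("ror", "ci_low", "ci_high")) {
      shown[[col]] <- round(shown[[col]], 1)
    }
    for (col in c("prr", "chi2", "ic_expected", "ic025")) {
      shown[[col]] <- round(shown[[col]], 2)
    }
    print(shown)
    if (nrow(x) > max_rows) cat("... and", nrow(x) - max_rows, "more rows\n")
  }
  invisible(x)
}

#' Write a signal table to TSV
#'
#' Presentation rounding is applied here (and only here): ROR, its
#' confidence bounds, and the event percentage to 1 decimal place; PRR,
#' chi-squared and the IC statistics to 2. A footer-style comment line is
#' not written; the companion run manifest records totals and the number
#' of pairs tested.
#'
#' @param st a `signal_table` from [detect_signals()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_signal_table <- function(st, path) {
  stopifnot(inherits(st, "signal_table"))
  out <- as.data.frame(st)
  out$pct_event <- round(out$pct_event, 1)
  for (col in c("ror", "ci_low", "ci_high")) out[[col]] <- round(out[[col]], 1)
  for (col in c("prr", "chi2", "ic_expected", "ic025")) {
    out[[col]] <- round(out[[col]], 2)
  }
  fwrite(as.data.table(out), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
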