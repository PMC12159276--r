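## Demographic and temporal summary of the reports naming a target event:
## sex breakdown, age distribution, top reporting countries, and per-year
## report counts.

#' Summarize demographics of the reports naming an event
#'
#' Restricts the report set to reports whose reactions include
#' `event_pt` and summarizes them: sex counts with percentages (against
#' the event-report count), mean and sample standard deviation of age
#' over reports with a stated age, the most frequent reporting countries,
#' and per-year report counts over the observed years.
#'
#' @param rs a [report_set()].
#' @param event_pt target preferred term.
#' @param top_countries how many countries to keep in the country
#'   breakdown.
#' @return An object of class `demographic_summary`: a list with
#'   `event_pt`, `n_event`, `n_total`, `pct_event` (= 100 n_event /
#'   n_total, unrounded), `sex` (data.frame `sex, n, pct` with `pct`
#'   rounded to 1 d.p.), `age_mean`, `age_sd`, `n_age_known`,
#'   `top_countries` (data.frame `country, n, pct`), and `yearly_counts`
#'   (data.frame `year, n` over observed years).
#' @examples
#' rs <- simulate_reports(simulation_spec(n_reports = 500, seed = 7))
#' summarize_reports(rs, "carpal tunnel syndrome")
#' @export
summarize_reports <- function(rs, event_pt, top_countries = 5L) {
  stopifnot(inherits(rs, "report_set"))
  stopifnot_scalar_string(event_pt, "event_pt")
  if (nrow(rs$demo) == 0L) stop("report set is empty", call. = FALSE)
  event_pt <- normalize_term(event_pt)

  ev_ids <- unique(rs$reactions[pt == event_pt, report_id])
  n_event <- length(ev_ids)
  n_total <- nrow(rs$demo)
  demo <- rs$demo[report_id %chin% ev_ids]

  sex_n <- vapply(c("female", "male", "unknown"),
                  function(s) sum(demo$sex == s), integer(1L))
  sex_df <- data.frame(
    sex = names(sex_n), n = unname(sex_n),
    pct = if (n_event > 0) round(100 * unname(sex_n) / n_event, 1) else
      rep(NA_real_, 3L),
    stringsAsFactors = FALSE
  )

  ages <- demo$age_years[!is.na(demo$age_years)]
  ctry <- demo$country[!is.na(demo$country)]
  if (length(ctry) && n_event > 0) {
    tab <- sort(table(ctry), decreasing = TRUE)
    tab <- head(tab, top_countries)
    ctry_df <- data.frame(
      country = names(tab), n = as.integer(tab),
      pct = round(100 * as.integer(tab) / n_event, 1),
      stringsAsFactors = FALSE
    )
  } else {
    ctry_df <- data.frame(country = character(), n = integer(),
                          pct = double(), stringsAsFactors = FALSE)
  }

  yrs <- demo$year[!is.na(demo$year)]
  if (length(yrs)) {
    ytab <- table(yrs)
    year_df <- data.frame(year = as.integer(names(ytab)),
                          n = as.integer(ytab))
  } else {
    year_df <- data.frame(year = integer(), n = integer())
  }

  structure(
    list(event_pt = event_pt, n_event = n_event, n_total = n_total,
         pct_event = 100 * n_event / n_total, sex = sex_df,
         age_mean = if (length(ages)) mean(ages) else NA_real_,
         age_sd = if (length(ages) > 1L) sd(ages) else NA_real_,
         n_age_known = length(ages), top_countries = ctry_df,
         yearly_counts = year_df),
    class = "demographic_summary"
  )
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat("<demographic_summary> event: '", x$event_pt, "'\n", sep = "")
  cat(sprintf("  %s of %s reports (%.2f%%) name the event\n",
              format(x$n_event, big.mark = ","),
              format(x$n_total, big.mark = ","), x$pct_event))
  if (x$n_event > 0) {
    s <- x$sex
    cat(sprintf("  sex: %d female (%.1f%%), %d male (%.1f%%), %d unknown (%.1f%%)\n",
                s$n[1], s$pct[1], s$n[2], s$pct[2], s$n[3], s$pct[3]))
    if (!is.na(x$age_mean)) {
      cat(sprintf("  age: %.1f +/- %.1f years (n=%d with stated age)\n",
                  x$age_mean, x$age_sd, x$n_age_known))
    }
    if (nrow(x$top_countries)) {
      cat("  top countries: ",
          paste0(x$top_countries$country, " (", x$top_countries$n, ", ",
                 x$top_countries$pct, "%)", collapse = ", "), "\n", sep = "")
    }
    if (nrow(x$yearly_counts)) {
      cat("  years: ", min(x$yearly_counts$year), "-",
          max(x$yearly_counts$year), " (", sum(x$yearly_counts$n),
          " dated reports)\n", sep = "")
    }
  }
  invisible(x)
}

#' Write demographic summary tables to TSV
#'
#' `write_summary()` writes a long key/value TSV of the headline numbers
#' plus the sex and country breakdowns; `write_yearly_counts()` writes
#' the per-year event-report counts (the tabular form of the usual
#' reports-per-year bar chart).
#'
#' @param ds a [summarize_reports()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_summary <- function(ds, path) {
  stopifnot(inherits(ds, "demographic_summary"))
  rows <- data.table(
    field = c("event_pt", "n_event", "n_total", "pct_event",
              paste0("n_", ds$sex$sex), paste0("pct_", ds$sex$sex),
              "age_mean", "age_sd", "n_age_known",
              if (nrow(ds$top_countries))
                paste0("n_country_", ds$top_countries$country)),
    value = c(ds$event_pt, ds$n_event, ds$n_total,
              sprintf("%.2f", ds$pct_event),
              ds$sex$n, sprintf("%.1f", ds$sex$pct),
              sprintf("%.1f", ds$age_mean), sprintf("%.1f", ds$age_sd),
              ds$n_age_known,
              if (nrow(ds$top_countries)) ds$top_countries$n)
  )
  fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
write_yearly_counts <- function(ds, path) {
  stopifnot(inherits(ds, "demographic_summary"))
  fwrite(as.data.table(ds$yearly_counts), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Bar chart of event reports per year
#'
#' Plots the `yearly_counts` component of a [summarize_reports()] result
#' as a bar chart (requires ggplot2).
#'
#' @param ds a [summarize_reports()] result.
#' @return A ggplot object.
#' @export
plot_yearly_counts <- function(ds) {
  stopifnot(inherits(ds, "demographic_summary"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(ds$yearly_counts, ggplot2::aes(x = year, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Year", y = "Reports",
                  title = paste0("Reports naming '", ds$event_pt,
                                 "' per year")) +
    ggplot2::theme_minimal()
}
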