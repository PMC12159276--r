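## Key/value text serialization for margin and simulation specifications.
##
## The format is line-based: `key = value` pairs, `#` comments, blank
## lines ignored. Repeatable keys carry `;`-separated fields:
##   drug    = <name>; <a>; <n_drug>        (margin spec)
##   country = <name>; <count>              (margin spec demographics)
##   drug    = <name>; <prob>               (simulation spec catalogue)
##   inject  = <name>; <target_ror>         (simulation spec)

parse_kv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) {
    stop("malformed line(s) in spec file (expected 'key = value'): ",
         paste(head(lines[eq < 0], 3L), collapse = " | "), call. = FALSE)
  }
  data.frame(
    key = trimws(substr(lines, 1L, eq - 1L)),
    value = trimws(substr(lines, eq + 1L, nchar(lines))),
    stringsAsFactors = FALSE
  )
}

kv_get <- function(kv, key, required = FALSE, default = NULL) {
  v <- kv$value[kv$key == key]
  if (!length(v)) {
    if (required) stop("spec file is missing key '", key, "'",
                       call. = FALSE)
    return(default)
  }
  v[[1L]]
}

split_fields <- function(value) trimws(strsplit(value, ";", fixed = TRUE)[[1L]])

#' Read or write a margin specification file
#'
#' Serializes a [margin_spec()] as a plain-text `key = value` file.
#' Scalar keys: `event_pt`, `n_total`, `n_event`, `filler_drug`,
#' `filler_pt`, and (optionally) the demographics keys `n_female`,
#' `n_male`, `n_unknown`, `age_mean`, `age_sd`, `year_start`,
#' `year_end`. Repeatable keys: `drug = <name>; <a>; <n_drug>` and
#' `country = <name>; <count>`.
#'
#' @param path file path.
#' @return `read_margin_spec()` returns a [margin_spec()];
#'   `write_margin_spec()` returns the path invisibly.
#' @export
read_margin_spec <- function(path) {
  kv <- parse_kv_file(path)
  drug_rows <- lapply(kv$value[kv$key == "drug"], split_fields)
  if (!length(drug_rows)) {
    stop("margin spec file lists no drugs", call. = FALSE)
  }
  if (any(lengths(drug_rows) != 3L)) {
    stop("each 'drug' line must have 3 fields: name; a; n_drug",
         call. = FALSE)
  }
  drugs <- data.frame(
    drug = vapply(drug_rows, `[`, "", 1L),
    a = as.integer(vapply(drug_rows, `[`, "", 2L)),
    n_drug = as.integer(vapply(drug_rows, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  demographics <- NULL
  if (!is.null(kv_get(kv, "n_female"))) {
    ctry_rows <- lapply(kv$value[kv$key == "country"], split_fields)
    countries <- if (length(ctry_rows)) {
      stats::setNames(as.integer(vapply(ctry_rows, `[`, "", 2L)),
                      vapply(ctry_rows, `[`, "", 1L))
    }
    num_or_null <- function(key) {
      v <- kv_get(kv, key)
      if (is.null(v)) NULL else as.double(v)
    }
    demographics <- list(
      n_female = as.integer(kv_get(kv, "n_female", required = TRUE)),
      n_male = as.integer(kv_get(kv, "n_male", required = TRUE)),
      n_unknown = as.integer(kv_get(kv, "n_unknown", required = TRUE)),
      age_mean = num_or_null("age_mean"),
      age_sd = num_or_null("age_sd"),
      countries = countries,
      year_start = num_or_null("year_start"),
      year_end = num_or_null("year_end")
    )
  }
  margin_spec(
    event_pt = kv_get(kv, "event_pt", required = TRUE),
    n_total = as.double(kv_get(kv, "n_total", required = TRUE)),
    n_event = as.double(kv_get(kv, "n_event", required = TRUE)),
    drugs = drugs,
    filler_drug = kv_get(kv, "filler_drug", default = "other suspect drug"),
    filler_pt = kv_get(kv, "filler_pt", default = "drug ineffective"),
    demographics = demographics
  )
}

#' @param spec a [margin_spec()].
#' @rdname read_margin_spec
#' @export
write_margin_spec <- function(spec, path) {
  stopifnot(inherits(spec, "margin_spec"))
  lines <- c(
    "# pvsignal margin specification",
    paste("event_pt =", spec$event_pt),
    paste("n_total =", format(spec$n_total, scientific = FALSE)),
    paste("n_event =", format(spec$n_event, scientific = FALSE)),
    paste("filler_drug =", spec$filler_drug),
    paste("filler_pt =", spec$filler_pt),
    sprintf("drug = %s; %d; %d", spec$drugs$drug, spec$drugs$a,
            spec$drugs$n_drug)
  )
  d <- spec$demographics
  if (!is.null(d)) {
    lines <- c(
      lines,
      sprintf("n_female = %d", d$n_female),
      sprintf("n_male = %d", d$n_male),
      sprintf("n_unknown = %d", d$n_unknown),
      if (!is.null(d$age_mean)) sprintf("age_mean = %g", d$age_mean),
      if (!is.null(d$age_sd)) sprintf("age_sd = %g", d$age_sd),
      if (!is.null(d$countries))
        sprintf("country = %s; %d", names(d$countries), d$countries),
      if (!is.null(d$year_start)) sprintf("year_start = %d",
                                          as.integer(d$year_start)),
      if (!is.null(d$year_end)) sprintf("year_end = %d",
                                        as.integer(d$year_end))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a simulation specification file
#'
#' Serializes a [simulation_spec()] as a plain-text `key = value` file.
#' Scalar keys: `n_reports`, `event_pt`, `background_prob`, `filler_pt`,
#' `age_mean`, `age_sd`, `year_start`, `year_end`, `seed`. Repeatable
#' keys: `drug = <name>; <prob>` (catalogue) and
#' `inject = <name>; <target_ror>`.
#'
#' @param path file path.
#' @return `read_simulation_spec()` returns a [simulation_spec()];
#'   `write_simulation_spec()` returns the path invisibly.
#' @export
read_simulation_spec <- function(path) {
  kv <- parse_kv_file(path)
  drug_rows <- lapply(kv$value[kv$key == "drug"], split_fields)
  drugs <- if (length(drug_rows)) {
    if (any(lengths(drug_rows) != 2L)) {
      stop("each 'drug' line must have 2 fields: name; prob",
           call. = FALSE)
    }
    data.frame(drug = vapply(drug_rows, `[`, "", 1L),
               prob = as.double(vapply(drug_rows, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  inj_rows <- lapply(kv$value[kv$key == "inject"], split_fields)
  injected <- if (length(inj_rows)) {
    data.frame(drug = vapply(inj_rows, `[`, "", 1L),
               target_ror = as.double(vapply(inj_rows, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  simulation_spec(
    n_reports = as.double(kv_get(kv, "n_reports", required = TRUE)),
    drugs = drugs,
    event_pt = kv_get(kv, "event_pt",
                      default = "carpal tunnel syndrome"),
    background_prob = as.double(kv_get(kv, "background_prob",
                                       default = "0.01")),
    injected = injected,
    filler_pt = kv_get(kv, "filler_pt", default = "drug ineffective"),
    age_mean = as.double(kv_get(kv, "age_mean", default = "57")),
    age_sd = as.double(kv_get(kv, "age_sd", default = "15")),
    year_range = c(as.integer(kv_get(kv, "year_start", default = "2004")),
                   as.integer(kv_get(kv, "year_end", default = "2024"))),
    seed = as.integer(kv_get(kv, "seed", default = "1"))
  )
}

#' @param spec a [simulation_spec()].
#' @rdname read_simulation_spec
#' @export
write_simulation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  lines <- c(
    "# pvsignal simulation specification",
    sprintf("n_reports = %d", as.integer(spec$n_reports)),
    paste("event_pt =", spec$event_pt),
    sprintf("background_prob = %g", spec$background_prob),
    paste("filler_pt =", spec$filler_pt),
    sprintf("age_mean = %g", spec$age_mean),
    sprintf("age_sd = %g", spec$age_sd),
    sprintf("year_start = %d", spec$year_range[1L]),
    sprintf("year_end = %d", spec$year_range[2L]),
    sprintf("seed = %d", spec$seed),
    sprintf("drug = %s; %g", spec$drugs$drug, spec$drugs$prob),
    if (!is.null(spec$injected))
      sprintf("inject = %s; %g", spec$injected$drug,
              spec$injected$target_ror)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Bundled margin specification: carpal tunnel syndrome in FAERS
#'
#' Loads the packaged margin specification describing the carpal tunnel
#' syndrome (CTS) disproportionality screen of FAERS reports from
#' October 2003 to September 2024: 12,929,504 reports of which 6,837
#' name CTS, the ten drugs most strongly associated with CTS with their
#' primary-suspect report counts, and the CTS reports' demographics
#' (4,753 female / 1,717 male / 367 unknown; age 57.0 +/- 14.9 years;
#' 4,699 from the United States). Reconstructing this spec and screening
#' it reproduces the published RORs and signal set.
#'
#' @return A [margin_spec()].
#' @examples
#' spec <- cts_margin_spec()
#' detect_signals_from_margins(spec$drugs, spec$n_event, spec$n_total,
#'                             event_pt = spec$event_pt)
#' @export
cts_margin_spec <- function() {
  read_margin_spec(system.file("extdata", "cts-faers-margins.txt",
                               package = "pvsignal", mustWork = TRUE))
}
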