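## In-memory model of a spontaneous-report database (FAERS-style) and
## readers/writers for its delimited three-table layout (DEMO, DRUG, REAC)
## plus a single flat-table dialect used in tests.

ROLE_CODES <- c(
  PS = "primary_suspect", SS = "secondary_suspect",
  C  = "concomitant",     I  = "interacting"
)
SEX_CODES <- c(F = "female", M = "male", UNK = "unknown")

#' Construct a report set
#'
#' A `report_set` is the package's in-memory model of a spontaneous-report
#' database: one demographics row per report, one or more drug rows per
#' report (each with a role code), and one or more reaction rows per
#' report (MedDRA preferred terms). Drug names and preferred terms are
#' normalized on construction (see [normalize_term()]).
#'
#' @param demo data.frame with columns `report_id` (unique strings),
#'   `sex` (`"female"`, `"male"` or `"unknown"`), `age_years` (numeric,
#'   `NA` allowed, otherwise in \[0, 130\]), `country` (string or `NA`),
#'   `year` (integer calendar year or `NA`).
#' @param drugs data.frame with columns `report_id`, `drug_seq` (integer
#'   order within the report), `drug_name`, and `role` (one of
#'   `"primary_suspect"`, `"secondary_suspect"`, `"concomitant"`,
#'   `"interacting"`).
#' @param reactions data.frame with columns `report_id` and `pt`
#'   (preferred term).
#' @param provenance free-text label describing where the reports came
#'   from.
#' @return An object of class `report_set`.
#' @details Every report must carry at least one drug and one reaction;
#'   drug and reaction rows must reference a `report_id` present in
#'   `demo`. Use [read_reports()] to build a report set from files.
#' @seealso [read_reports()], [write_reports()], [count_event_pairs()]
#' @examples
#' rs <- report_set(
#'   demo = data.frame(report_id = "r1", sex = "female", age_years = 60,
#'                     country = "us", year = 2020),
#'   drugs = data.frame(report_id = "r1", drug_seq = 1L,
#'                      drug_name = "anastrozole", role = "primary_suspect"),
#'   reactions = data.frame(report_id = "r1", pt = "carpal tunnel syndrome")
#' )
#' n_reports(rs)
#' @export
report_set <- function(demo, drugs, reactions, provenance = "in-memory") {
  demo <- as.data.table(demo)
  drugs <- as.data.table(drugs)
  reactions <- as.data.table(reactions)

  need <- function(dt, cols, table) {
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop("missing mandatory column(s) in ", table, " table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(demo, c("report_id", "sex", "age_years", "country", "year"), "demo")
  need(drugs, c("report_id", "drug_seq", "drug_name", "role"), "drug")
  need(reactions, c("report_id", "pt"), "reaction")

  demo[, report_id := as.character(report_id)]
  drugs[, report_id := as.character(report_id)]
  reactions[, report_id := as.character(report_id)]

  if (anyDuplicated(demo$report_id)) {
    stop("duplicate report_id in demographics: ",
         paste(unique(demo$report_id[duplicated(demo$report_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(demo$sex %in% SEX_CODES)) {
    stop("sex must be one of: ", paste(SEX_CODES, collapse = ", "),
         call. = FALSE)
  }
  demo[, age_years := as.double(age_years)]
  bad_age <- !is.na(demo$age_years) &
    (demo$age_years < 0 | demo$age_years > 130)
  if (any(bad_age)) {
    stop("age_years outside [0, 130] for report(s): ",
         paste(head(demo$report_id[bad_age], 5L), collapse = ", "),
         call. = FALSE)
  }
  demo[, year := as.integer(year)]

  if (!all(drugs$role %in% ROLE_CODES)) {
    stop("drug role must be one of: ", paste(ROLE_CODES, collapse = ", "),
         call. = FALSE)
  }
  drugs[, `:=`(drug_seq = as.integer(drug_seq),
               drug_name = normalize_term_fast(drug_name))]
  reactions[, pt := normalize_term_fast(pt)]
  if (any(!nzchar(drugs$drug_name))) {
    stop("empty drug_name after normalization", call. = FALSE)
  }
  if (any(!nzchar(reactions$pt))) {
    stop("empty preferred term after normalization", call. = FALSE)
  }

  ids <- demo$report_id
  no_drug <- setdiff(ids, drugs$report_id)
  no_reac <- setdiff(ids, reactions$report_id)
  if (length(no_drug)) {
    stop("report(s) without any drug row: ",
         paste(head(no_drug, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(no_reac)) {
    stop("report(s) without any reaction row: ",
         paste(head(no_reac, 5L), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(c(drugs$report_id, reactions$report_id), ids)
  if (length(orphan)) {
    stop("drug/reaction row(s) referencing unknown report_id: ",
         paste(head(orphan, 5L), collapse = ", "), call. = FALSE)
  }

  setkey(demo, report_id)
  setkey(drugs, report_id, drug_seq)
  setkey(reactions, report_id, pt)
  structure(
    list(demo = demo[], drugs = drugs[], reactions = reactions[],
         provenance = as.character(provenance)[1L]),
    class = "report_set"
  )
}

#' Number of reports in a report set
#'
#' @param rs a [report_set()].
#' @return Integer count of distinct reports.
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$demo)
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", format(nrow(x$demo), big.mark = ","), " reports (",
      x$provenance, ")\n", sep = "")
  cat("  drug rows:     ", format(nrow(x$drugs), big.mark = ","), "\n",
      sep = "")
  cat("  reaction rows: ", format(nrow(x$reactions), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

dialect_sep <- function(dialect = c("tsv", "dollar")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") "\t" else "$"
}

age_to_years <- function(age, unit) {
  age <- suppressWarnings(as.double(age))
  unit <- toupper(trimws(as.character(unit)))
  out <- rep(NA_real_, length(age))
  for (u in list(c("YR", 1), c("MON", 12), c("DY", 365.25))) {
    i <- which(unit == u[1])
    out[i] <- age[i] / as.double(u[2])
  }
  out
}

#' Read spontaneous reports from FAERS-style delimited tables
#'
#' Reads the three-table layout (demographics, drugs, reactions) joined on
#' `report_id`. The expected columns are: DEMO `report_id, sex, age,
#' age_unit, country, event_year` with `sex` in `F/M/UNK` and `age_unit`
#' in `YR/MON/DY`; DRUG `report_id, drug_seq, drug_name, role_cod` with
#' `role_cod` in `PS/SS/C/I`; REAC `report_id, pt`.
#'
#' Rows with an empty or missing `report_id` are dropped (a message
#' reports how many). Drug or reaction rows referencing a `report_id`
#' absent from the demographics table are dropped with a warning. Ages
#' reported in months or days are converted to years. Duplicate
#' demographics rows are collapsed when identical and rejected when they
#' conflict.
#'
#' @param demo_path,drug_path,reac_path paths to the three tables.
#' @param dialect field separator dialect: `"tsv"` (tab) or `"dollar"`
#'   (`$`, as in FAERS quarterly ASCII extracts).
#' @param provenance label stored on the resulting set.
#' @return A [report_set()].
#' @seealso [write_reports()], [read_reports_flat()]
#' @export
read_reports <- function(demo_path, drug_path, reac_path,
                         dialect = c("tsv", "dollar"),
                         provenance = demo_path) {
  sep <- dialect_sep(dialect)
  for (p in c(demo_path, drug_path, reac_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  demo <- fread(demo_path, sep = sep, colClasses = list(character = "report_id"),
                na.strings = c("", "NA"), showProgress = FALSE)
  drug <- fread(drug_path, sep = sep, colClasses = list(character = "report_id"),
                na.strings = c("", "NA"), showProgress = FALSE)
  reac <- fread(reac_path, sep = sep, colClasses = list(character = "report_id"),
                na.strings = c("", "NA"), showProgress = FALSE)

  need <- function(dt, cols, table) {
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop("missing mandatory column(s) in ", table, " table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(demo, c("report_id", "sex", "age", "age_unit", "country",
               "event_year"), "DEMO")
  need(drug, c("report_id", "drug_seq", "drug_name", "role_cod"), "DRUG")
  need(reac, c("report_id", "pt"), "REAC")

  drop_bad_ids <- function(dt, table) {
    bad <- is.na(dt$report_id) | !nzchar(trimws(dt$report_id))
    if (any(bad)) {
      message("dropped ", sum(bad), " ", table,
              " row(s) with unparseable report_id")
    }
    dt[!bad]
  }
  demo <- drop_bad_ids(demo, "DEMO")
  drug <- drop_bad_ids(drug, "DRUG")
  reac <- drop_bad_ids(reac, "REAC")

  sex <- unname(SEX_CODES[toupper(trimws(as.character(demo$sex)))])
  sex[is.na(sex)] <- "unknown"
  demo_p <- data.table(
    report_id = trimws(demo$report_id),
    sex = sex,
    age_years = age_to_years(demo$age, demo$age_unit),
    country = ifelse(is.na(demo$country), NA_character_,
                     normalize_term(demo$country)),
    year = suppressWarnings(as.integer(demo$event_year))
  )
  if (anyDuplicated(demo_p$report_id)) {
    demo_p <- unique(demo_p)
    dup <- unique(demo_p$report_id[duplicated(demo_p$report_id)])
    if (length(dup)) {
      stop("conflicting demographics for duplicated report_id(s): ",
           paste(head(dup, 10L), collapse = ", "), call. = FALSE)
    }
  }

  known <- demo_p$report_id
  drug[, report_id := trimws(report_id)]
  reac[, report_id := trimws(report_id)]
  orphan_drug <- !(drug$report_id %chin% known)
  orphan_reac <- !(reac$report_id %chin% known)
  if (any(orphan_drug)) {
    warning("dropped ", sum(orphan_drug),
            " DRUG row(s) referencing report_id absent from DEMO",
            call. = FALSE)
    drug <- drug[!orphan_drug]
  }
  if (any(orphan_reac)) {
    warning("dropped ", sum(orphan_reac),
            " REAC row(s) referencing report_id absent from DEMO",
            call. = FALSE)
    reac <- reac[!orphan_reac]
  }

  role <- unname(ROLE_CODES[toupper(trimws(as.character(drug$role_cod)))])
  if (anyNA(role)) {
    warning("dropped ", sum(is.na(role)), " DRUG row(s) with invalid role_cod",
            call. = FALSE)
    drug <- drug[!is.na(role)]
    role <- role[!is.na(role)]
  }
  drugs_p <- data.table(
    report_id = drug$report_id,
    drug_seq = suppressWarnings(as.integer(drug$drug_seq)),
    drug_name = drug$drug_name,
    role = role
  )
  reac_p <- data.table(report_id = reac$report_id, pt = reac$pt)

  # reports left without a drug or reaction after orphan filtering cannot
  # enter contingency counting; drop them with a warning
  ok <- demo_p$report_id %chin% drugs_p$report_id &
    demo_p$report_id %chin% reac_p$report_id
  if (any(!ok)) {
    warning("dropped ", sum(!ok),
            " report(s) lacking drug or reaction rows", call. = FALSE)
    demo_p <- demo_p[ok]
    drugs_p <- drugs_p[report_id %chin% demo_p$report_id]
    reac_p <- reac_p[report_id %chin% demo_p$report_id]
  }
  report_set(demo_p, drugs_p, reac_p, provenance = provenance)
}

#' Write a report set to FAERS-style delimited tables
#'
#' Inverse of [read_reports()]: `read_reports()` applied to the written
#' files reproduces the report set field-for-field. Output row order is
#' fixed (sorted by `report_id`, then `drug_seq`/`pt`), so writing the
#' same set twice produces byte-identical files.
#'
#' @param rs a [report_set()].
#' @param demo_path,drug_path,reac_path output paths.
#' @param dialect field separator dialect, as in [read_reports()].
#' @return Invisibly, the three paths.
#' @export
write_reports <- function(rs, demo_path, drug_path, reac_path,
                          dialect = c("tsv", "dollar")) {
  stopifnot(inherits(rs, "report_set"))
  sep <- dialect_sep(dialect)
  demo <- rs$demo[order(report_id)]
  out_demo <- data.table(
    report_id = demo$report_id,
    sex = names(SEX_CODES)[match(demo$sex, SEX_CODES)],
    age = demo$age_years,
    age_unit = ifelse(is.na(demo$age_years), NA_character_, "YR"),
    country = demo$country,
    event_year = demo$year
  )
  drugs <- rs$drugs[order(report_id, drug_seq, drug_name)]
  out_drug <- data.table(
    report_id = drugs$report_id,
    drug_seq = drugs$drug_seq,
    drug_name = drugs$drug_name,
    role_cod = names(ROLE_CODES)[match(drugs$role, ROLE_CODES)]
  )
  reac <- rs$reactions[order(report_id, pt)]
  out_reac <- data.table(report_id = reac$report_id, pt = reac$pt)

  fwrite(out_demo, demo_path, sep = sep, na = "", quote = FALSE)
  fwrite(out_drug, drug_path, sep = sep, na = "", quote = FALSE)
  fwrite(out_reac, reac_path, sep = sep, na = "", quote = FALSE)
  invisible(c(demo_path, drug_path, reac_path))
}

#' Read or write the single flat-table dialect
#'
#' The flat dialect stores one row per (report, drug, reaction) triple
#' with columns `report_id, sex, age, country, year, drug_name, role_cod,
#' pt` (age always in years). It is convenient for small hand-written
#' fixtures; the three-table layout of [read_reports()] is the primary
#' format.
#'
#' @param path file path.
#' @param provenance label stored on the resulting set.
#' @return `read_reports_flat()` returns a [report_set()];
#'   `write_reports_flat()` returns the path invisibly.
#' @export
read_reports_flat <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  flat <- fread(path, sep = "\t", colClasses = list(character = "report_id"),
                na.strings = c("", "NA"), showProgress = FALSE)
  need <- setdiff(c("report_id", "sex", "age", "country", "year",
                    "drug_name", "role_cod", "pt"), names(flat))
  if (length(need)) {
    stop("missing mandatory column(s) in flat table: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- is.na(flat$report_id) | !nzchar(trimws(flat$report_id))
  if (any(bad)) {
    message("dropped ", sum(bad), " flat row(s) with unparseable report_id")
    flat <- flat[!bad]
  }
  flat[, report_id := trimws(report_id)]
  sex <- unname(SEX_CODES[toupper(trimws(as.character(flat$sex)))])
  sex[is.na(sex)] <- "unknown"
  demo <- unique(data.table(
    report_id = flat$report_id, sex = sex,
    age_years = suppressWarnings(as.double(flat$age)),
    country = ifelse(is.na(flat$country), NA_character_,
                     normalize_term(flat$country)),
    year = suppressWarnings(as.integer(flat$year))
  ))
  if (anyDuplicated(demo$report_id)) {
    dup <- unique(demo$report_id[duplicated(demo$report_id)])
    stop("conflicting demographics for duplicated report_id(s): ",
         paste(head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  role <- unname(ROLE_CODES[toupper(trimws(as.character(flat$role_cod)))])
  drugs <- unique(data.table(report_id = flat$report_id,
                             drug_name = flat$drug_name, role = role))
  drugs <- drugs[!is.na(role)]
  drugs[, drug_seq := seq_len(.N), by = report_id]
  reacs <- unique(data.table(report_id = flat$report_id, pt = flat$pt))
  report_set(demo, drugs, reacs, provenance = provenance)
}

#' @param rs a [report_set()].
#' @rdname read_reports_flat
#' @export
write_reports_flat <- function(rs, path) {
  stopifnot(inherits(rs, "report_set"))
  flat <- rs$drugs[rs$reactions, on = "report_id",
                   allow.cartesian = TRUE][rs$demo, on = "report_id"]
  out <- data.table(
    report_id = flat$report_id,
    sex = names(SEX_CODES)[match(flat$sex, SEX_CODES)],
    age = flat$age_years,
    country = flat$country,
    year = flat$year,
    drug_name = flat$drug_name,
    role_cod = names(ROLE_CODES)[match(flat$role, ROLE_CODES)],
    pt = flat$pt
  )
  setorder(out, report_id, drug_name, pt)
  fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
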