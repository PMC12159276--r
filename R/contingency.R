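## 2x2 contingency tables for drug-event pairs, counting reports (not drug
## mentions) and restricting the exposure to drugs in the primary-suspect
## role, so the four cells of every table sum to the report total.

#' Count drug-event margins for one adverse event
#'
#' For a target preferred term, computes for every drug the pair
#' `(a, n_drug)` where `a` is the number of reports in which the drug
#' appears as primary suspect *and* the report lists the event, and
#' `n_drug` is the number of reports in which the drug appears as primary
#' suspect at all. Also returns the event margin `n_event` (reports
#' listing the event under any drug/role) and the database size
#' `n_total`. A drug-event pair is counted at most once per report even
#' if the report lists the drug or the term repeatedly; a report with
#' several distinct primary-suspect drugs contributes to each of them.
#'
#' @param rs a [report_set()].
#' @param event_pt the target preferred term (normalized internally).
#' @return A list with elements `margins` (data.frame of `drug`, `a`,
#'   `n_drug`, one row per drug ever seen as primary suspect), `n_event`,
#'   `n_total`, and `event_pt`.
#' @seealso [build_table()], [detect_signals()]
#' @export
count_event_pairs <- function(rs, event_pt) {
  stopifnot(inherits(rs, "report_set"))
  stopifnot_scalar_string(event_pt, "event_pt")
  if (nrow(rs$demo) == 0L) stop("report set is empty", call. = FALSE)
  event_pt <- normalize_term(event_pt)

  ev_ids <- unique(rs$reactions[pt == event_pt, report_id])
  ps <- unique(rs$drugs[role == "primary_suspect",
                        list(report_id, drug_name)])
  m <- ps[, list(n_drug = .N), by = drug_name]
  a <- ps[report_id %chin% ev_ids, list(a = .N), by = drug_name]
  m <- a[m, on = "drug_name"]
  m[is.na(a), a := 0L]
  setorder(m, drug_name)
  list(
    margins = data.frame(drug = m$drug_name, a = as.integer(m$a),
                         n_drug = as.integer(m$n_drug),
                         stringsAsFactors = FALSE),
    n_event = length(ev_ids),
    n_total = nrow(rs$demo),
    event_pt = event_pt
  )
}

#' Build a 2x2 contingency table from its margins
#'
#' Given the joint count `a` and the three margins, derives the remaining
#' cells of the drug-by-event report table: `b = n_drug - a` (drug,
#' other events), `c = n_event - a` (other drugs, event), and
#' `d = n_total - n_drug - n_event + a` (neither).
#'
#' @param a reports with both the drug (primary suspect) and the event.
#' @param n_drug reports with the drug as primary suspect.
#' @param n_event reports with the event.
#' @param n_total all reports in the database.
#' @param drug,event_pt optional labels carried on the table.
#' @return An object of class `contingency_table` with fields `a`, `b`,
#'   `c`, `d`, the margins, and the labels.
#' @examples
#' build_table(54, 2064, 6837, 12929504, drug = "idursulfase",
#'             event_pt = "carpal tunnel syndrome")
#' @export
build_table <- function(a, n_drug, n_event, n_total,
                        drug = "", event_pt = "") {
  a <- stopifnot_count(a, "a")
  n_drug <- stopifnot_count(n_drug, "n_drug")
  n_event <- stopifnot_count(n_event, "n_event")
  n_total <- stopifnot_count(n_total, "n_total")
  if (a > n_drug) {
    stop("infeasible margins: a > n_drug (", a, " > ", n_drug, ")",
         call. = FALSE)
  }
  if (a > n_event) {
    stop("infeasible margins: a > n_event (", a, " > ", n_event, ")",
         call. = FALSE)
  }
  if (n_drug + n_event - a > n_total) {
    stop("infeasible margins: n_drug + n_event - a > n_total (",
         n_drug + n_event - a, " > ", n_total, ")", call. = FALSE)
  }
  structure(
    list(drug = as.character(drug), event_pt = as.character(event_pt),
         a = a, b = n_drug - a, c = n_event - a,
         d = n_total - n_drug - n_event + a,
         n_drug = n_drug, n_event = n_event, n_total = n_total),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  lab <- if (nzchar(x$drug) || nzchar(x$event_pt)) {
    paste0(" ", x$drug, " x ", x$event_pt)
  } else ""
  cat("<contingency_table>", lab, "\n", sep = "")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
}

#' Export per-drug margins to TSV
#'
#' Writes the `margins` component of [count_event_pairs()] output as a
#' three-column TSV (`drug`, `a`, `n_drug`) — the interchange format
#' consumed by [margin_spec()] reconstruction.
#'
#' @param pairs the list returned by [count_event_pairs()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_margins <- function(pairs, path) {
  stopifnot(is.list(pairs), !is.null(pairs$margins))
  fwrite(as.data.table(pairs$margins), path, sep = "\t", quote = FALSE)
  invisible(path)
}
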