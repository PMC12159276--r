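#' Normalize a drug name or preferred-term string
#'
#' Trims leading/trailing whitespace, case-folds to lower case, and
#' collapses internal runs of whitespace to a single space. No synonym
#' mapping is applied: distinct trade/generic spellings (e.g.
#' "alendronate" vs "alendronic acid") remain distinct terms, as they do
#' in FAERS itself. Normalization is idempotent.
#'
#' @param x character vector of drug names or MedDRA preferred terms.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_term(c("  Carpal  Tunnel SYNDROME ", "Idursulfase"))
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# normalize_term through the unique values only; O(levels) regex work
# instead of O(rows), which matters on multi-million-row report sets
normalize_term_fast <- function(x) {
  f <- factor(x)
  levels(f) <- normalize_term(levels(f))
  as.character(f)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# shared validators
stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    stop("`", what, "` must be a non-empty string", call. = FALSE)
  }
  invisible(x)
}

stopifnot_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != trunc(x)) {
    stop("`", what, "` must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.double(x))
}
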