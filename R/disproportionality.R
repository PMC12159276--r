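## Disproportionality statistics on a 2x2 report table: reporting odds
## ratio with Woolf confidence interval, proportional reporting ratio,
## Pearson chi-squared, and the BCPNN information component with its
## closed-form posterior-moment approximation.

#' Reporting odds ratio with Woolf confidence interval
#'
#' The ROR is `(a/c)/(b/d)`: the odds of the event among a drug's reports
#' relative to the odds among all other drugs' reports. The confidence
#' interval uses the Woolf (log-normal) method,
#' `exp(ln ROR -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t a [build_table()] contingency table.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @param correction apply the Haldane-Anscombe continuity correction
#'   (add 0.5 to every cell) before estimation. Off by default; without
#'   it a zero cell is an error, since the estimate is undefined.
#' @return A list with `ror`, `ci_low`, `ci_high`.
#' @references Rothman KJ, Greenland S, Lash TL. Modern Epidemiology
#'   (Woolf interval for the odds ratio).
#' @examples
#' t <- build_table(54, 2064, 6837, 12929504)
#' ror(t)
#' @export
ror <- function(t, z = 1.96, correction = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction) cells <- cells + 0.5
  if (any(cells == 0)) {
    stop("undefined ROR: zero cell(s) in the 2x2 table ",
         "(enable `correction` for the Haldane-Anscombe estimate)",
         call. = FALSE)
  }
  est <- (cells[1] / cells[3]) / (cells[2] / cells[4])
  se <- sqrt(sum(1 / cells))
  list(ror = est,
       ci_low = exp(log(est) - z * se),
       ci_high = exp(log(est) + z * se))
}

#' Proportional reporting ratio
#'
#' The PRR is `(a/(a+b)) / (c/(c+d))`: the event's share among the drug's
#' reports relative to its share among all other reports. A zero joint
#' or comparator count leaves the estimate undefined on the ratio scale
#' and raises an error unless the continuity correction is enabled.
#'
#' @inheritParams ror
#' @return The PRR as a single number.
#' @export
prr <- function(t, correction = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction) cells <- cells + 0.5
  if (cells[1] == 0 || cells[3] == 0 || cells[1] + cells[2] == 0 ||
      cells[3] + cells[4] == 0) {
    stop("undefined PRR: zero cell or denominator in the 2x2 table ",
         "(enable `correction` for the continuity-corrected estimate)",
         call. = FALSE)
  }
  (cells[1] / (cells[1] + cells[2])) / (cells[3] / (cells[3] + cells[4]))
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-squared, by default with the Yates
#' continuity correction (the form used in the Evans signal criteria).
#' Degenerate tables (a zero row or column margin) return 0 with a
#' warning rather than an error, so that screening loops keep running.
#'
#' @inheritParams ror
#' @param yates apply the Yates continuity correction (default on).
#' @return The chi-squared statistic (non-negative scalar).
#' @export
chi_squared <- function(t, yates = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  m <- as_matrix_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); chi-squared set to 0",
            call. = FALSE)
    return(0)
  }
  unname(suppressWarnings(stats::chisq.test(m, correct = yates)$statistic))
}

#' BCPNN prior pseudo-counts
#'
#' Priors for the information-component posterior used by [bcpnn_ic()]:
#' `alpha1`/`beta1` for the drug and event margins, `alpha`/`beta` for
#' the totals, `gamma11` for the joint cell, and `z` for the interval
#' multiplier. The defaults (1, 1, 2, 2, 1, 1.96) are the standard
#' uninformative choice under which the IC shrinks toward 0 for sparse
#' cells.
#'
#' @param alpha1,beta1 margin pseudo-counts (default 1).
#' @param alpha,beta total pseudo-counts (default 2).
#' @param gamma11 joint-cell pseudo-count (default 1).
#' @param z interval multiplier (default 1.96 for a 95% interval).
#' @return An object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1, z = 1.96) {
  p <- list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11, z = z)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   is.na(v) || v <= 0, logical(1L)))) {
    stop("all BCPNN priors must be strictly positive scalars",
         call. = FALSE)
  }
  structure(p, class = "bcpnn_priors")
}

#' BCPNN information component
#'
#' Computes the posterior expectation and variance of the information
#' component `IC = log2( P(drug, event) / (P(drug) P(event)) )` under the
#' Bayesian confidence propagation neural network model, using the
#' closed-form moment approximation of Bate et al. (1998), and the lower
#' interval bound `IC025 = E(IC) - z * sqrt(V(IC))`. With `N = n_total`,
#' `n1 = a + b` (drug margin) and `n2 = a + c` (event margin):
#'
#' \deqn{\gamma = \gamma_{11} (N+\alpha)(N+\beta) /
#'   ((n_1+\alpha_1)(n_2+\beta_1))}
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(n_1+\alpha_1)(n_2+\beta_1)}}
#'
#' and `V(IC)` is the corresponding sum of three shrunken-proportion
#' variance terms divided by `ln(2)^2`. `IC025 > 0` is the conventional
#' validation rule for a disproportionality signal.
#'
#' @inheritParams ror
#' @param priors a [bcpnn_priors()] object.
#' @return A list with `ic_expected` (bits), `ic_variance` (bits^2),
#'   and `ic025` (bits).
#' @references Bate A, Lindquist M, Edwards IR, et al. A Bayesian neural
#'   network method for adverse drug reaction signal generation.
#'   Eur J Clin Pharmacol. 1998;54(4):315-321.
#' @examples
#' bcpnn_ic(build_table(54, 2064, 6837, 12929504))
#' @export
bcpnn_ic <- function(t, priors = bcpnn_priors()) {
  stopifnot(inherits(t, "contingency_table"), inherits(priors, "bcpnn_priors"))
  if (t$n_total <= 0) stop("n_total must be positive", call. = FALSE)
  a <- t$a
  N <- t$n_total
  n1 <- t$a + t$b
  n2 <- t$a + t$c
  a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha;  be <- priors$beta
  g11 <- priors$gamma11
  g <- g11 * (N + al) * (N + be) / ((n1 + a1) * (n2 + b1))
  ic_expected <- log2((a + g11) * (N + al) * (N + be) /
                        ((N + g) * (n1 + a1) * (n2 + b1)))
  ic_variance <- (1 / log(2))^2 * (
    (N - a + g - g11) / ((a + g11) * (1 + N + g)) +
    (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
    (N - n2 + be - b1) / ((n2 + b1) * (1 + N + be))
  )
  list(ic_expected = ic_expected,
       ic_variance = ic_variance,
       ic025 = ic_expected - priors$z * sqrt(ic_variance))
}

#' All disproportionality statistics for one drug-event table
#'
#' Convenience wrapper computing [ror()], [prr()], [chi_squared()] and
#' [bcpnn_ic()] for one table. When the table has a zero cell and
#' `correction` is off, the ROR and PRR are returned as `NA` (with the
#' BCPNN and chi-squared statistics still computed) rather than erroring,
#' so database-wide screens keep running; call [ror()] directly for the
#' strict behaviour.
#'
#' @inheritParams ror
#' @inheritParams chi_squared
#' @param priors a [bcpnn_priors()] object.
#' @return An object of class `disprop_result`: a list with the table and
#'   fields `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `chi2`,
#'   `ic_expected`, `ic_variance`, `ic025`, `corrections` (character
#'   vector naming any corrections applied).
#' @export
disproportionality <- function(t, z = 1.96, correction = FALSE,
                               yates = TRUE, priors = bcpnn_priors()) {
  stopifnot(inherits(t, "contingency_table"))
  est <- tryCatch(ror(t, z = z, correction = correction),
                  error = function(e) list(ror = NA_real_,
                                           ci_low = NA_real_,
                                           ci_high = NA_real_))
  p <- tryCatch(prr(t, correction = correction),
                error = function(e) NA_real_)
  chi <- suppressWarnings(chi_squared(t, yates = yates))
  ic <- bcpnn_ic(t, priors = priors)
  corrections <- c(if (correction) "haldane-anscombe",
                   if (yates) "yates")
  structure(
    list(table = t, ror = est$ror, ror_ci_low = est$ci_low,
         ror_ci_high = est$ci_high, prr = p, chi2 = chi,
         ic_expected = ic$ic_expected, ic_variance = ic$ic_variance,
         ic025 = ic$ic025, corrections = corrections %||% character()),
    class = "disprop_result"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.disprop_result <- function(x, ...) {
  t <- x$table
  cat("<disprop_result> ", t$drug, " x ", t$event_pt, "\n", sep = "")
  cat(sprintf("  a=%d of n_drug=%d (n_event=%d, N=%d)\n",
              t$a, t$a + t$b, t$a + t$c, t$n_total))
  cat(sprintf("  ROR %.1f (95%% CI %.1f-%.1f)  PRR %.1f  chi2 %.1f\n",
              x$ror, x$ror_ci_low, x$ror_ci_high, x$prr, x$chi2))
  cat(sprintf("  IC %.2f (IC025 %.2f)\n", x$ic_expected, x$ic025))
  invisible(x)
}
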