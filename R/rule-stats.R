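#' Contingency table for an association rule
#'
#' Builds the 2x2 presence/absence table underlying every rule statistic.
#' For a rule X -> Y over a set of t case-level transactions, `a` counts
#' cases reporting all of X and all of Y, `b` cases with X but not Y,
#' `c` cases with Y but not X, and `d` cases with neither.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table`: a list with elements
#'   `a`, `b`, `c`, `d` and the total `t = a + b + c + d`.
#' @seealso [contingency()] to tally the table from a transaction set,
#'   [rule_stats()] to turn it into association indicators.
#' @examples
#' ct <- contingency_table(26, 2, 4, 4345)
#' rule_stats(ct)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), t = as.integer(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("X", "not X"), c("Y", "not Y")))
  cat("Rule contingency table (t =", x$t, ")\n")
  print(m)
  invisible(x)
}

#' Tally the contingency table of a rule over a transaction set
#'
#' @param ts A [transaction_set()].
#' @param x,y Character vectors of item keys (see [item_key()]); the
#'   antecedent and consequent. Must be non-empty and disjoint.
#' @return A [contingency_table()].
#' @export
contingency <- function(ts, x, y) {
  stopifnot(inherits(ts, "transaction_set"))
  if (length(x) == 0L || length(y) == 0L)
    stop("antecedent and consequent must be non-empty")
  if (length(intersect(x, y)) > 0L)
    stop("antecedent and consequent overlap: ",
         paste(intersect(x, y), collapse = ", "))
  has_x <- vapply(ts$transactions, function(tr) all(x %in% tr), logical(1))
  has_y <- vapply(ts$transactions, function(tr) all(y %in% tr), logical(1))
  contingency_table(sum(has_x & has_y), sum(has_x & !has_y),
                    sum(!has_x & has_y), sum(!has_x & !has_y))
}

#' Association indicators from a contingency table
#'
#' Computes the four classical rule indicators:
#' support = a/t, confidence = a/(a+b),
#' lift = confidence / ((a+c)/t), and conviction. Conviction is undefined
#' (returned as `NA`) when the rule is exceptionless (b = 0, confidence 1):
#' its denominator is zero.
#'
#' Two conviction variants are available. The `"standard"` form is
#' ((b+d)/t) / (b/(a+b)), algebraically (1 - supp(Y)) / (1 - confidence).
#' The `"as_printed"` form replaces the numerator with (c+d)/t, a variant
#' that circulates in some published method descriptions; it is provided so
#' the two can be compared, but the standard form is the default and is the
#' one consistent with the conviction values of published JADER rule tables.
#'
#' @param ct A [contingency_table()].
#' @param conviction_formula `"standard"` (default) or `"as_printed"`.
#' @return An object of class `rule_stats`: a list with numeric elements
#'   `support`, `confidence`, `lift`, `conviction` (the last `NA_real_`
#'   when undefined), kept at full precision; round only at report time.
#' @examples
#' rule_stats(contingency_table(4, 1, 7, 674))
#' @export
rule_stats <- function(ct, conviction_formula = c("standard", "as_printed")) {
  stopifnot(inherits(ct, "contingency_table"))
  conviction_formula <- match.arg(conviction_formula)
  a <- ct$a; b <- ct$b; cc <- ct$c; d <- ct$d; t <- ct$t
  if (t < 1L) stop("empty transaction set: t must be >= 1")
  if (a + b == 0L) stop("confidence undefined: antecedent never observed (a + b = 0)")
  if (a + cc == 0L) stop("lift undefined: consequent never observed (a + c = 0)")
  support <- a / t
  confidence <- a / (a + b)
  lift <- confidence / ((a + cc) / t)
  conviction <- if (b == 0L) NA_real_ else {
    num <- if (conviction_formula == "standard") (b + d) / t else (cc + d) / t
    num / (b / (a + b))
  }
  structure(list(support = support, confidence = confidence,
                 lift = lift, conviction = conviction,
                 conviction_formula = conviction_formula),
            class = "rule_stats")
}

#' @export
print.rule_stats <- function(x, digits = 4, ...) {
  cat(sprintf("support %.*f, confidence %.*f, lift %.*f, conviction %s\n",
              digits, x$support, digits, x$confidence, digits, x$lift,
              if (is.na(x$conviction)) "NA" else
                formatC(x$conviction, digits = digits, format = "f")))
  invisible(x)
}

#' Reconstruct integer contingency tables from rounded rule statistics
#'
#' Published rule tables print support, confidence, lift and conviction
#' rounded to a few decimals at a stated cohort size t. Because all four
#' are ratios of the integer cells, an exhaustive search over (a, b, c)
#' recovers the tables consistent with every printed value simultaneously
#' — usually a unique one. For gender-consequent rules the four rounded
#' statistics may leave a few candidate `c` values; supplying the known
#' consequent marginal (`y_total` = a + c, e.g. the cohort's female case
#' count) restores uniqueness.
#'
#' @param t Integer cohort size.
#' @param stats Named numeric vector with elements `support`, `confidence`,
#'   `lift` and optionally `conviction` (omit or set `NA` for rules printed
#'   with conviction NA, which forces b = 0).
#' @param digits Named integer vector: decimals each printed statistic was
#'   rounded to, e.g. `c(support = 4, confidence = 2, lift = 1, conviction = 1)`.
#' @param y_total Optional known value of a + c.
#' @param conviction_formula Passed to [rule_stats()].
#' @return A list of [contingency_table()] objects matching all constraints
#'   (length 1 when the reconstruction is unique).
#' @export
reconstruct_contingency <- function(t, stats, digits, y_total = NULL,
                                    conviction_formula = "standard") {
  t <- as.integer(t)
  need <- c("support", "confidence", "lift")
  if (!all(need %in% names(stats))) stop("stats must name support, confidence, lift")
  conv <- if ("conviction" %in% names(stats)) stats[["conviction"]] else NA_real_
  rounds_to <- function(value, target, dg) {
    is.finite(value) && abs(round(value, dg) - target) < 1e-9
  }
  eps <- 1e-9
  ds <- digits[["support"]]; half_s <- 0.5 * 10^-ds
  a_lo <- max(1L, ceiling((stats[["support"]] - half_s) * t - eps))
  a_hi <- floor((stats[["support"]] + half_s) * t + eps)
  out <- list()
  for (a in seq.int(a_lo, length.out = max(0L, a_hi - a_lo + 1L))) {
    dc <- digits[["confidence"]]; half_c <- 0.5 * 10^-dc
    ab_lo <- max(a, ceiling(a / (stats[["confidence"]] + half_c) - eps))
    ab_hi <- floor(a / max(stats[["confidence"]] - half_c, eps) + eps)
    for (ab in seq.int(ab_lo, length.out = max(0L, ab_hi - ab_lo + 1L))) {
      b <- ab - a
      if (is.na(conv) && b != 0L) next
      confidence <- a / ab
      dl <- digits[["lift"]]; half_l <- 0.5 * 10^-dl
      # lift = confidence / ((a+c)/t)  =>  a+c = confidence * t / lift
      ac_lo <- max(a, ceiling(confidence * t / (stats[["lift"]] + half_l) - eps))
      ac_hi <- min(t - b, floor(confidence * t / max(stats[["lift"]] - half_l, eps) + eps))
      for (ac in seq.int(ac_lo, length.out = max(0L, ac_hi - ac_lo + 1L))) {
        cc <- ac - a
        if (!is.null(y_total) && ac != y_total) next
        d <- t - a - b - cc
        if (d < 0L) next
        ct <- contingency_table(a, b, cc, d)
        st <- rule_stats(ct, conviction_formula)
        ok <- rounds_to(st$support, stats[["support"]], ds) &&
          rounds_to(st$confidence, stats[["confidence"]], dc) &&
          rounds_to(st$lift, stats[["lift"]], dl)
        if (ok && !is.na(conv))
          ok <- rounds_to(st$conviction, conv, digits[["conviction"]])
        if (ok && is.na(conv)) ok <- is.na(st$conviction)
        if (ok) out[[length(out) + 1L]] <- ct
      }
    }
  }
  out
}
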