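#' Cohort summary
#'
#' Case and adverse-reaction totals, overall and per gender. ADR totals
#' use per-case deduplicated terms — the same convention the transaction
#' builders use — so the summary matches what the miner sees.
#'
#' @param cohort A `jader_cases` object.
#' @return Object of class `cohort_summary`: list with `n_cases`,
#'   `n_adr`, per-gender `cases` and `adrs` (named vectors over female,
#'   male, unknown), and `adr_convention`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "jader_cases"))
  g <- factor(cohort$gender, levels = c("female", "male", "unknown"))
  n_terms <- lengths(cohort$adr_terms)
  structure(list(n_cases = length(cohort),
                 n_adr = sum(n_terms),
                 cases = table(g),
                 adrs = tapply(n_terms, g, sum, default = 0L),
                 adr_convention = "per-case deduplicated terms"),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort:", x$n_cases, "case(s),", x$n_adr,
      "adverse reactions (", x$adr_convention, ")\n")
  for (g in names(x$cases))
    cat(sprintf("  %-8s %5d case(s), %5d ADR(s)\n", g, x$cases[[g]], x$adrs[[g]]))
  invisible(x)
}

new_adr_report <- function(class_name, analysis_kind, rows, fit, cohort_summary,
                           top_k) {
  structure(list(class_name = class_name, analysis_kind = analysis_kind,
                 rows = rows, fit = fit, cohort_summary = cohort_summary,
                 top_k = top_k),
            class = "adr_report")
}

empty_report_rows <- function() {
  data.frame(X = character(0), Y = character(0), support = numeric(0),
             confidence = numeric(0), lift = numeric(0),
             conviction = numeric(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), t = integer(0),
             stringsAsFactors = FALSE)
}

rules_to_rows <- function(rules_df) {
  if (nrow(rules_df) == 0L) return(empty_report_rows())
  data.frame(
    X = vapply(rules_df$lhs, function(k) paste(display_label(k), collapse = ", "),
               character(1)) %||% character(0),
    Y = vapply(rules_df$rhs, function(k) paste(display_label(k), collapse = ", "),
               character(1)) %||% character(0),
    support = rules_df$support, confidence = rules_df$confidence,
    lift = rules_df$lift, conviction = rules_df$conviction,
    a = rules_df$a, b = rules_df$b, c = rules_df$c, d = rules_df$d,
    t = rules_df$t, stringsAsFactors = FALSE)
}

#' ADR-to-ADR association analysis
#'
#' Builds ADR-only transactions from the cohort, mines association rules,
#' keeps rules with a single adverse-reaction consequent (published rule
#' tables show only those; set `include_multi_consequent` to keep all)
#' and reports the top rules by descending support, ties broken by
#' descending confidence, descending lift, then antecedent labels.
#'
#' @param cohort Non-empty `jader_cases` object.
#' @param config A [miner_config()].
#' @param top_k Number of ranked rows to report, default 5.
#' @param class_name Label for the report, e.g. `"SSRI"`.
#' @param include_multi_consequent Keep rules with multi-item consequents.
#' @return Object of class `adr_report`; element `rows` holds the ranked
#'   table (full precision), `fit` the complete `adr_rules` object.
#' @export
run_adr_analysis <- function(cohort, config = miner_config(), top_k = 5,
                             class_name = "cohort",
                             include_multi_consequent = FALSE) {
  stopifnot(inherits(cohort, "jader_cases"))
  if (length(cohort) == 0L) stop("empty cohort")
  ts <- build_adr_transactions(cohort)
  fit <- apriori_rules(ts, config)
  r <- fit$rules
  if (!include_multi_consequent)
    r <- r[lengths(r$rhs) == 1L, , drop = FALSE]
  rows <- rules_to_rows(r)
  rows <- utils::head(rows, top_k)
  new_adr_report(class_name, "adr_adr", rows, fit, summarize_cohort(cohort),
                 top_k)
}

#' Demographics-to-gender association analysis
#'
#' Builds transactions of ADR + age-decade + gender items, mines rules
#' constrained to a single gender consequent with gender-free
#' antecedents, and reports, per gender, the top rules by descending
#' support. Gender-unknown cases stay in the transaction total, so the
#' gender marginal (and hence lift) is taken over the whole cohort.
#'
#' @inheritParams run_adr_analysis
#' @param top_k_per_gender Ranked rows per gender, default 3.
#' @param age_map See [default_age_map()].
#' @return An `adr_report` (analysis kind `demo_gender`); rows list the
#'   female block first, then the male block.
#' @export
run_demo_analysis <- function(cohort, config = miner_config(consequent_kind = "gender"),
                              top_k_per_gender = 3, class_name = "cohort",
                              age_map = default_age_map()) {
  stopifnot(inherits(cohort, "jader_cases"))
  if (length(cohort) == 0L) stop("empty cohort")
  if (is.null(config$consequent_kind)) config$consequent_kind <- "gender"
  smry <- summarize_cohort(cohort)
  if (sum(smry$cases[c("female", "male")]) == 0L) {
    warning("no gender-known cases in cohort; empty report")
    return(new_adr_report(class_name, "demo_gender", empty_report_rows(),
                          NULL, smry, top_k_per_gender))
  }
  ts <- build_demo_transactions(cohort, age_map)
  fit <- apriori_rules(ts, config)
  r <- fit$rules
  blocks <- lapply(c("female", "male"), function(g) {
    utils::head(r[r$rhs_key == item_key("gender", g), , drop = FALSE],
                top_k_per_gender)
  })
  rows <- rules_to_rows(do.call(rbind, blocks))
  new_adr_report(class_name, "demo_gender", rows, fit, smry, top_k_per_gender)
}

#' @export
print.adr_report <- function(x, ...) {
  cat(sprintf("%s analysis, cohort '%s': %d reported rule(s)\n",
              if (x$analysis_kind == "adr_adr") "ADR-ADR" else "demographics-gender",
              x$class_name, nrow(x$rows)))
  print(x$cohort_summary)
  if (nrow(x$rows)) {
    shown <- format_report_rows(x$rows, default_report_digits(x$analysis_kind))
    print(shown, row.names = FALSE)
  }
  invisible(x)
}

default_report_digits <- function(analysis_kind) {
  if (analysis_kind == "adr_adr")
    c(support = 4, confidence = 2, lift = 1, conviction = 1)
  else
    c(support = 4, confidence = 2, lift = 2, conviction = 2)
}

format_report_rows <- function(rows, digits) {
  fmt <- function(v, d) {
    out <- formatC(round(v, d), format = "f", digits = d)
    out[is.na(v)] <- "NA"
    out
  }
  data.frame(X = rows$X, Y = rows$Y,
             Support = fmt(rows$support, digits[["support"]]),
             Confidence = fmt(rows$confidence, digits[["confidence"]]),
             Lift = fmt(rows$lift, digits[["lift"]]),
             Conviction = fmt(rows$conviction, digits[["conviction"]]),
             stringsAsFactors = FALSE)
}

#' Write a ranked rule report to CSV
#'
#' Writes the rounded report table (columns Type, X, Y, Support,
#' Confidence, Lift, Conviction; literal `NA` token for undefined
#' conviction) and a full-precision companion file
#' (`<path minus .csv>_full.csv`) that also carries the contingency
#' cells. Byte output is deterministic for identical input.
#'
#' @param report An `adr_report`.
#' @param path Output CSV path.
#' @param digits Named rounding digits; defaults depend on the analysis
#'   kind (support 4, confidence 2, lift/conviction 1 for ADR-ADR or 2
#'   for demographic reports).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(report, path, digits = NULL) {
  stopifnot(inherits(report, "adr_report"))
  if (is.null(digits)) digits <- default_report_digits(report$analysis_kind)
  rows <- report$rows
  rounded <- cbind(Type = rep(report$class_name, nrow(rows)),
                   format_report_rows(rows, digits))
  if (nrow(rows) == 0L)
    rounded <- data.frame(Type = character(0), X = character(0), Y = character(0),
                          Support = character(0), Confidence = character(0),
                          Lift = character(0), Conviction = character(0))
  full <- cbind(Type = rep(report$class_name, nrow(rows)),
                rows[, c("X", "Y", "support", "confidence", "lift",
                         "conviction", "a", "b", "c", "d", "t")])
  if (nrow(rows) == 0L) full <- full[0, , drop = FALSE]
  full_num <- full
  for (col in c("support", "confidence", "lift", "conviction"))
    full_num[[col]] <- ifelse(is.na(full[[col]]), "NA",
                              formatC(full[[col]], format = "g", digits = 15))
  full_path <- sub("\\.csv$", "_full.csv", path)
  if (identical(full_path, path)) full_path <- paste0(path, "_full.csv")
  write_csv_det(data.frame(lapply(rounded, as.character),
                           stringsAsFactors = FALSE, check.names = FALSE), path)
  write_csv_det(data.frame(lapply(full_num, as.character),
                           stringsAsFactors = FALSE, check.names = FALSE), full_path)
  invisible(c(report = path, full = full_path))
}
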