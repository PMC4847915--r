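#' Canonical column names per JADER-style table schema
#'
#' @param schema `"DEMO"`, `"REAC"` or `"DRUG"`.
#' @return Character vector of required canonical column names.
#' @export
jader_schema_columns <- function(schema = c("DEMO", "REAC", "DRUG")) {
  switch(match.arg(schema),
         DEMO = c("case_id", "gender", "age", "weight"),
         REAC = c("case_id", "adr_term", "outcome"),
         DRUG = c("case_id", "drug_name", "causality"))
}

#' Default value maps for gender and causality fields
#'
#' Real JADER releases code gender and causality in Japanese; synthetic
#' fixtures use English. Both map onto the package's enumerations;
#' anything outside the map becomes `"unknown"`.
#' @return Named character vector.
#' @export
default_gender_map <- function() {
  c("female" = "female", "male" = "male",
    "女性" = "female", "男性" = "male")
}

#' @rdname default_gender_map
#' @export
default_causality_map <- function() {
  c("suspected" = "suspected", "concomitant" = "concomitant",
    "interacting" = "interacting",
    "被疑薬" = "suspected", "併用薬" = "concomitant",
    "相互作用" = "interacting")
}

#' Read one JADER-style CSV table
#'
#' Reads a DEMO, REAC or DRUG table, validating the header against the
#' schema's required columns (after applying `col_map`), preserving row
#' order, and normalising enumerated fields. Extra columns are ignored.
#'
#' @param path CSV file path; first row is the header, quoted fields
#'   allowed.
#' @param schema `"DEMO"`, `"REAC"` or `"DRUG"`.
#' @param encoding Text encoding of the file; `"UTF-8"` for fixtures,
#'   `"CP932"` for real JADER downloads.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the header names actually present (e.g.
#'   `c(case_id = "識別番号")`).
#' @param gender_map,causality_map Value maps; see [default_gender_map()].
#' @return A data.frame with the canonical columns (character), classed
#'   `jader_demo`, `jader_reac` or `jader_drug`.
#' @export
read_jader_table <- function(path, schema = c("DEMO", "REAC", "DRUG"),
                             encoding = "UTF-8", col_map = NULL,
                             gender_map = default_gender_map(),
                             causality_map = default_causality_map()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = encoding, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read ", path, " with encoding ", encoding,
                             ": ", conditionMessage(e)),
    warning = function(w) stop("cannot read ", path, " with encoding ", encoding,
                               ": ", conditionMessage(w)))
  cols <- jader_schema_columns(schema)
  src <- stats::setNames(cols, cols)
  if (!is.null(col_map)) src[names(col_map)] <- col_map
  missing <- src[!(src %in% names(raw))]
  if (length(missing))
    stop(schema, " table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- stats::setNames(raw[, unname(src), drop = FALSE], names(src))
  if (any(!nzchar(trimws(out$case_id))))
    stop(schema, " table: empty case_id at data row(s) ",
         paste(which(!nzchar(trimws(out$case_id))), collapse = ", "))
  out$case_id <- trimws(out$case_id)
  if (schema == "DEMO") {
    g <- unname(gender_map[out$gender])
    out$gender <- ifelse(is.na(g), "unknown", g)
  } else if (schema == "REAC") {
    out$adr_term <- trimws(out$adr_term)
    bad <- which(!nzchar(out$adr_term))
    if (length(bad))
      stop("REAC table: empty adr_term at data row(s) ",
           paste(bad, collapse = ", "))
  } else {
    out$drug_name <- trimws(out$drug_name)
    if (any(!nzchar(out$drug_name)))
      stop("DRUG table: empty drug_name at data row(s) ",
           paste(which(!nzchar(out$drug_name)), collapse = ", "))
    cz <- unname(causality_map[out$causality])
    out$causality <- ifelse(is.na(cz), "unknown", cz)
  }
  class(out) <- c(paste0("jader_", tolower(schema)), "data.frame")
  out
}

new_jader_cases <- function(case_id, gender, age_raw, adr_terms,
                            drug_names, drug_causality) {
  structure(list(case_id = case_id, gender = gender, age_raw = age_raw,
                 adr_terms = adr_terms, drug_names = drug_names,
                 drug_causality = drug_causality),
            class = "jader_cases")
}

#' Join DEMO/REAC/DRUG tables into per-case records
#'
#' One case per DEMO row (the patient is the unit of analysis). REAC and
#' DRUG rows whose case_id has no DEMO row are dropped with a message.
#' ADR terms are deduplicated per case; cases without any REAC row are
#' kept with an empty ADR set — they still count in the transaction total
#' and populate the d cell of contingency tables.
#'
#' @param demo,reac,drug Tables from [read_jader_table()]; `drug` may be
#'   `NULL` when no cohort selection is needed.
#' @param quiet Suppress the dropped-row / size messages.
#' @return An object of class `jader_cases` (column-oriented list with
#'   `case_id`, `gender`, `age_raw` and list columns `adr_terms`,
#'   `drug_names`, `drug_causality`), subsettable with `[`.
#' @export
assemble_cases <- function(demo, reac, drug = NULL, quiet = FALSE) {
  stopifnot(inherits(demo, "jader_demo"), inherits(reac, "jader_reac"))
  if (anyDuplicated(demo$case_id))
    stop("duplicate case_id in DEMO table: ",
         paste(unique(demo$case_id[duplicated(demo$case_id)]), collapse = ", "))
  lev <- demo$case_id
  drop_msg <- function(tbl, what) {
    n_drop <- sum(!(tbl$case_id %in% lev))
    if (n_drop > 0 && !quiet)
      message("assemble_cases: dropped ", n_drop, " ", what,
              " row(s) with case_id absent from DEMO")
    tbl[tbl$case_id %in% lev, , drop = FALSE]
  }
  reac <- drop_msg(reac, "REAC")
  adr <- lapply(split(reac$adr_term, factor(reac$case_id, levels = lev)),
                function(a) sort(unique(a), method = "radix"))
  if (!is.null(drug)) {
    stopifnot(inherits(drug, "jader_drug"))
    drug <- drop_msg(drug, "DRUG")
    f <- factor(drug$case_id, levels = lev)
    dn <- split(drug$drug_name, f)
    dc <- split(drug$causality, f)
  } else {
    dn <- dc <- rep(list(character(0)), length(lev))
  }
  if (!quiet) message("assemble_cases: ", length(lev), " case(s)")
  new_jader_cases(lev, demo$gender, demo$age, unname(adr),
                  unname(dn), unname(dc))
}

#' @export
length.jader_cases <- function(x) length(x$case_id)

#' @export
`[.jader_cases` <- function(x, i) {
  new_jader_cases(x$case_id[i], x$gender[i], x$age_raw[i],
                  x$adr_terms[i], x$drug_names[i], x$drug_causality[i])
}

#' @export
print.jader_cases <- function(x, ...) {
  cat("JADER cases:", length(x), "case(s)\n")
  if (length(x)) {
    cat("  gender:", paste(names(table(x$gender)), table(x$gender),
                           sep = "=", collapse = ", "), "\n")
    cat("  ADR terms per case: mean",
        round(mean(lengths(x$adr_terms)), 2), "\n")
  }
  invisible(x)
}

#' Drug-class cohort configuration
#'
#' @param class_name Cohort label, e.g. `"SSRI"`.
#' @param member_names Non-empty character vector of drug-name match
#'   strings (generic names; JADER names carry salt/brand suffixes, hence
#'   the substring default).
#' @param match_mode `"substring"` (default) or `"exact"`.
#' @param causality_filter Causality roles that qualify a case; default
#'   `"suspected"`, the conservative pharmacovigilance convention.
#' @return Object of class `drug_class_config`.
#' @export
drug_class_config <- function(class_name, member_names,
                              match_mode = c("substring", "exact"),
                              causality_filter = "suspected") {
  if (length(member_names) == 0L || any(!nzchar(member_names)))
    stop("drug class '", class_name, "' needs a non-empty member_names list")
  stopifnot(all(causality_filter %in%
                  c("suspected", "concomitant", "interacting", "unknown")))
  structure(list(class_name = class_name, member_names = member_names,
                 match_mode = match.arg(match_mode),
                 causality_filter = causality_filter),
            class = "drug_class_config")
}

#' Select the cases exposed to a drug class
#'
#' Retains the cases having at least one drug entry whose name matches a
#' configured member name (substring containment or exact equality) and
#' whose causality role is within the configured filter. A case on drugs
#' of several classes appears in each class's cohort.
#'
#' @param cases A `jader_cases` object.
#' @param config A [drug_class_config()].
#' @return The matching subset, still a `jader_cases` object.
#' @export
filter_cohort <- function(cases, config) {
  stopifnot(inherits(cases, "jader_cases"), inherits(config, "drug_class_config"))
  hit <- vapply(seq_along(cases$case_id), function(i) {
    nm <- cases$drug_names[[i]]
    cz <- cases$drug_causality[[i]]
    ok <- cz %in% config$causality_filter
    if (!any(ok)) return(FALSE)
    nm <- nm[ok]
    if (config$match_mode == "exact") any(nm %in% config$member_names)
    else any(vapply(config$member_names,
                    function(m) any(grepl(m, nm, fixed = TRUE)), logical(1)))
  }, logical(1))
  cases[hit]
}
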