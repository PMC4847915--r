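#' Item keys
#'
#' Items carry a kind (`adr`, `age_decade`, `gender`) and a label. The
#' canonical key `"<kind>:<label>"` is what transactions store; sorting
#' keys byte-wise (radix) gives the canonical (kind, label) item order on
#' which candidate generation and all output ordering rely.
#'
#' @param kind One of `"adr"`, `"age_decade"`, `"gender"`.
#' @param label Non-empty item label.
#' @return Character key(s).
#' @export
item_key <- function(kind, label) {
  stopifnot(all(kind %in% c("adr", "age_decade", "gender")),
            all(nzchar(label)))
  paste0(kind, ":", label)
}

item_kind <- function(key) sub(":.*$", "", key)

item_label <- function(key) sub("^[^:]*:", "", key)

#' Human-readable label for an item key
#'
#' ADR labels pass through verbatim; gender and age-decade labels are
#' capitalised the way published rule tables print them ("Female",
#' "Twenties").
#' @param key Character vector of item keys.
#' @return Character vector of display labels.
#' @export
display_label <- function(key) {
  kind <- item_kind(key)
  lab <- item_label(key)
  cap <- kind %in% c("gender", "age_decade")
  lab[cap] <- paste0(toupper(substr(lab[cap], 1, 1)), substr(lab[cap], 2, nchar(lab[cap])))
  lab
}

#' Construct a transaction set
#'
#' A transaction set is the mining input: one item set per case, plus the
#' total case count t. Cases with no items contribute empty transactions
#' and still count in t — they populate the d cell of every rule's
#' contingency table.
#'
#' @param transactions List of character vectors of item keys (one per
#'   case). Items are deduplicated and canonically sorted per transaction.
#' @return Object of class `transaction_set` with elements `transactions`
#'   (list), `t` (integer) and `vocabulary` (data.frame with `key`,
#'   `kind`, `label`).
#' @export
transaction_set <- function(transactions) {
  stopifnot(is.list(transactions))
  transactions <- lapply(transactions, function(tr) {
    tr <- unique(as.character(tr))
    sort(tr, method = "radix")
  })
  keys <- unlist(transactions, use.names = FALSE) %||% character(0)
  keys <- sort(unique(keys), method = "radix")
  vocab <- data.frame(key = keys, kind = item_kind(keys),
                      label = item_label(keys), stringsAsFactors = FALSE)
  structure(list(transactions = transactions,
                 t = length(transactions),
                 vocabulary = vocab),
            class = "transaction_set")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.transaction_set <- function(x, ...) {
  cat("Transaction set: t =", x$t, "cases,",
      nrow(x$vocabulary), "distinct items\n")
  if (x$t > 0) {
    sz <- lengths(x$transactions)
    cat(sprintf("  items per case: min %d / median %g / max %d (%d empty)\n",
                min(sz), stats::median(sz), max(sz), sum(sz == 0L)))
  }
  invisible(x)
}

#' ADR-only transactions from a cohort
#'
#' One transaction per case containing its deduplicated adverse-reaction
#' items. This is the input of the ADR-to-ADR association analysis.
#'
#' @param cohort A [jader_cases] object (see [assemble_cases()]).
#' @return A [transaction_set()] with `t` equal to the cohort size.
#' @export
build_adr_transactions <- function(cohort) {
  stopifnot(inherits(cohort, "jader_cases"))
  transaction_set(lapply(cohort$adr_terms, function(a)
    if (length(a)) item_key("adr", a) else character(0)))
}

#' Default decade-string to age-item map
#'
#' Maps JADER-style decade-coded age strings to canonical English decade
#' labels. Strings outside the map (e.g. "10歳未満", "高齢者") yield no
#' age item. Ninety and above collapse into `"nineties+"`.
#' @return Named character vector: raw string -> canonical label.
#' @export
default_age_map <- function() {
  c("10代" = "tens",      "20代" = "twenties",
    "30代" = "thirties",  "40代" = "forties",
    "50代" = "fifties",   "60代" = "sixties",
    "70代" = "seventies", "80代" = "eighties",
    "90代" = "nineties+", "100歳以上" = "nineties+")
}

#' Map a decade-coded age string to an age item
#'
#' @param age_raw Character vector of raw age strings (e.g. `"20代"`).
#' @param age_map Named map from raw strings to canonical decade labels;
#'   see [default_age_map()].
#' @return Character vector of `age_decade` item keys, `NA_character_`
#'   where the string is empty or unmapped (no item).
#' @examples
#' age_to_decade_item(c("20代", "", "80代"))
#' @export
age_to_decade_item <- function(age_raw, age_map = default_age_map()) {
  lab <- unname(age_map[as.character(age_raw)])
  ifelse(is.na(lab), NA_character_, item_key("age_decade", ifelse(is.na(lab), "x", lab)))
}

#' Demographic transactions from a cohort
#'
#' One transaction per case containing its ADR items, one `age_decade`
#' item when the age string maps, and one `gender` item when gender is
#' female or male. Gender- and age-unknown cases stay in the set with the
#' item simply absent, so t equals the full cohort size; this matters for
#' the consequent marginal (and hence lift) of gender rules.
#'
#' @inheritParams build_adr_transactions
#' @param age_map See [default_age_map()].
#' @return A [transaction_set()].
#' @export
build_demo_transactions <- function(cohort, age_map = default_age_map()) {
  stopifnot(inherits(cohort, "jader_cases"))
  age_items <- age_to_decade_item(cohort$age_raw, age_map)
  gender_items <- ifelse(cohort$gender %in% c("female", "male"),
                         item_key("gender", ifelse(cohort$gender == "unknown",
                                                   "x", cohort$gender)),
                         NA_character_)
  trs <- vector("list", length(cohort$case_id))
  for (i in seq_along(trs)) {
    it <- if (length(cohort$adr_terms[[i]])) item_key("adr", cohort$adr_terms[[i]]) else character(0)
    if (!is.na(age_items[i])) it <- c(it, age_items[i])
    if (!is.na(gender_items[i])) it <- c(it, gender_items[i])
    trs[[i]] <- it
  }
  transaction_set(trs)
}

#' Export transactions in basket format
#'
#' Writes one transaction per line, item keys separated by tabs, for
#' cross-checking with external itemset miners. Empty transactions become
#' empty lines so line count equals t.
#'
#' @param ts A [transaction_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_basket <- function(ts, path) {
  stopifnot(inherits(ts, "transaction_set"))
  lines <- vapply(ts$transactions, paste, character(1), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
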