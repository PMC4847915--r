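# Independent oracles: exhaustive power-set itemset enumeration and direct
# per-transaction rule scoring. Deliberately share no code with the
# level-wise miner (bitmask counting here, tid-list intersection there).

brute_frequent <- function(transactions, min_support, max_len = 10) {
  t <- length(transactions)
  items <- sort(unique(unlist(transactions, use.names = FALSE)), method = "radix")
  n <- length(items)
  stopifnot(n <= 30)
  bits <- 2L^(seq_len(n) - 1L)
  tmask <- vapply(transactions, function(tr)
    sum(bits[match(tr, items)]), numeric(1))
  keys <- character(0); sets <- list(); counts <- integer(0)
  for (mask in seq_len(2L^n - 1L)) {
    member <- bitwAnd(mask, bits) > 0
    if (sum(member) > max_len) next
    cnt <- sum(bitwAnd(tmask, mask) == mask)
    if (cnt / t >= min_support - 1e-9) {
      sets[[length(sets) + 1L]] <- items[member]
      counts[length(counts) + 1L] <- cnt
      keys[length(keys) + 1L] <- paste(items[member], collapse = "\x1f")
    }
  }
  df <- data.frame(key = keys, count = counts,
                   size = lengths(sets), stringsAsFactors = FALSE)
  df$items <- sets
  df[order(df$size, df$key, method = "radix"), , drop = FALSE]
}

brute_rules <- function(transactions, min_support, min_confidence,
                        consequent_kind = NULL, max_len = 10) {
  t <- length(transactions)
  bf <- brute_frequent(transactions, min_support, max_len)
  rows <- list()
  for (r in which(bf$size >= 2)) {
    its <- bf$items[[r]]
    n <- length(its)
    for (mask in seq_len(2L^n - 2L)) {
      sel <- bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0
      X <- its[sel]; Y <- its[!sel]
      if (!is.null(consequent_kind)) {
        if (length(Y) != 1L || !startsWith(Y, paste0(consequent_kind, ":"))) next
        if (any(startsWith(X, paste0(consequent_kind, ":")))) next
      }
      has_x <- vapply(transactions, function(tr) all(X %in% tr), logical(1))
      has_y <- vapply(transactions, function(tr) all(Y %in% tr), logical(1))
      a <- sum(has_x & has_y); b <- sum(has_x & !has_y)
      cc <- sum(!has_x & has_y); d <- sum(!has_x & !has_y)
      conf <- a / (a + b)
      if (conf + 1e-12 < min_confidence) next
      rows[[length(rows) + 1L]] <- data.frame(
        lhs_key = paste(X, collapse = "\x1f"),
        rhs_key = paste(Y, collapse = "\x1f"),
        a = a, b = b, c = cc, d = d,
        support = a / t, confidence = conf,
        lift = conf / ((a + cc) / t),
        conviction = if (b == 0) NA_real_ else ((b + d) / t) / (b / (a + b)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(lhs_key = character(0), rhs_key = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), support = numeric(0),
                      confidence = numeric(0), lift = numeric(0),
                      conviction = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$lhs_key, out$rhs_key, method = "radix"), , drop = FALSE]
}

# random transaction set over items a..l; caller controls the RNG state
random_transactions <- function(n_trans, n_items, p_range = c(0.1, 0.6)) {
  items <- paste0("adr:", letters[seq_len(n_items)])
  p <- stats::runif(n_items, p_range[1], p_range[2])
  lapply(seq_len(n_trans), function(i) items[stats::runif(n_items) < p])
}

expect_same_rules <- function(fit, oracle) {
  got <- fit$rules
  got <- got[order(got$lhs_key, got$rhs_key, method = "radix"), , drop = FALSE]
  expect_equal(nrow(got), nrow(oracle))
  if (nrow(oracle) == 0) return(invisible(NULL))
  expect_identical(got$lhs_key, oracle$lhs_key)
  expect_identical(got$rhs_key, oracle$rhs_key)
  expect_identical(got$a, oracle$a)
  expect_identical(got$b, oracle$b)
  expect_identical(got$c, oracle$c)
  expect_identical(got$d, oracle$d)
  expect_equal(got$support, oracle$support, tolerance = 1e-12)
  expect_equal(got$confidence, oracle$confidence, tolerance = 1e-12)
  expect_equal(got$lift, oracle$lift, tolerance = 1e-12)
  expect_equal(got$conviction, oracle$conviction, tolerance = 1e-12)
}

# tiny in-code cohort builder
make_cases <- function(case_id, gender, age_raw, adr_terms,
                       drug_names = NULL, causality = NULL) {
  n <- length(case_id)
  if (is.null(drug_names)) drug_names <- rep(list(character(0)), n)
  if (is.null(causality))
    causality <- lapply(drug_names, function(d) rep("suspected", length(d)))
  structure(list(case_id = case_id, gender = gender, age_raw = age_raw,
                 adr_terms = lapply(adr_terms, function(a)
                   sort(unique(a), method = "radix")),
                 drug_names = drug_names, drug_causality = causality),
            class = "jader_cases")
}

write_csv_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
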