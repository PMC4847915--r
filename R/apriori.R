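#' Mining control parameters
#'
#' @param min_support Minimum support (fraction of transactions) for a
#'   frequent itemset; default 0.001 — at 1,000+ case cohorts this keeps
#'   rules backed by at least a handful of reports.
#' @param min_confidence Minimum rule confidence; default 0.8.
#' @param max_len Maximum itemset length, default 10.
#' @param consequent_kind Optional item kind (e.g. `"gender"`). When set,
#'   emitted rules must have exactly one item of that kind as consequent
#'   and none of it in the antecedent — the shape of the
#'   demographics-to-gender analysis.
#' @param conviction_formula Passed to [rule_stats()].
#' @return Object of class `miner_config`.
#' @export
miner_config <- function(min_support = 0.001, min_confidence = 0.8,
                         max_len = 10, consequent_kind = NULL,
                         conviction_formula = c("standard", "as_printed")) {
  stopifnot(is.numeric(min_support), min_support > 0, min_support <= 1,
            is.numeric(min_confidence), min_confidence > 0, min_confidence <= 1,
            max_len >= 2)
  if (!is.null(consequent_kind))
    stopifnot(consequent_kind %in% c("adr", "age_decade", "gender"))
  structure(list(min_support = min_support,
                 min_confidence = min_confidence,
                 max_len = as.integer(max_len),
                 consequent_kind = consequent_kind,
                 conviction_formula = match.arg(conviction_formula)),
            class = "miner_config")
}

SET_SEP <- "\x1f"  # itemset hash key separator; never occurs in item keys

set_key <- function(items) paste(items, collapse = SET_SEP)

#' Level-wise apriori frequent itemset mining
#'
#' Classic apriori: frequent k-itemsets are built by joining frequent
#' (k-1)-itemsets that share a (k-2)-prefix under canonical item order,
#' pruning every candidate with an infrequent subset (downward closure),
#' and counting support by intersecting per-itemset transaction-id lists.
#'
#' @param ts A [transaction_set()] with `t >= 1`.
#' @param config A [miner_config()].
#' @return Object of class `frequent_itemsets`: a data.frame with columns
#'   `key`, `items` (list column of item-key vectors, canonically
#'   sorted), `size`, `count`, `support`, ordered by size then key.
#'   Attribute `t` carries the transaction total.
#' @export
frequent_itemsets <- function(ts, config = miner_config()) {
  stopifnot(inherits(ts, "transaction_set"), inherits(config, "miner_config"))
  if (ts$t == 0L) stop("cannot mine an empty transaction set (t = 0)")
  t <- ts$t
  min_count <- config$min_support * t
  tol <- 1e-9

  ids <- rep.int(seq_len(t), lengths(ts$transactions))
  all_items <- unlist(ts$transactions, use.names = FALSE)
  tidlists <- if (length(all_items)) split(ids, all_items) else list()
  counts1 <- lengths(tidlists)
  keep <- counts1 >= min_count - tol
  lv_items <- lapply(sort(names(tidlists)[keep], method = "radix"), identity)
  lv_tids <- lapply(unlist(lv_items), function(k) tidlists[[k]])
  lv_items <- lapply(lv_items, as.character)

  res_items <- lv_items
  res_counts <- as.list(unname(counts1[vapply(lv_items, identity, character(1))]))

  freq_keys <- new.env(parent = emptyenv())
  for (it in lv_items) assign(set_key(it), TRUE, envir = freq_keys)

  k <- 2L
  while (length(lv_items) >= 2L && k <= config$max_len) {
    prefixes <- vapply(lv_items, function(it) set_key(it[-length(it)]), character(1))
    lasts <- vapply(lv_items, function(it) it[length(it)], character(1))
    nxt_items <- list(); nxt_tids <- list(); nxt_counts <- integer(0)
    for (grp in split(seq_along(lv_items), prefixes)) {
      if (length(grp) < 2L) next
      grp <- grp[order(lasts[grp], method = "radix")]
      for (i in seq_len(length(grp) - 1L)) {
        for (j in seq.int(i + 1L, length(grp))) {
          cand <- c(lv_items[[grp[i]]], lasts[grp[j]])
          if (k >= 3L) {  # downward-closure prune over all (k-1)-subsets
            ok <- TRUE
            for (drop in seq_len(k)) {
              if (!exists(set_key(cand[-drop]), envir = freq_keys, inherits = FALSE)) {
                ok <- FALSE; break
              }
            }
            if (!ok) next
          }
          tid <- intersect(lv_tids[[grp[i]]], lv_tids[[grp[j]]])
          if (length(tid) >= min_count - tol) {
            nxt_items[[length(nxt_items) + 1L]] <- cand
            nxt_tids[[length(nxt_tids) + 1L]] <- tid
            nxt_counts[length(nxt_counts) + 1L] <- length(tid)
          }
        }
      }
    }
    if (length(nxt_items) == 0L) break
    ord <- order(vapply(nxt_items, set_key, character(1)), method = "radix")
    nxt_items <- nxt_items[ord]; nxt_tids <- nxt_tids[ord]; nxt_counts <- nxt_counts[ord]
    for (it in nxt_items) assign(set_key(it), TRUE, envir = freq_keys)
    res_items <- c(res_items, nxt_items)
    res_counts <- c(res_counts, as.list(nxt_counts))
    lv_items <- nxt_items; lv_tids <- nxt_tids
    k <- k + 1L
  }

  counts <- as.integer(unlist(res_counts))
  out <- data.frame(key = vapply(res_items, set_key, character(1)),
                    size = lengths(res_items),
                    count = counts,
                    support = counts / t,
                    stringsAsFactors = FALSE)
  out$items <- res_items
  out <- out[order(out$size, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "t") <- t
  attr(out, "min_support") <- config$min_support
  class(out) <- c("frequent_itemsets", "data.frame")
  out
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2, every partition into a
#' non-empty antecedent X and consequent Y is scored; rules with
#' confidence >= `min_confidence` are kept, each carrying its full
#' contingency table and [rule_stats()]. With `consequent_kind` set, Y
#' must be exactly one item of that kind and X must contain none of it.
#'
#' @param itemsets Result of [frequent_itemsets()] on the same `ts`.
#' @param ts The [transaction_set()] the itemsets were mined from.
#' @param config A [miner_config()].
#' @return An `adr_rules` object; see [apriori_rules()].
#' @export
generate_rules <- function(itemsets, ts, config = miner_config()) {
  stopifnot(inherits(itemsets, "frequent_itemsets"),
            inherits(ts, "transaction_set"))
  t <- attr(itemsets, "t")
  if (!identical(t, ts$t)) stop("itemsets were not mined from this transaction set")
  count_of <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(itemsets)))
    assign(itemsets$key[r], itemsets$count[r], envir = count_of)

  tol <- 1e-12
  lhs <- list(); rhs <- list()
  a_ <- integer(0); b_ <- integer(0); c_ <- integer(0); d_ <- integer(0)
  sup <- conf <- lift <- convv <- numeric(0)

  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  for (r in seq_len(nrow(big))) {
    items <- big$items[[r]]
    n <- length(items)
    a <- big$count[r]
    kinds <- item_kind(items)
    for (mask in seq_len(2L^n - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(n) - 1L)))
      X <- items[sel]; Y <- items[!sel]
      if (!is.null(config$consequent_kind)) {
        if (length(Y) != 1L || item_kind(Y) != config$consequent_kind) next
        if (any(kinds[sel] == config$consequent_kind)) next
      }
      count_x <- get(set_key(X), envir = count_of)
      cf <- a / count_x
      if (cf + tol < config$min_confidence) next
      count_y <- get(set_key(Y), envir = count_of)
      ct <- contingency_table(a, count_x - a, count_y - a, t - count_x - count_y + a)
      st <- rule_stats(ct, config$conviction_formula)
      i <- length(lhs) + 1L
      lhs[[i]] <- X; rhs[[i]] <- Y
      a_[i] <- ct$a; b_[i] <- ct$b; c_[i] <- ct$c; d_[i] <- ct$d
      sup[i] <- st$support; conf[i] <- st$confidence
      lift[i] <- st$lift; convv[i] <- st$conviction
    }
  }

  rules <- data.frame(lhs_key = vapply(lhs, set_key, character(1)) %||% character(0),
                      rhs_key = vapply(rhs, set_key, character(1)) %||% character(0),
                      a = a_, b = b_, c = c_, d = d_, t = rep.int(t, length(a_)),
                      support = sup, confidence = conf, lift = lift,
                      conviction = convv, stringsAsFactors = FALSE)
  rules$lhs <- lhs
  rules$rhs <- rhs
  ord <- order(-rules$support, -rules$confidence, -rules$lift,
               rules$lhs_key, rules$rhs_key, method = "radix")
  rules <- rules[ord, , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(rules = rules, itemsets = itemsets, config = config, t = t),
            class = "adr_rules")
}

#' Mine association rules from a transaction set
#'
#' The package's central fitting function: level-wise apriori frequent
#' itemset search ([frequent_itemsets()]) followed by rule generation
#' ([generate_rules()]). Output ordering is deterministic — descending
#' support, then confidence, then lift, then canonical antecedent /
#' consequent keys — and independent of transaction order.
#'
#' @param ts A [transaction_set()].
#' @param config A [miner_config()].
#' @param ... Passed to [miner_config()] when `config` is not supplied.
#' @return Object of class `adr_rules` with elements `rules` (data.frame:
#'   list columns `lhs`, `rhs`, their keys, the contingency cells
#'   `a,b,c,d,t` and the four statistics), `itemsets`, `config`, `t`.
#' @examples
#' ts <- transaction_set(list(c("adr:A", "adr:B"), c("adr:A", "adr:B"), "adr:A"))
#' fit <- apriori_rules(ts, miner_config(min_support = 0.5, min_confidence = 0.6))
#' fit
#' @export
apriori_rules <- function(ts, config = miner_config(...), ...) {
  generate_rules(frequent_itemsets(ts, config), ts, config)
}

#' @export
print.adr_rules <- function(x, n = 6, ...) {
  cat(sprintf("Association rules: %d rule(s) from %d frequent itemset(s), t = %d\n",
              nrow(x$rules), nrow(x$itemsets), x$t))
  cat(sprintf("  thresholds: support >= %g, confidence >= %g%s\n",
              x$config$min_support, x$config$min_confidence,
              if (is.null(x$config$consequent_kind)) "" else
                paste0(", consequent kind = ", x$config$consequent_kind)))
  if (nrow(x$rules) > 0) {
    df <- as.data.frame(x)
    print(utils::head(df, n), row.names = FALSE)
    if (nrow(df) > n) cat("  ...", nrow(df) - n, "more rule(s)\n")
  }
  invisible(x)
}

#' @export
summary.adr_rules <- function(object, ...) {
  r <- object$rules
  cat(sprintf("adr_rules: %d rules over t = %d transactions\n", nrow(r), object$t))
  if (nrow(r) > 0) {
    cat("rule length (|X| + |Y|):\n")
    print(table(lengths(r$lhs) + lengths(r$rhs)))
    print(summary(r[, c("support", "confidence", "lift", "conviction")]))
  }
  invisible(object)
}

#' @export
as.data.frame.adr_rules <- function(x, ...) {
  r <- x$rules
  data.frame(X = vapply(r$lhs, function(k) paste(display_label(k), collapse = ", "),
                        character(1)) %||% character(0),
             Y = vapply(r$rhs, function(k) paste(display_label(k), collapse = ", "),
                        character(1)) %||% character(0),
             support = r$support, confidence = r$confidence,
             lift = r$lift, conviction = r$conviction,
             stringsAsFactors = FALSE)
}

#' @export
head.adr_rules <- function(x, n = 6L, ...) utils::head(as.data.frame(x), n, ...)
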