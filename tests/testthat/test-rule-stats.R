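test_that("contingency tallies presence/absence of rule sides per case", {
  ts <- transaction_set(list(c("adr:A", "adr:B"), "adr:A", "adr:B", character(0)))
  ct <- contingency(ts, "adr:A", "adr:B")
  expect_identical(unlist(ct[c("a", "b", "c", "d", "t")]),
                   c(a = 1L, b = 1L, c = 1L, d = 1L, t = 4L))

  # antecedent absent from every transaction
  ts2 <- transaction_set(list("adr:B", "adr:B", character(0)))
  ct2 <- contingency(ts2, "adr:A", "adr:B")
  expect_identical(c(ct2$a, ct2$b), c(0L, 0L))

  expect_error(contingency(ts, c("adr:A", "adr:B"), "adr:B"), "overlap")
  expect_error(contingency(ts, character(0), "adr:B"), "non-empty")
})

test_that("contingency agrees with an independent per-transaction tally", {
  set.seed(11)
  for (rep in 1:20) {
    trans <- random_transactions(60, 8)
    ts <- transaction_set(trans)
    pool <- ts$vocabulary$key
    if (length(pool) < 3) next
    x <- sample(pool, 2)
    y <- sample(setdiff(pool, x), 1)
    ct <- contingency(ts, x, y)
    hx <- vapply(ts$transactions, function(tr) all(x %in% tr), logical(1))
    hy <- vapply(ts$transactions, function(tr) all(y %in% tr), logical(1))
    expect_identical(c(ct$a, ct$b, ct$c, ct$d),
                     c(sum(hx & hy), sum(hx & !hy), sum(!hx & hy), sum(!hx & !hy)))
    expect_identical(ct$t, ts$t)
  }
})

test_that("published antidepressant rule rows are reproduced from their integer tables", {
  # each row: cells a, b, c, d then the printed support/confidence/lift/conviction
  rows <- list(
    list(ct = c(26, 2, 4, 4345),    printed = c(0.0059, 0.93, 135.5, 13.9),
         digits = c(4, 2, 1, 1)),   # SSRI AST -> ALT increased
    list(ct = c(6, 0, 7, 922),      printed = c(0.0064, 1.00, 71.9, NA),
         digits = c(4, 2, 1, 1)),   # SNRI INR increased -> drug interaction
    list(ct = c(4, 1, 7, 674),      printed = c(0.0058, 0.80, 49.9, 4.9),
         digits = c(4, 2, 1, 1)),   # NaSSA anxiety -> irritability
    list(ct = c(24, 3, 368, 291),   printed = c(0.035, 0.89, 1.56, 3.86),
         digits = c(3, 2, 2, 2)),   # NaSSA suicidal ideation -> female
    list(ct = c(52, 12, 2510, 1803), printed = c(0.012, 0.81, 1.39, 2.21),
         digits = c(3, 2, 2, 2)),   # SSRI twenties + suicide attempt -> female
    list(ct = c(20, 3, 489, 423),   printed = c(0.02, 0.87, 1.60, 3.49),
         digits = c(2, 2, 2, 2)))   # SNRI eighties + SIADH -> female
  for (row in rows) {
    st <- rule_stats(do.call(contingency_table, as.list(row$ct)))
    got <- c(round(st$support, row$digits[1]), round(st$confidence, row$digits[2]),
             round(st$lift, row$digits[3]),
             if (is.na(st$conviction)) NA else round(st$conviction, row$digits[4]))
    expect_equal(got, row$printed)
  }
})

test_that("degenerate and boundary tables behave as defined", {
  # perfect co-occurrence: a = t
  st <- rule_stats(contingency_table(7, 0, 0, 0))
  expect_equal(unlist(st[c("support", "confidence", "lift")]),
               c(support = 1, confidence = 1, lift = 1))
  expect_true(is.na(st$conviction))
  # exact independence: a/t = ((a+b)/t) ((a+c)/t)
  st2 <- rule_stats(contingency_table(10, 10, 10, 10))
  expect_equal(st2$lift, 1)
  expect_error(rule_stats(contingency_table(0, 0, 0, 0)), "t must be")
  expect_error(rule_stats(contingency_table(0, 0, 3, 5)), "antecedent never")
  expect_error(rule_stats(contingency_table(0, 4, 0, 5)), "consequent never")
  expect_error(contingency_table(-1, 1, 1, 1), "non-negative")
})

test_that("algebraic identities hold across random tables", {
  set.seed(5)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(20:2000, 1), runif(4, 0.05, 1)))
    if (cells[1] + cells[2] == 0 || cells[1] + cells[3] == 0) next
    ct <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    st <- rule_stats(ct)
    supp_y <- (ct$a + ct$c) / ct$t
    # lift * supp(Y) = confidence exactly
    expect_equal(st$lift * supp_y, st$confidence, tolerance = 1e-12)
    # conviction = (1 - supp(Y)) / (1 - confidence), NA iff confidence = 1
    if (ct$b == 0L) {
      expect_true(is.na(st$conviction))
      expect_equal(st$confidence, 1)
    } else {
      expect_equal(st$conviction, (1 - supp_y) / (1 - st$confidence),
                   tolerance = 1e-12)
    }
    expect_lte(st$support, st$confidence + 1e-12)
  }
})

test_that("swapping rule sides keeps support and lift, not confidence/conviction", {
  fwd <- rule_stats(contingency_table(30, 5, 50, 915))
  rev <- rule_stats(contingency_table(30, 50, 5, 915))
  expect_equal(fwd$support, rev$support)
  expect_equal(fwd$lift, rev$lift, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fwd$confidence, rev$confidence)))
  expect_false(isTRUE(all.equal(fwd$conviction, rev$conviction)))
})

test_that("integer tables are reconstructable from printed rounded statistics", {
  # ADR-ADR rows: the four rounded statistics pin the table uniquely
  got <- reconstruct_contingency(
    4377, c(support = 0.0059, confidence = 0.93, lift = 135.5, conviction = 13.9),
    digits = c(support = 4, confidence = 2, lift = 1, conviction = 1))
  expect_length(got, 1)
  expect_identical(unlist(got[[1]][c("a", "b", "c", "d")]),
                   c(a = 26L, b = 2L, c = 4L, d = 4345L))

  got2 <- reconstruct_contingency(
    935, c(support = 0.0064, confidence = 1.00, lift = 71.9, conviction = NA),
    digits = c(support = 4, confidence = 2, lift = 1, conviction = 1))
  expect_length(got2, 1)
  expect_identical(unlist(got2[[1]][c("a", "b", "c", "d")]),
                   c(a = 6L, b = 0L, c = 7L, d = 922L))

  got3 <- reconstruct_contingency(
    686, c(support = 0.0058, confidence = 0.80, lift = 49.9, conviction = 4.9),
    digits = c(support = 4, confidence = 2, lift = 1, conviction = 1))
  expect_length(got3, 1)
  expect_identical(unlist(got3[[1]][c("a", "b", "c", "d")]),
                   c(a = 4L, b = 1L, c = 7L, d = 674L))

  # gender-consequent rows need the cohort's per-gender total to be unique
  got4 <- reconstruct_contingency(
    4377, c(support = 0.012, confidence = 0.81, lift = 1.39, conviction = 2.21),
    digits = c(support = 3, confidence = 2, lift = 2, conviction = 2),
    y_total = 2562)
  expect_length(got4, 1)
  expect_identical(unlist(got4[[1]][c("a", "b", "c", "d")]),
                   c(a = 52L, b = 12L, c = 2510L, d = 1803L))

  got5 <- reconstruct_contingency(
    686, c(support = 0.035, confidence = 0.89, lift = 1.56, conviction = 3.86),
    digits = c(support = 3, confidence = 2, lift = 2, conviction = 2),
    y_total = 392)
  expect_length(got5, 1)
  expect_identical(unlist(got5[[1]][c("a", "b", "c", "d")]),
                   c(a = 24L, b = 3L, c = 368L, d = 291L))

  got6 <- reconstruct_contingency(
    935, c(support = 0.02, confidence = 0.87, lift = 1.60, conviction = 3.49),
    digits = c(support = 2, confidence = 2, lift = 2, conviction = 2),
    y_total = 509)
  expect_length(got6, 1)
  expect_identical(unlist(got6[[1]][c("a", "b", "c", "d")]),
                   c(a = 20L, b = 3L, c = 489L, d = 423L))
})
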