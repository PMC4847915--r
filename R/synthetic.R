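#' Specification for the synthetic JADER-like generator
#'
#' Describes a spontaneous-report population with known ground truth:
#' marginal demographics, a drug-class mixture, independent background
#' adverse-reaction rates, planted pairwise ADR associations, and
#' gender-conditional ADR rates. Every planted association has
#' closed-form rule statistics ([analytic_rule_statistics()]), so the
#' whole pipeline can be validated without any real download.
#'
#' Generation model, per case: gender ~ `gender_probs`; age decade ~
#' `age_decade_probs` (value `"unknown"` yields an empty age string); one
#' drug class ~ class probabilities, then one member drug uniformly,
#' recorded with causality "suspected". Each vocabulary term is added
#' independently with its background rate. For a planted pair (X, Y),
#' with probability `p_x` X is added; for those cases Y's presence is
#' drawn with probability `p_y_given_x` (this conditional draw replaces
#' Y's background draw, so `p_y_given_x` is the exact conditional rate —
#' in particular `p_y_given_x = 1` forces rule confidence 1 whenever X
#' has background rate 0, and `background(Y) = p_y_given_x` makes X and Y
#' exactly independent). A gender-effect term is likewise drawn with its
#' gender-conditional probability for female/male cases; gender-unknown
#' cases fall back to the term's background rate.
#'
#' @param n_cases Number of cases.
#' @param seed RNG seed; fixed seed gives byte-identical CSV output.
#' @param gender_probs Named probabilities `female`, `male`, `unknown`;
#'   must sum to 1.
#' @param age_decade_probs Named probabilities over raw age strings
#'   (e.g. `"20代"`) plus `"unknown"`; must sum to 1.
#' @param drug_classes Named list: class name -> list(`drugs` = member
#'   drug names, `prob` = class probability); probs must sum to 1.
#' @param adr_vocabulary Character vector of ADR preferred terms.
#' @param background_rate Named per-term marginal probability (terms
#'   absent from the vector default to 0).
#' @param planted_pairs `NULL` or data.frame with columns `x`, `y`,
#'   `p_x`, `p_y_given_x`; terms must be in the vocabulary and must not
#'   be reused across planted mechanisms.
#' @param planted_gender_effects `NULL` or data.frame with columns
#'   `term`, `p_female`, `p_male`.
#' @param encoding Output CSV encoding, `"UTF-8"` (default) or
#'   `"CP932"`.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_cases, seed = 1,
                           gender_probs = c(female = 0.58, male = 0.39, unknown = 0.03),
                           age_decade_probs = default_age_decade_probs(),
                           drug_classes = default_drug_classes(),
                           adr_vocabulary,
                           background_rate,
                           planted_pairs = NULL,
                           planted_gender_effects = NULL,
                           encoding = "UTF-8") {
  stopifnot(n_cases >= 0, n_cases == round(n_cases))
  chk_dist <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be non-negative and sum to 1")
  }
  chk_dist(gender_probs, "gender_probs")
  stopifnot(all(c("female", "male", "unknown") %in% names(gender_probs)))
  chk_dist(age_decade_probs, "age_decade_probs")
  class_probs <- vapply(drug_classes, function(cl) cl$prob, numeric(1))
  chk_dist(class_probs, "drug class probabilities")
  if (any(vapply(drug_classes, function(cl) length(cl$drugs) == 0L, logical(1))))
    stop("every drug class needs at least one member drug")
  stopifnot(length(adr_vocabulary) > 0, !anyDuplicated(adr_vocabulary))
  bg <- stats::setNames(rep(0, length(adr_vocabulary)), adr_vocabulary)
  if (!all(names(background_rate) %in% adr_vocabulary))
    stop("background_rate names outside adr_vocabulary: ",
         paste(setdiff(names(background_rate), adr_vocabulary), collapse = ", "))
  bg[names(background_rate)] <- background_rate
  if (any(bg < 0 | bg > 1)) stop("background rates must be in [0, 1]")
  planted_terms <- character(0)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("x", "y", "p_x", "p_y_given_x") %in% names(planted_pairs)))
    with(planted_pairs, stopifnot(all(p_x >= 0 & p_x <= 1),
                                  all(p_y_given_x >= 0 & p_y_given_x <= 1),
                                  all(x != y)))
    planted_terms <- c(planted_pairs$x, planted_pairs$y)
  }
  if (!is.null(planted_gender_effects)) {
    stopifnot(all(c("term", "p_female", "p_male") %in% names(planted_gender_effects)))
    with(planted_gender_effects,
         stopifnot(all(p_female >= 0 & p_female <= 1),
                   all(p_male >= 0 & p_male <= 1)))
    planted_terms <- c(planted_terms, planted_gender_effects$term)
  }
  if (!all(planted_terms %in% adr_vocabulary))
    stop("planted terms outside adr_vocabulary: ",
         paste(setdiff(planted_terms, adr_vocabulary), collapse = ", "))
  if (anyDuplicated(planted_terms))
    stop("a term may take part in only one planted mechanism")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 gender_probs = gender_probs,
                 age_decade_probs = age_decade_probs,
                 drug_classes = drug_classes,
                 adr_vocabulary = adr_vocabulary,
                 background_rate = bg,
                 planted_pairs = planted_pairs,
                 planted_gender_effects = planted_gender_effects,
                 encoding = encoding),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_age_decade_probs <- function() {
  c("10代" = 0.04, "20代" = 0.14, "30代" = 0.18, "40代" = 0.16,
    "50代" = 0.13, "60代" = 0.13, "70代" = 0.11, "80代" = 0.07,
    "90代" = 0.02, "unknown" = 0.02)
}

#' @rdname generator_spec
#' @export
default_drug_classes <- function() {
  list(SSRI = list(drugs = c("パロキセチン塩酸塩水和物", "セルトラリン塩酸塩",
                             "フルボキサミンマレイン酸塩",
                             "エスシタロプラムシュウ酸塩"), prob = 0.73),
       SNRI = list(drugs = c("デュロキセチン塩酸塩", "ミルナシプラン塩酸塩"),
                   prob = 0.16),
       NaSSA = list(drugs = c("ミルタザピン"), prob = 0.11))
}

#' Default synthetic study population
#'
#' A ready-made [generator_spec()] emulating an antidepressant cohort in a
#' spontaneous-report database: female-skewed gender mix, adult-heavy age
#' distribution, a 0.73/0.16/0.11 SSRI/SNRI/NaSSA class mixture, a
#' 22-term ADR vocabulary with background rates between 0.02 and 0.08,
#' two planted ADR pairs (one with conditional probability 1, so its rule
#' has confidence exactly 1 and conviction NA) and two gender-skewed
#' terms. Planted pair antecedents have background rate 0 so the planted
#' conditional is the rule confidence up to consequent contamination.
#'
#' @param n_cases Number of cases, default 5000.
#' @param seed RNG seed.
#' @return A `generator_spec`.
#' @export
default_generator_spec <- function(n_cases = 5000, seed = 1) {
  vocab <- c("Nausea", "Somnolence", "Dizziness", "Headache", "Vomiting",
             "Insomnia", "Serotonin syndrome", "Hyponatraemia",
             "Liver disorder", "Malaise", "Constipation", "Diarrhoea",
             "Weight increased", "Tremor", "Agitation", "Anxiety",
             "Aspartate aminotransferase increased",
             "Alanine aminotransferase increased",
             "International normalised ratio increased", "Drug interaction",
             "Suicidal ideation", "Rhabdomyolysis")
  bg <- c("Nausea" = 0.08, "Somnolence" = 0.06, "Dizziness" = 0.06,
          "Headache" = 0.05, "Vomiting" = 0.05, "Insomnia" = 0.05,
          "Serotonin syndrome" = 0.03, "Hyponatraemia" = 0.04,
          "Liver disorder" = 0.04, "Malaise" = 0.05, "Constipation" = 0.04,
          "Diarrhoea" = 0.04, "Weight increased" = 0.03, "Tremor" = 0.03,
          "Agitation" = 0.03, "Anxiety" = 0.04,
          "Aspartate aminotransferase increased" = 0,
          "Alanine aminotransferase increased" = 0.002,
          "International normalised ratio increased" = 0,
          "Drug interaction" = 0.002,
          "Suicidal ideation" = 0.002, "Rhabdomyolysis" = 0.001)
  pairs <- data.frame(
    x = c("Aspartate aminotransferase increased",
          "International normalised ratio increased"),
    y = c("Alanine aminotransferase increased", "Drug interaction"),
    p_x = c(0.02, 0.008),
    p_y_given_x = c(0.95, 1.0),
    stringsAsFactors = FALSE)
  gender_fx <- data.frame(
    term = c("Suicidal ideation", "Rhabdomyolysis"),
    p_female = c(0.06, 0.002),
    p_male = c(0.01, 0.035),
    stringsAsFactors = FALSE)
  generator_spec(n_cases = n_cases, seed = seed,
                 adr_vocabulary = vocab, background_rate = bg,
                 planted_pairs = pairs, planted_gender_effects = gender_fx)
}

#' Generate synthetic DEMO/DRUG/REAC tables with ground truth
#'
#' Samples a case population from a [generator_spec()] and returns the
#' three relational tables plus a ground-truth manifest. Output is fully
#' reproducible: a fixed seed yields byte-identical CSV files.
#'
#' @param spec A [generator_spec()].
#' @param out_dir Optional directory; when given, `demo.csv`, `drug.csv`
#'   and `reac.csv` are written there in the spec's encoding.
#' @return List with data.frames `demo`, `drug`, `reac`, the `manifest`
#'   (list: per-case data frame `cases` with list column `adr_terms`,
#'   `class_sizes`, and `planted` — analytic statistics per planted
#'   rule), and `paths` when files were written.
#' @export
generate_jader <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_cases
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  gp <- spec$gender_probs
  gender <- if (n) sample(names(gp), n, replace = TRUE, prob = gp) else character(0)
  ap <- spec$age_decade_probs
  age_raw <- if (n) sample(names(ap), n, replace = TRUE, prob = ap) else character(0)
  age_raw[age_raw == "unknown"] <- ""
  cls_names <- names(spec$drug_classes)
  cls_probs <- vapply(spec$drug_classes, function(cl) cl$prob, numeric(1))
  cls <- if (n) sample(cls_names, n, replace = TRUE, prob = cls_probs) else character(0)
  drug <- vapply(cls, function(cl) {
    ds <- spec$drug_classes[[cl]]$drugs
    if (length(ds) == 1L) ds else sample(ds, 1L)
  }, character(1), USE.NAMES = FALSE)

  vocab <- spec$adr_vocabulary
  has <- matrix(FALSE, nrow = max(n, 0L), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  if (n) {
    for (term in vocab)
      has[, term] <- stats::runif(n) < spec$background_rate[[term]]
    if (!is.null(spec$planted_pairs)) {
      for (r in seq_len(nrow(spec$planted_pairs))) {
        p <- spec$planted_pairs[r, ]
        px <- stats::runif(n) < p$p_x
        has[, p$x] <- has[, p$x] | px
        # conditional draw replaces the background draw where X is planted
        has[, p$y] <- ifelse(px, stats::runif(n) < p$p_y_given_x, has[, p$y])
      }
    }
    if (!is.null(spec$planted_gender_effects)) {
      for (r in seq_len(nrow(spec$planted_gender_effects))) {
        p <- spec$planted_gender_effects[r, ]
        known <- gender %in% c("female", "male")
        rate <- ifelse(gender == "female", p$p_female, p$p_male)
        has[, p$term] <- ifelse(known, stats::runif(n) < rate, has[, p$term])
      }
    }
  }

  case_id <- sprintf("C%07d", seq_len(n))
  demo <- data.frame(case_id = case_id,
                     gender = ifelse(gender == "unknown", "", gender),
                     age = age_raw, weight = rep("", n),
                     stringsAsFactors = FALSE)
  drug_tbl <- data.frame(case_id = case_id, drug_name = drug,
                         causality = rep("suspected", n),
                         stringsAsFactors = FALSE)
  adr_sets <- lapply(seq_len(n), function(i)
    sort(vocab[has[i, ]], method = "radix"))
  n_adr <- lengths(adr_sets)
  reac <- data.frame(case_id = rep(case_id, n_adr),
                     adr_term = unlist(adr_sets, use.names = FALSE) %||% character(0),
                     outcome = rep("", sum(n_adr)),
                     stringsAsFactors = FALSE)

  planted <- list()
  if (!is.null(spec$planted_pairs))
    for (r in seq_len(nrow(spec$planted_pairs)))
      planted[[length(planted) + 1L]] <- c(
        list(x = spec$planted_pairs$x[r], y = spec$planted_pairs$y[r],
             kind = "adr_pair"),
        unclass(analytic_rule_statistics(spec, spec$planted_pairs$x[r],
                                         spec$planted_pairs$y[r]))[1:4])
  if (!is.null(spec$planted_gender_effects))
    for (r in seq_len(nrow(spec$planted_gender_effects)))
      for (g in c("female", "male"))
        planted[[length(planted) + 1L]] <- c(
          list(x = spec$planted_gender_effects$term[r], y = g,
               kind = "gender_effect"),
          unclass(analytic_rule_statistics(
            spec, spec$planted_gender_effects$term[r], g))[1:4])

  cases <- data.frame(case_id = case_id, gender = gender, age_raw = age_raw,
                      class = cls, drug = drug, n_adr = n_adr,
                      stringsAsFactors = FALSE)
  cases$adr_terms <- adr_sets
  manifest <- list(cases = cases,
                   class_sizes = table(factor(cls, levels = cls_names)),
                   planted = planted)

  out <- list(demo = demo, drug = drug_tbl, reac = reac, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, c("demo.csv", "drug.csv", "reac.csv"))
    write_csv_det(demo, paths[1], spec$encoding)
    write_csv_det(drug_tbl, paths[2], spec$encoding)
    write_csv_det(reac, paths[3], spec$encoding)
    out$paths <- stats::setNames(paths, c("demo", "drug", "reac"))
  }
  out
}

# deterministic CSV writer: fixed eol, quoting and encoding
write_csv_det <- function(df, path, encoding = "UTF-8") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(x) {
    q <- grepl('[",\n]', x)
    x[q] <- paste0('"', gsub('"', '""', x[q]), '"')
    x
  }
  lines <- c(paste(esc(names(df)), collapse = ","),
             if (nrow(df)) do.call(paste, c(lapply(df, esc), sep = ",")))
  writeLines(iconv(lines, from = "UTF-8", to = encoding), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Closed-form statistics of a planted rule
#'
#' Under the generating model, every planted association has analytic
#' support, confidence, lift and conviction, accounting for background
#' contamination of both terms' marginals. For a planted pair (X, Y):
#' P(X) = 1 - (1 - p_x)(1 - bg_X),
#' P(Y) = p_x p_y_given_x + (1 - p_x) bg_Y, and
#' P(X and Y) = p_x p_y_given_x + (1 - p_x) bg_X bg_Y.
#' For a gender effect Z with conditional rates by gender, the consequent
#' marginal is the gender probability itself (gender-unknown cases count
#' in t with no gender item) and
#' P(Z) = P(f) p_female + P(m) p_male + P(u) bg_Z.
#'
#' @param spec A [generator_spec()].
#' @param x Antecedent: a planted pair's X term, or a gender-effect term.
#' @param y Consequent: the pair's Y term, or `"female"`/`"male"`.
#' @return A `rule_stats` object (conviction `NA` when confidence is 1).
#' @export
analytic_rule_statistics <- function(spec, x, y) {
  stopifnot(inherits(spec, "generator_spec"))
  bg <- spec$background_rate
  pp <- spec$planted_pairs
  ge <- spec$planted_gender_effects
  if (!is.null(pp) && any(pp$x == x & pp$y == y)) {
    r <- pp[pp$x == x & pp$y == y, ]
    bx <- bg[[x]]; by <- bg[[y]]
    p_x <- 1 - (1 - r$p_x) * (1 - bx)
    p_y <- r$p_x * r$p_y_given_x + (1 - r$p_x) * by
    # planted X: Y by conditional draw; unplanted: both via background
    p_xy <- r$p_x * r$p_y_given_x + (1 - r$p_x) * bx * by
  } else if (!is.null(ge) && x %in% ge$term && y %in% c("female", "male")) {
    r <- ge[ge$term == x, ]
    bz <- bg[[x]]
    gp <- spec$gender_probs
    p_y <- gp[[y]]
    p_x <- gp[["female"]] * r$p_female + gp[["male"]] * r$p_male +
      gp[["unknown"]] * bz
    p_xy <- p_y * (if (y == "female") r$p_female else r$p_male)
  } else {
    stop("rule (", x, " -> ", y, ") is not planted in this spec")
  }
  if (p_x <= 0) stop("antecedent has probability 0 under this spec")
  conf <- p_xy / p_x
  structure(list(support = p_xy, confidence = conf, lift = conf / p_y,
                 conviction = if (conf >= 1) NA_real_ else (1 - p_y) / (1 - conf),
                 conviction_formula = "standard"),
            class = "rule_stats")
}
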