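# Seeded generator of multi-quarter raw SRS series.
#
# The generator emulates the structural features that periodical SRS
# publishing exposes: follow-up CaseIDs whose life span may be gapped
# (present, absent, present again), heavily skewed symptom frequencies,
# multivalued sensitive sets, and demographic-conditioned drug-reaction
# associations planted at a known lift.

#' Configuration for the synthetic SRS series generator
#'
#' @param n_quarters number of quarters to generate.
#' @param cases_per_quarter number of *new* CaseIDs per quarter (follow-up
#'   records of earlier cases come on top).
#' @param followup_prob per quarter, the chance that a still-open case files
#'   a follow-up record.
#' @param lifespan_max maximum number of quarters a case stays open after
#'   its first report (each case draws its own span uniformly).
#' @param gap_prob chance that a due follow-up skips the quarter and
#'   reappears later, creating the "present, absent, present" patterns that
#'   distinguish periodical from continuous publishing.
#' @param n_symptoms size of the symptom vocabulary.
#' @param zipf_exponent exponent of the Zipf law for symptom frequencies
#'   (larger = more skewed).
#' @param extra_symptom_rate Poisson mean of symptoms per case beyond the
#'   mandatory first.
#' @param n_drugs size of the drug vocabulary.
#' @param second_drug_prob chance of a second suspect drug on a report.
#' @param dup_prob chance that a new case files a second report within its
#'   first quarter (same person, possibly one extra symptom) — exercising
#'   super-record merging.
#' @param age_range,prop_female,weight_mean,weight_sd demographic model:
#'   ages uniform over `age_range` (years), sex female with probability
#'   `prop_female`, weight normal (kg), truncated to the schema range.
#' @param planted_rules list of planted associations; each element is a
#'   list with `drug`, `reaction`, `attribute`, `op`, `value` (the
#'   demographic condition), `lift` (multiplier on the baseline reaction
#'   rate among exposed), `exposure` (drug probability in the condition
#'   subpopulation) and `base_rate` (baseline reaction probability).
#' @param seed integer seed; the whole series is a deterministic function
#'   of the configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_quarters = 6, cases_per_quarter = 2000,
                         followup_prob = 0.3, lifespan_max = 4,
                         gap_prob = 0.25, n_symptoms = 200,
                         zipf_exponent = 1.2, extra_symptom_rate = 0.3,
                         n_drugs = 30, second_drug_prob = 0.3,
                         dup_prob = 0.05, age_range = c(18, 90),
                         prop_female = 0.55, weight_mean = 75,
                         weight_sd = 15,
                         planted_rules = default_planted_rules(),
                         seed = 1L) {
  stopifnot(n_quarters >= 1, cases_per_quarter >= 1, lifespan_max >= 1,
            followup_prob >= 0, followup_prob <= 1,
            gap_prob >= 0, gap_prob <= 1, n_symptoms >= 1,
            zipf_exponent > 0, extra_symptom_rate >= 0,
            age_range[1] < age_range[2])
  structure(as.list(environment()), class = "synth_config")
}

#' @rdname synth_config
#' @export
default_planted_rules <- function() {
  list(list(drug = "D01", reaction = "MyocardialInfarction",
            attribute = "Age", op = ">", value = 60,
            lift = 25, exposure = 0.2, base_rate = 0.01))
}

#' @rdname synth_config
#' @export
synth_schema <- function(config = synth_config()) {
  srs_schema(attr_categorical("Sex", sex_taxonomy()),
             attr_numeric("Age", 0, 100),
             attr_numeric("Weight", 30, 150))
}

#' Generate a synthetic multi-quarter SRS series
#'
#' Each quarter mixes newly reported cases with follow-up records of cases
#' still inside their life span; a follow-up keeps the person's leaf QID,
#' drugs and symptoms (only the *published* generalizations will differ
#' across releases — exactly the divergence the BFL attacks exploit).
#' Symptom draws follow a Zipf law; each planted rule inflates the joint
#' (drug, reaction) frequency within its demographic subpopulation by the
#' configured lift.
#'
#' @param config a [synth_config].
#' @return List of class `synth_series`: `schema`, `quarters` (raw data
#'   frames `D_1..D_n` with columns `case_id`, `quarter`, `Sex`, `Age`,
#'   `Weight`, `drugs`, `sensitive`), and `config`.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  schema <- synth_schema(cf)
  symptoms <- sprintf("S%03d", seq_len(cf$n_symptoms))
  sym_p <- seq_len(cf$n_symptoms)^(-cf$zipf_exponent)
  sym_p <- sym_p / sum(sym_p)
  drugs <- sprintf("D%02d", seq_len(cf$n_drugs))
  drug_p <- seq_len(cf$n_drugs)^(-1)
  drug_p <- drug_p / sum(drug_p)

  registry <- NULL   # open cases: one row per case with its fixed content
  quarters <- vector("list", cf$n_quarters)
  next_id <- 1L
  for (q in seq_len(cf$n_quarters)) {
    n_new <- cf$cases_per_quarter
    ids <- seq.int(next_id, length.out = n_new)
    next_id <- next_id + n_new
    sex <- ifelse(stats::runif(n_new) < cf$prop_female, "Female", "Male")
    age <- sample(cf$age_range[1]:cf$age_range[2], n_new, replace = TRUE)
    weight <- round(pmin(pmax(stats::rnorm(n_new, cf$weight_mean,
                                           cf$weight_sd), 35), 145), 1)
    n_sym <- 1L + stats::rpois(n_new, cf$extra_symptom_rate)
    sens <- lapply(seq_len(n_new), function(i)
      sample(symptoms, min(n_sym[i], cf$n_symptoms), prob = sym_p))
    n_drug <- 1L + stats::rbinom(n_new, 1L, cf$second_drug_prob)
    drg <- lapply(seq_len(n_new), function(i)
      sample(drugs, n_drug[i], prob = drug_p))

    # planted demographic-conditioned associations
    for (rule in cf$planted_rules) {
      in_cond <- eval_leaf_condition(rule, sex, age, weight)
      exposed <- in_cond & (stats::runif(n_new) < rule$exposure |
                            vapply(drg, function(x) rule$drug %in% x, TRUE))
      drg[exposed] <- lapply(drg[exposed], function(x)
        unique(c(x, rule$drug)))
      p_reac <- ifelse(exposed, pmin(rule$base_rate * rule$lift, 0.95),
                       rule$base_rate)
      hit <- in_cond & stats::runif(n_new) < p_reac
      sens[hit] <- lapply(sens[hit], function(x)
        unique(c(x, rule$reaction)))
    }

    new_rows <- data.frame(
      case_id = ids, quarter = q, Sex = sex, Age = age, Weight = weight,
      drugs = join_terms(drg), sensitive = join_terms(sens),
      stringsAsFactors = FALSE)

    # within-quarter duplicate reports of some new cases
    dup <- which(stats::runif(n_new) < cf$dup_prob)
    if (length(dup)) {
      dup_rows <- new_rows[dup, , drop = FALSE]
      extra <- sample(symptoms, length(dup), prob = sym_p, replace = TRUE)
      dup_rows$sensitive <- vapply(seq_along(dup), function(i)
        paste(unique(c(split_terms(dup_rows$sensitive[i])[[1]], extra[i])),
              collapse = ";"), "")
      new_rows <- rbind(new_rows, dup_rows)
    }

    # follow-ups of open cases (same person: identical leaf QID and content)
    fu_rows <- NULL
    if (!is.null(registry) && nrow(registry)) {
      open <- registry$birth_q < q & q <= registry$birth_q + registry$span
      due <- open & stats::runif(nrow(registry)) < cf$followup_prob
      due <- due & stats::runif(nrow(registry)) >= cf$gap_prob
      if (any(due)) {
        fu_rows <- registry[due, c("case_id", "Sex", "Age", "Weight",
                                   "drugs", "sensitive")]
        fu_rows <- cbind(fu_rows[, "case_id", drop = FALSE], quarter = q,
                         fu_rows[, -1, drop = FALSE])
      }
    }

    quarter_df <- rbind(new_rows, fu_rows)
    quarter_df <- quarter_df[order(quarter_df$case_id), , drop = FALSE]
    rownames(quarter_df) <- NULL
    quarters[[q]] <- quarter_df

    registry <- rbind(registry, data.frame(
      case_id = ids, birth_q = q,
      span = sample.int(cf$lifespan_max, n_new, replace = TRUE),
      Sex = sex, Age = age, Weight = weight,
      drugs = join_terms(drg), sensitive = join_terms(sens),
      stringsAsFactors = FALSE))
  }
  structure(list(schema = schema, quarters = quarters, config = cf),
            class = "synth_series")
}

#' @export
print.synth_series <- function(x, ...) {
  cat("Synthetic SRS series: ", length(x$quarters), " quarters, ",
      sum(vapply(x$quarters, nrow, 0L)), " records\n", sep = "")
  invisible(x)
}

eval_leaf_condition <- function(rule, sex, age, weight) {
  v <- switch(rule$attribute, Sex = sex, Age = age, Weight = weight,
              stop("unknown condition attribute: ", rule$attribute))
  if (rule$attribute == "Sex") {
    if (rule$op != "==") stop("categorical conditions support '==' only")
    return(v == rule$value)
  }
  val <- as.numeric(rule$value)
  switch(rule$op, ">" = v > val, ">=" = v >= val, "<" = v < val,
         "<=" = v <= val, "==" = v == val)
}
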