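# Composition of smoothed annual transition probabilities into interval,
# remaining-lifetime, treated, and marginal (any-path) absolute risks.
#
# Two projection modes:
#   * fixed-path: Interval Risk = 1 - prod_a (1 - pi_a), the probability of
#     making the j -> k transition while remaining in j until it happens;
#   * marginal: the (j, k) entry of the ordered product of annual
#     transition matrices, which accumulates probability through any path.
# Treatment is a constant per-year relative risk reduction RR applied to
# every annual target-state probability: pi -> (1 - RR) * pi.

#' Covariate profile
#'
#' @param sex,prs,smoker,statin_use,antihtn_use Covariate values: sex and
#'   the binary flags in \{0, 1\}, `prs` in standard-deviation units.
#' @return Named list.
#' @export
risk_profile <- function(sex = 0, prs = 0, smoker = 0, statin_use = 0,
                         antihtn_use = 0) {
  list(sex = sex, prs = prs, smoker = smoker, statin_use = statin_use,
       antihtn_use = antihtn_use)
}

#' Risk query
#'
#' @param profile Covariate profile from [risk_profile()].
#' @param start_state,target_state State labels (target defaults to CAD).
#' @param start_age,end_age Half-open age window `[start_age, end_age)`;
#'   lifetime queries use `end_age = L` (default 80).
#' @param treated Apply the treatment relative risk reduction?
#' @param treatment_rr Per-year relative risk reduction in `[0, 1]`
#'   (default 0.20, the trial-imputed statin effect).
#' @param mode `"fixed-path"` or `"marginal"`.
#' @return List of class `risk_query`.
#' @export
risk_query <- function(profile = risk_profile(), start_state = "Health",
                       start_age = 40, end_age = 80,
                       target_state = "CAD", treated = FALSE,
                       treatment_rr = 0.20, mode = "fixed-path") {
  .check_state(start_state, "start_state")
  .check_state(target_state, "target_state")
  stopifnot(start_age < end_age, treatment_rr >= 0, treatment_rr <= 1)
  mode <- match.arg(mode, c("fixed-path", "marginal"))
  structure(list(profile = profile, start_state = start_state,
                 start_age = start_age, end_age = end_age,
                 target_state = target_state, treated = treated,
                 treatment_rr = treatment_rr, mode = mode),
            class = "risk_query")
}

# smoothed-beta matrix (ages x terms) for one transition; NULL if absent
.beta_matrix <- function(tab, from, to) {
  sub <- tab[tab$from_state == from & tab$to_state == to, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  terms <- .term_names(attr(tab, "covariates"))
  ages <- sort(unique(sub$age))
  B <- matrix(NA_real_, length(ages), length(terms),
              dimnames = list(ages, terms))
  B[cbind(match(sub$age, ages), match(sub$term, terms))] <- sub$beta
  B
}

.profile_vector <- function(tab, profile) {
  terms <- .term_names(attr(tab, "covariates"))
  x <- stats::setNames(numeric(length(terms)), terms)
  x["intercept"] <- 1
  for (nm in setdiff(terms, "intercept")) x[nm] <- as.numeric(profile[[nm]])
  x
}

# annual probability series for one transition over given ages (0 where
# the transition is unavailable in the table)
.pi_series <- function(tab, profile, from, to, ages, warn = TRUE) {
  B <- .beta_matrix(tab, from, to)
  if (is.null(B)) {
    if (warn) {
      warning(sprintf("transition %s -> %s unavailable; probability set to 0",
                      from, to), call. = FALSE)
    }
    return(stats::setNames(rep(0, length(ages)), ages))
  }
  x <- .profile_vector(tab, profile)
  have <- intersect(as.character(ages), rownames(B))
  if (length(have) < length(ages)) {
    stop(sprintf("smoothed table does not cover ages %s for %s -> %s",
                 paste(setdiff(as.character(ages), have), collapse = ","),
                 from, to), call. = FALSE)
  }
  pi <- stats::plogis(as.vector(B[as.character(ages), , drop = FALSE] %*% x))
  stats::setNames(pi, ages)
}

#' Annual transition probability row
#'
#' Probabilities over the successor states of `from_state` at one age for
#' one profile: off-diagonal entries via the smoothed logistic
#' coefficients, self entry by complement.  If the fitted destinations sum
#' above 1 they are rescaled to sum 1 with the self entry set to 0 (with a
#' warning).  Unavailable transitions contribute probability 0.
#'
#' @param tab Smoothed `coef_table`.
#' @param profile [risk_profile()].
#' @param from_state State label (non-absorbing).
#' @param age Integer age covered by the table.
#' @param warn Warn about unavailable transitions (default `TRUE`;
#'   internal callers silence repeats).
#' @return Named probability vector over `successor_states(from_state)`,
#'   summing to 1.
#' @export
annual_transition_row <- function(tab, profile, from_state, age,
                                  warn = TRUE) {
  .check_state(from_state, "from_state")
  if (from_state == "Death") stop("Death has no successors")
  succ <- successor_states(from_state)
  dest <- setdiff(succ, from_state)
  p <- vapply(dest, function(to)
    unname(.pi_series(tab, profile, from_state, to, age, warn = warn)),
    numeric(1))
  s <- sum(p)
  if (s > 1) {
    warning(sprintf("destination probabilities from %s at age %s sum to %.4f; rescaled",
                    from_state, age, s), call. = FALSE)
    p <- p / s
    s <- 1
  }
  out <- stats::setNames(numeric(length(succ)), succ)
  out[dest] <- p
  out[from_state] <- 1 - s
  out
}

#' Interval risk from a per-age probability sequence
#'
#' `1 - prod(1 - pi_a)`; 0 for an empty interval.
#'
#' @param pis Annual probabilities in `[0, 1]`.
#' @return Probability.
#' @export
interval_risk <- function(pis) {
  stopifnot(all(pis >= 0 & pis <= 1))
  if (length(pis) == 0) return(0)
  1 - prod(1 - pis)
}

#' Absolute risk for a query
#'
#' Fixed-path mode composes the start -> target annual probabilities over
#' `[start_age, end_age)` with `1 - prod(1 - pi)` (treated queries first
#' scale each annual target probability by `1 - RR`).  Marginal mode uses
#' the ordered product of annual transition matrices and so accumulates
#' probability through every path; it requires an absorbing-side target
#' (CAD or Death).
#'
#' @param tab Smoothed `coef_table`.
#' @param query [risk_query()].
#' @return List of class `risk_result`: `risk`, `per_age_probs`,
#'   `query`.
#' @export
project_risk <- function(tab, query) {
  stopifnot(inherits(query, "risk_query"))
  if (query$treated) {
    if (isTRUE(as.numeric(query$profile$statin_use) == 1)) {
      stop("treated projection requested for a profile already on statins; ",
           "the imputed benefit applies only to statin-free individuals",
           call. = FALSE)
    }
  }
  if (state_absorbing(query$start_state)) {
    stop("risk query from an absorbing start state is not defined")
  }
  if (query$start_state == "CAD" && query$target_state == "CAD") {
    return(structure(list(risk = 1, per_age_probs = numeric(0),
                          query = query), class = "risk_result"))
  }
  ages <- seq.int(query$start_age, query$end_age - 1L)
  rr <- if (query$treated) query$treatment_rr else 0
  if (query$mode == "fixed-path") {
    pis <- .pi_series(tab, query$profile, query$start_state,
                      query$target_state, ages)
    pis <- (1 - rr) * pis
    risk <- interval_risk(pis)
  } else {
    if (!query$target_state %in% c("CAD", "Death")) {
      stop("marginal mode requires an absorbing target (CAD or Death)")
    }
    P <- diag(length(ms_states()))
    dimnames(P) <- list(ms_states(), ms_states())
    pis <- stats::setNames(numeric(length(ages)), ages)
    for (a in ages) {
      Tm <- build_transition_matrix(tab, query$profile, a,
                                    treatment_rr = rr,
                                    target_state = query$target_state,
                                    warn = identical(a, ages[1]))
      P <- P %*% Tm
      pis[as.character(a)] <- P[query$start_state, query$target_state]
    }
    risk <- P[query$start_state, query$target_state]
  }
  structure(list(risk = unname(risk), per_age_probs = pis, query = query),
            class = "risk_result")
}

#' Remaining lifetime risk
#'
#' Fixed-path interval risk from `start_age` to the maximum age of life
#' `L` (default 80).
#'
#' @inheritParams project_risk
#' @param L Maximum age of life.
#' @return `risk_result`.
#' @export
remaining_lifetime_risk <- function(tab, query, L = 80) {
  query$end_age <- L
  project_risk(tab, query)
}

#' Treated interval risk
#'
#' The query's annual target probabilities are each multiplied by
#' `1 - RR` before composition.  Rejected for profiles already on statins.
#'
#' @inheritParams project_risk
#' @return `risk_result`.
#' @export
treated_interval_risk <- function(tab, query) {
  query$treated <- TRUE
  project_risk(tab, query)
}

#' Absolute risk reduction from treatment
#'
#' Untreated minus treated risk for the same query; nonnegative for
#' `RR` in `[0, 1]`.
#'
#' @inheritParams project_risk
#' @return Probability difference.
#' @export
absolute_risk_reduction <- function(tab, query) {
  query$treated <- FALSE
  untreated <- project_risk(tab, query)$risk
  query$treated <- TRUE
  treated <- project_risk(tab, query)$risk
  untreated - treated
}

#' Annual transition matrix
#'
#' Row-stochastic matrix over the ten states for one profile and age:
#' non-absorbing rows from [annual_transition_row()], the Death row a unit
#' vector.  An optional treatment effect scales the target-state column
#' probabilities of non-target rows by `1 - RR` before the self-entry
#' complement is taken.
#'
#' @inheritParams annual_transition_row
#' @param treatment_rr Per-year relative risk reduction applied to
#'   `target_state` entries (0 = untreated).
#' @param target_state Target of the treatment effect (default CAD).
#' @param warn Warn about unavailable transitions.
#' @return 10 x 10 named matrix with unit row sums.
#' @export
build_transition_matrix <- function(tab, profile, age, treatment_rr = 0,
                                    target_state = "CAD", warn = TRUE) {
  states <- ms_states()
  Tm <- matrix(0, length(states), length(states),
               dimnames = list(states, states))
  Tm["Death", "Death"] <- 1
  for (from in setdiff(states, "Death")) {
    row <- annual_transition_row(tab, profile, from, age, warn = warn)
    if (treatment_rr > 0 && target_state %in% names(row) &&
        from != target_state) {
      removed <- treatment_rr * row[target_state]
      row[target_state] <- row[target_state] - removed
      row[from] <- row[from] + removed
    }
    Tm[from, names(row)] <- row
  }
  Tm
}

#' Bootstrap standard error of a projection
#'
#' Resamples persons (not person-years) with replacement, refits,
#' resmooths and reprojects per replicate, and reports the mean and
#' standard error of the projected risk across replicates.  Replicates in
#' which a transition needed by the query cannot be fitted at any age are
#' recorded as missing.
#'
#' @param records Person-record `data.frame` (training data).
#' @param query [risk_query()].
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed RNG seed; the same seed reproduces the result exactly.
#' @param age_range,covariates,config Passed to [fit_all()] /
#'   [smooth_table()].
#' @return `risk_result` with `risk` (point estimate on the full data),
#'   `boot_mean`, `se`, `n_boot`, `n_valid`.
#' @export
bootstrap_projection <- function(records, query, n_boot = 1000, seed = 1,
                                 age_range = c(40, 80),
                                 covariates = default_covariates(),
                                 config = smoother_config()) {
  stopifnot(n_boot >= 2)
  records <- person_records(records)
  fit_project <- function(recs) {
    py <- expand_person_years(recs, age_range[1], age_range[2])
    raw <- fit_all(py, age_range, covariates)
    sub <- raw[raw$from_state == query$start_state &
                 raw$to_state == query$target_state, ]
    if (query$mode == "fixed-path" && all(!is.finite(sub$se))) return(NA_real_)
    sm <- suppressWarnings(smooth_table(raw, config))
    tryCatch(suppressWarnings(project_risk(sm, query)$risk),
             error = function(e) NA_real_)
  }
  point <- fit_project(records)
  set.seed(seed)
  idx <- matrix(sample.int(nrow(records), nrow(records) * n_boot,
                           replace = TRUE), nrow = n_boot)
  reps <- vapply(seq_len(n_boot), function(b) {
    recs <- records[idx[b, ], , drop = FALSE]
    recs$person_id <- paste0(recs$person_id, "_b", seq_len(nrow(recs)))
    fit_project(recs)
  }, numeric(1))
  valid <- reps[!is.na(reps)]
  structure(list(risk = point, boot_mean = mean(valid),
                 se = stats::sd(valid), n_boot = n_boot,
                 n_valid = length(valid), query = query),
            class = "risk_result")
}
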