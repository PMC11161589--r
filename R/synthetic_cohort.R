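# Synthetic longitudinal cohort with known ground-truth age-varying
# transition models.
#
# Each person's trajectory is simulated year by year: the successor state
# is a categorical draw from the ground-truth annual transition row for
# their current state, age and covariates, honouring the restricted
# topology, the absorbing states, censoring, and medication initiation.
# The generator's defaults emulate the published cohort structure:
# staggered entry in early adulthood (median first EHR observation ~24
# years), ~30 years of follow-up, risk-factor accrual rates giving ~40%
# lifetime hypertension / ~24% hyperlipidemia / ~10% diabetes, and CAD and
# death as competing absorbing outcomes.

#' Ground-truth coefficient set
#'
#' Named list mapping `"from|to"` transition keys to either a constant
#' named coefficient vector (terms `intercept, sex, prs, smoker,
#' statin_use, antihtn_use`) or a `function(age)` returning one.  The
#' default is age-constant, with modest covariate effects on the CAD and
#' death destinations.
#'
#' @param covariate_effects Include nonzero sex/prs/smoker/statin effects
#'   on CAD and death transitions?  `FALSE` gives an intercept-only truth.
#' @return Named list of coefficient vectors.
#' @export
default_truth <- function(covariate_effects = TRUE) {
  base <- c(intercept = 0, sex = 0, prs = 0, smoker = 0,
            statin_use = 0, antihtn_use = 0)
  mk <- function(p, sex = 0, prs = 0, smoker = 0, statin = 0) {
    b <- base
    b["intercept"] <- stats::qlogis(p)
    if (covariate_effects) {
      b["sex"] <- sex; b["prs"] <- prs; b["smoker"] <- smoker
      b["statin_use"] <- statin
    }
    b
  }
  # annual baseline probabilities; CAD/death destinations carry covariate
  # effects (male sex, standardized PRS, smoking raise risk; statins lower)
  list(
    "Health|Ht"                     = mk(0.012),
    "Health|HyperLip"               = mk(0.008),
    "Health|Dm"                     = mk(0.003),
    "Health|CAD"                    = mk(0.002, 0.5, 0.3, 0.4, -0.2),
    "Health|Death"                  = mk(0.003, 0.3, 0, 0.5),
    "Ht|Ht&HyperLip"                = mk(0.012),
    "Ht|Ht&Dm"                      = mk(0.005),
    "Ht|CAD"                        = mk(0.004, 0.5, 0.3, 0.4, -0.2),
    "Ht|Death"                      = mk(0.004, 0.3, 0, 0.5),
    "HyperLip|Ht&HyperLip"          = mk(0.014),
    "HyperLip|Dm&HyperLip"          = mk(0.004),
    "HyperLip|CAD"                  = mk(0.004, 0.5, 0.3, 0.4, -0.2),
    "HyperLip|Death"                = mk(0.003, 0.3, 0, 0.5),
    "Dm|Ht&Dm"                      = mk(0.014),
    "Dm|Dm&HyperLip"                = mk(0.010),
    "Dm|CAD"                        = mk(0.005, 0.5, 0.3, 0.4, -0.2),
    "Dm|Death"                      = mk(0.005, 0.3, 0, 0.5),
    "Ht&HyperLip|Ht&HyperLip&Dm"    = mk(0.008),
    "Ht&HyperLip|CAD"               = mk(0.008, 0.5, 0.3, 0.4, -0.2),
    "Ht&HyperLip|Death"             = mk(0.005, 0.3, 0, 0.5),
    "Ht&Dm|Ht&HyperLip&Dm"          = mk(0.010),
    "Ht&Dm|CAD"                     = mk(0.009, 0.5, 0.3, 0.4, -0.2),
    "Ht&Dm|Death"                   = mk(0.006, 0.3, 0, 0.5),
    "Dm&HyperLip|Ht&HyperLip&Dm"    = mk(0.012),
    "Dm&HyperLip|CAD"               = mk(0.009, 0.5, 0.3, 0.4, -0.2),
    "Dm&HyperLip|Death"             = mk(0.005, 0.3, 0, 0.5),
    "Ht&HyperLip&Dm|CAD"            = mk(0.015, 0.5, 0.3, 0.4, -0.2),
    "Ht&HyperLip&Dm|Death"          = mk(0.007, 0.3, 0, 0.5),
    "CAD|Death"                     = mk(0.020, 0.3)
  )
}

#' Generator configuration
#'
#' @param n_persons Cohort size.
#' @param seed RNG seed; a fixed seed gives a bit-identical cohort.
#' @param coefs Ground-truth coefficient set (see [default_truth()]).
#' @param entry_rate Rate of the exponential entry-age offset above
#'   `entry_min` (default gives median first observation ~24.3 years).
#' @param entry_min Minimum entry age.
#' @param followup_mean,followup_sd Normal follow-up duration, years.
#' @param smoker_prob,sex_prob Bernoulli covariate probabilities.
#' @param statin_hazard,antihtn_hazard Annual medication-initiation
#'   probabilities from age 40.
#' @param L Maximum age of life (trajectories stop at `L`).
#' @param same_year_dx_prob Probability of injecting a same-year double
#'   diagnosis (level-skipping year) to exercise the skip-handling path.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_persons = 10000, seed = 1,
                             coefs = default_truth(),
                             entry_rate = log(2) / 6.3, entry_min = 18,
                             followup_mean = 29.4, followup_sd = 8.0,
                             smoker_prob = 0.105, sex_prob = 0.458,
                             statin_hazard = 0.008, antihtn_hazard = 0.010,
                             L = 80, same_year_dx_prob = 0) {
  cfg <- structure(list(n_persons = n_persons, seed = seed, coefs = coefs,
                        entry_rate = entry_rate, entry_min = entry_min,
                        followup_mean = followup_mean,
                        followup_sd = followup_sd,
                        smoker_prob = smoker_prob, sex_prob = sex_prob,
                        statin_hazard = statin_hazard,
                        antihtn_hazard = antihtn_hazard, L = L,
                        same_year_dx_prob = same_year_dx_prob),
                   class = "generator_config")
  .validate_truth(cfg)
  cfg
}

# coefficient vector for a transition at an age (NULL if absent)
.truth_beta <- function(coefs, from, to, age) {
  v <- coefs[[paste(from, to, sep = "|")]]
  if (is.null(v)) return(NULL)
  if (is.function(v)) v <- v(age)
  v
}

# reject configs whose implied row sums exceed 1 anywhere (checked at the
# all-zero covariate profile and a high-risk profile)
.validate_truth <- function(cfg) {
  probes <- list(risk_profile(), risk_profile(sex = 1, prs = 3, smoker = 1))
  froms <- setdiff(ms_states(), "Death")
  for (a in seq.int(cfg$entry_min, cfg$L - 1L)) {
    for (from in froms) {
      dest <- setdiff(successor_states(from), from)
      for (pr in probes) {
        s <- 0
        for (to in dest) {
          b <- .truth_beta(cfg$coefs, from, to, a)
          if (is.null(b)) next
          s <- s + stats::plogis(sum(b * c(1, pr$sex, pr$prs, pr$smoker,
                                           pr$statin_use, pr$antihtn_use)))
        }
        if (s > 1) {
          stop(sprintf("ground truth implies row sum %.3f > 1 for %s at age %d",
                       s, from, a), call. = FALSE)
        }
      }
    }
  }
  invisible(cfg)
}

#' Simulate a cohort of person records
#'
#' @param config [generator_config()].
#' @return Person-record `data.frame` (see [person_record_columns()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_persons
  if (n == 0) {
    empty <- stats::setNames(
      as.data.frame(rep(list(numeric(0)), length(person_record_columns()))),
      person_record_columns())
    empty$person_id <- character(0)
    return(person_records(empty))
  }
  set.seed(config$seed)
  sex <- stats::rbinom(n, 1, config$sex_prob)
  prs <- stats::rnorm(n)
  smoker <- stats::rbinom(n, 1, config$smoker_prob)
  entry <- config$entry_min + stats::rexp(n, config$entry_rate)
  followup <- pmax(1, stats::rnorm(n, config$followup_mean,
                                   config$followup_sd))
  censor <- pmax(entry, pmin(entry + followup, config$L))
  enroll <- stats::runif(n, 40, 69)
  statin_start <- 40 + .geom_start(n, config$statin_hazard)
  antihtn_start <- 40 + .geom_start(n, config$antihtn_hazard)

  state <- rep("Health", n)
  dx <- matrix(NA_real_, n, 4,
               dimnames = list(NULL, c("Ht", "HyperLip", "Dm", "CAD")))
  death_age <- rep(NA_real_, n)
  a0 <- min(floor(entry))
  for (a in seq.int(a0, config$L - 1L)) {
    active <- which(entry <= a & a < censor & state != "Death")
    if (length(active) == 0) next
    for (from in unique(state[active])) {
      ii <- active[state[active] == from]
      dest <- setdiff(successor_states(from), from)
      if (length(dest) == 0) next
      X <- cbind(1, sex[ii], prs[ii], smoker[ii],
                 as.numeric(!is.na(statin_start[ii]) & statin_start[ii] <= a),
                 as.numeric(!is.na(antihtn_start[ii]) & antihtn_start[ii] <= a))
      P <- matrix(0, length(ii), length(dest))
      for (d in seq_along(dest)) {
        b <- .truth_beta(config$coefs, from, dest[d], a)
        if (!is.null(b)) P[, d] <- stats::plogis(as.vector(X %*% b))
      }
      u <- stats::runif(length(ii))
      cum <- P
      if (ncol(P) > 1) {
        for (d in 2:ncol(P)) cum[, d] <- cum[, d - 1] + P[, d]
      }
      pick <- rowSums(u > cum) + 1L   # length(dest)+1 means self-loop
      moved <- pick <= length(dest)
      if (!any(moved)) next
      to <- dest[pick[moved]]
      ids <- ii[moved]
      for (k in seq_along(ids)) {
        i <- ids[k]
        if (to[k] == "Death") {
          death_age[i] <- a + 1
          state[i] <- "Death"
        } else if (to[k] == "CAD") {
          dx[i, "CAD"] <- a + 1
          state[i] <- "CAD"
        } else {
          gained <- setdiff(state_rf_set(to[k]), state_rf_set(state[i]))
          dx[i, gained] <- a + 1
          state[i] <- to[k]
        }
      }
    }
  }
  censor <- ifelse(!is.na(death_age), pmin(censor, death_age), censor)

  rec <- data.frame(
    person_id = sprintf("p%06d", seq_len(n)),
    sex = sex, prs = prs,
    birth_year = as.integer(stats::runif(n, 1935, 1970)),
    first_obs_age = entry, smoker = smoker,
    ht_dx_age = dx[, "Ht"], hyperlip_dx_age = dx[, "HyperLip"],
    dm_dx_age = dx[, "Dm"], cad_dx_age = dx[, "CAD"],
    death_age = death_age, censor_age = censor,
    statin_start_age = statin_start, antihtn_start_age = antihtn_start,
    enroll_age = enroll, stringsAsFactors = FALSE)

  if (config$same_year_dx_prob > 0) {
    # inject same-year double diagnoses: for single-risk-factor persons,
    # add a second risk factor at the same diagnosis age
    cols <- c("ht_dx_age", "hyperlip_dx_age", "dm_dx_age")
    n_rf <- rowSums(!is.na(rec[cols]))
    cand <- which(n_rf == 1 &
                    stats::runif(n) < config$same_year_dx_prob)
    for (i in cand) {
      have <- which(!is.na(rec[i, cols]))
      add <- setdiff(seq_along(cols), have)[1]
      rec[i, cols[add]] <- rec[i, cols[have]]
    }
  }
  person_records(rec)
}

# medication start offsets: geometric waiting time, NA if never within 60y
.geom_start <- function(n, hazard) {
  if (hazard <= 0) return(rep(NA_real_, n))
  g <- stats::rgeom(n, hazard)
  ifelse(g > 60, NA_real_, g)
}

#' Ground-truth risk for a query
#'
#' The exact fixed-path or marginal risk implied by the generating
#' coefficients (no fitting), used as the parameter-recovery oracle.
#'
#' @param config [generator_config()].
#' @param query [risk_query()].
#' @return Probability.
#' @export
ground_truth_risk <- function(config, query) {
  stopifnot(inherits(config, "generator_config"),
            inherits(query, "risk_query"))
  pr <- query$profile
  x <- c(1, pr$sex, pr$prs, pr$smoker, pr$statin_use, pr$antihtn_use)
  ages <- seq.int(query$start_age, query$end_age - 1L)
  rr <- if (query$treated) query$treatment_rr else 0
  pi_of <- function(from, to, a) {
    b <- .truth_beta(config$coefs, from, to, a)
    if (is.null(b)) 0 else stats::plogis(sum(b * x))
  }
  if (query$mode == "fixed-path") {
    pis <- vapply(ages, function(a)
      (1 - rr) * pi_of(query$start_state, query$target_state, a), numeric(1))
    return(interval_risk(pis))
  }
  states <- ms_states()
  P <- diag(length(states)); dimnames(P) <- list(states, states)
  for (a in ages) {
    Tm <- matrix(0, length(states), length(states),
                 dimnames = list(states, states))
    Tm["Death", "Death"] <- 1
    for (from in setdiff(states, "Death")) {
      dest <- setdiff(successor_states(from), from)
      p <- vapply(dest, function(to) pi_of(from, to, a), numeric(1))
      if (rr > 0 && query$target_state %in% dest && from != query$target_state) {
        p[query$target_state] <- (1 - rr) * p[query$target_state]
      }
      Tm[from, dest] <- p
      Tm[from, from] <- 1 - sum(p)
    }
    P <- P %*% Tm
  }
  unname(P[query$start_state, query$target_state])
}
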