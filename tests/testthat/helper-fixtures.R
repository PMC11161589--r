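# Shared fixture builders: all fixtures are constructed in code.

# one person record with overridable fields
make_record <- function(person_id = "p1", sex = 0, prs = 0,
                        birth_year = 1950, first_obs_age = 25, smoker = 0,
                        ht_dx_age = NA, hyperlip_dx_age = NA,
                        dm_dx_age = NA, cad_dx_age = NA, death_age = NA,
                        censor_age = 80, statin_start_age = NA,
                        antihtn_start_age = NA, enroll_age = 40) {
  data.frame(person_id = person_id, sex = sex, prs = prs,
             birth_year = birth_year, first_obs_age = first_obs_age,
             smoker = smoker, ht_dx_age = ht_dx_age,
             hyperlip_dx_age = hyperlip_dx_age, dm_dx_age = dm_dx_age,
             cad_dx_age = cad_dx_age, death_age = death_age,
             censor_age = censor_age, statin_start_age = statin_start_age,
             antihtn_start_age = antihtn_start_age,
             enroll_age = enroll_age, stringsAsFactors = FALSE)
}

# a degenerate smoothed table with constant intercept-only coefficients:
# every allowed non-self transition gets the same annual probability
make_flat_table <- function(pi_by_transition, ages = 40:79,
                            covariates = character(0)) {
  ts <- transition_set(include_cad_death = TRUE)
  ts <- ts[ts$from_state != ts$to_state, ]
  rows <- list()
  for (r in seq_len(nrow(ts))) {
    key <- paste(ts$from_state[r], ts$to_state[r], sep = "|")
    p <- pi_by_transition[[key]]
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      from_state = ts$from_state[r], to_state = ts$to_state[r],
      age = ages, term = "intercept", beta = qlogis(p), se = 0.1,
      n_at_risk = 1000L, n_events = 10L, variant = "smoothed",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("coef_table", "data.frame")
  attr(tab, "covariates") <- covariates
  tab
}
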