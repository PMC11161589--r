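# flat-rate fixture used throughout: constant annual probabilities
flat_pis <- list("Health|Ht" = 0.02, "Health|HyperLip" = 0.01,
                 "Health|Dm" = 0.005, "Health|CAD" = 0.01,
                 "Health|Death" = 0.003, "Ht|Ht&HyperLip" = 0.01,
                 "Ht|Ht&Dm" = 0.005, "Ht|CAD" = 0.02, "Ht|Death" = 0.004,
                 "HyperLip|Ht&HyperLip" = 0.01, "HyperLip|Dm&HyperLip" = 0.004,
                 "HyperLip|CAD" = 0.015, "HyperLip|Death" = 0.004,
                 "Dm|Ht&Dm" = 0.01, "Dm|Dm&HyperLip" = 0.008,
                 "Dm|CAD" = 0.02, "Dm|Death" = 0.005,
                 "Ht&HyperLip|Ht&HyperLip&Dm" = 0.008,
                 "Ht&HyperLip|CAD" = 0.03, "Ht&HyperLip|Death" = 0.005,
                 "Ht&Dm|Ht&HyperLip&Dm" = 0.008, "Ht&Dm|CAD" = 0.03,
                 "Ht&Dm|Death" = 0.006,
                 "Dm&HyperLip|Ht&HyperLip&Dm" = 0.008,
                 "Dm&HyperLip|CAD" = 0.03, "Dm&HyperLip|Death" = 0.005,
                 "Ht&HyperLip&Dm|CAD" = 0.04, "Ht&HyperLip&Dm|Death" = 0.008,
                 "CAD|Death" = 0.02)

test_that("interval risk product formula", {
  expect_identical(interval_risk(numeric(0)), 0)
  expect_identical(interval_risk(rep(0, 10)), 0)
  expect_identical(interval_risk(c(0.2, 1, 0.1)), 1)
  expect_equal(interval_risk(rep(0.01, 40)), 1 - 0.99^40, tolerance = 1e-12)
})

test_that("annual transition rows conserve probability", {
  tab <- make_flat_table(flat_pis)
  row <- annual_transition_row(tab, risk_profile(), "Health", 50)
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_equal(unname(row["CAD"]), 0.01, tolerance = 1e-12)
  expect_equal(unname(row["Health"]),
               1 - (0.02 + 0.01 + 0.005 + 0.01 + 0.003), tolerance = 1e-12)
  # all destination probs 0 -> self prob 1
  tab0 <- make_flat_table(lapply(flat_pis, function(x) 1e-30))
  row0 <- annual_transition_row(tab0, risk_profile(), "Health", 50)
  expect_equal(unname(row0["Health"]), 1, tolerance = 1e-12)
  # over-unity rows are rescaled to sum 1
  tabhot <- make_flat_table(list("Ht&HyperLip&Dm|CAD" = 0.7,
                                 "Ht&HyperLip&Dm|Death" = 0.6))
  expect_warning(
    rowh <- annual_transition_row(tabhot, risk_profile(),
                                  "Ht&HyperLip&Dm", 50),
    "rescaled")
  expect_equal(sum(rowh), 1, tolerance = 1e-12)
  expect_equal(unname(rowh["Ht&HyperLip&Dm"]), 0, tolerance = 1e-12)
})

test_that("probability conservation over random profiles and ages", {
  # a table with genuine covariate effects
  rec <- simulate_cohort(generator_config(n_persons = 4000, seed = 77))
  py <- expand_person_years(rec)
  raw <- suppressWarnings(fit_all(py))
  tab <- suppressWarnings(smooth_table(raw))
  set.seed(7)
  for (i in 1:250) {
    prof <- risk_profile(sex = rbinom(1, 1, 0.5), prs = rnorm(1),
                         smoker = rbinom(1, 1, 0.2),
                         statin_use = rbinom(1, 1, 0.2),
                         antihtn_use = rbinom(1, 1, 0.2))
    from <- sample(setdiff(ms_states(), c("CAD", "Death")), 1)
    a <- sample(40:79, 1)
    row <- suppressWarnings(annual_transition_row(tab, prof, from, a))
    expect_equal(sum(row), 1, tolerance = 1e-12)
    expect_true(all(row >= 0))
  }
})

test_that("lifetime, treated and marginal risks on a flat table", {
  tab <- make_flat_table(flat_pis)
  prof <- risk_profile()
  q <- risk_query(prof, start_age = 40, end_age = 80)
  r <- project_risk(tab, q)
  expect_equal(r$risk, 1 - (1 - 0.01)^40, tolerance = 1e-12)
  # risk is reproducible from the stored per-age sequence
  expect_equal(r$risk, interval_risk(r$per_age_probs), tolerance = 1e-15)
  # one-year query equals that year's probability
  q79 <- risk_query(prof, start_age = 79, end_age = 80)
  expect_equal(project_risk(tab, q79)$risk, 0.01, tolerance = 1e-12)
  # treated: each annual probability scaled by 1 - RR
  qt <- risk_query(prof, treated = TRUE, treatment_rr = 0.2)
  expect_equal(project_risk(tab, qt)$risk, 1 - (1 - 0.008)^40,
               tolerance = 1e-12)
  expect_equal(absolute_risk_reduction(tab, q),
               (1 - 0.99^40) - (1 - 0.992^40), tolerance = 1e-12)
  # RR = 0 and RR = 1 limits
  expect_equal(project_risk(tab, risk_query(prof, treated = TRUE,
                                            treatment_rr = 0))$risk,
               r$risk, tolerance = 1e-15)
  expect_equal(project_risk(tab, risk_query(prof, treated = TRUE,
                                            treatment_rr = 1))$risk, 0)
  # profiles already on statins are rejected for treated queries
  expect_error(
    treated_interval_risk(tab, risk_query(risk_profile(statin_use = 1))),
    "statin")
})

test_that("remaining_lifetime_risk composes with L and rejects absorbing", {
  tab <- make_flat_table(flat_pis)
  q <- risk_query(risk_profile(), start_age = 60, end_age = 70)
  expect_equal(remaining_lifetime_risk(tab, q, L = 80)$risk,
               1 - 0.99^20, tolerance = 1e-12)
  expect_error(project_risk(tab, risk_query(start_state = "Death")),
               "absorbing")
})

test_that("risk is monotone in the interval and under treatment", {
  tab <- make_flat_table(flat_pis)
  prof <- risk_profile()
  risks_end <- sapply(c(50, 60, 70, 80), function(a2)
    project_risk(tab, risk_query(prof, start_age = 40, end_age = a2))$risk)
  expect_true(all(diff(risks_end) > 0))
  risks_start <- sapply(c(40, 50, 60), function(a1)
    project_risk(tab, risk_query(prof, start_age = a1, end_age = 80))$risk)
  expect_true(all(diff(risks_start) < 0))
  set.seed(11)
  for (rr in runif(20)) {
    q <- risk_query(prof, treated = TRUE, treatment_rr = rr)
    expect_lte(project_risk(tab, q)$risk,
               project_risk(tab, risk_query(prof))$risk)
  }
})

test_that("transition matrices are row-stochastic with absorbing rows", {
  tab <- make_flat_table(flat_pis)
  Tm <- build_transition_matrix(tab, risk_profile(), 55)
  expect_equal(unname(rowSums(Tm)), rep(1, 10), tolerance = 1e-12)
  expect_identical(unname(Tm["Death", ]),
                   as.numeric(ms_states() == "Death"))
  expect_equal(unname(Tm["CAD", "Death"]), 0.02, tolerance = 1e-12)
  expect_equal(unname(Tm["CAD", "CAD"]), 0.98, tolerance = 1e-12)
})

test_that("marginal risk equals brute-force path enumeration", {
  # 2-state identity: with no exits other than j -> CAD, the marginal
  # equals the fixed-path closed form
  tab2 <- make_flat_table(list("Ht&HyperLip&Dm|CAD" = 0.03))
  prof <- risk_profile()
  qm <- risk_query(prof, start_state = "Ht&HyperLip&Dm", start_age = 40,
                   end_age = 60, mode = "marginal")
  expect_equal(suppressWarnings(project_risk(tab2, qm))$risk,
               1 - 0.97^20, tolerance = 1e-12)

  # 3-state chain Health -> Ht -> CAD over 2 years: enumerate paths
  p_ht <- 0.1; p_cad_h <- 0.02; p_cad_ht <- 0.05
  tab3 <- make_flat_table(list("Health|Ht" = p_ht, "Health|CAD" = p_cad_h,
                               "Ht|CAD" = p_cad_ht))
  q2 <- risk_query(prof, start_age = 40, end_age = 42, mode = "marginal")
  # paths: CAD year 1; stay -> CAD year 2; Ht year 1 -> CAD year 2
  want <- p_cad_h +
    (1 - p_cad_h - p_ht) * p_cad_h +
    p_ht * p_cad_ht
  expect_equal(suppressWarnings(project_risk(tab3, q2))$risk, want,
               tolerance = 1e-12)
  # marginal >= fixed-path on the same table
  qf <- risk_query(prof, start_age = 40, end_age = 42)
  expect_gte(suppressWarnings(project_risk(tab3, q2))$risk,
             project_risk(tab3, qf)$risk)
  # non-absorbing marginal targets are rejected
  expect_error(project_risk(tab3, risk_query(prof, target_state = "Ht",
                                             mode = "marginal")),
               "absorbing")
})

test_that("marginal dominates fixed-path when death is absent", {
  # the dominance holds when no probability leaks to a competing absorbing
  # state; with death in the topology the marginal can fall below the
  # fixed-path value because the matrix product loses mass to death
  no_death <- flat_pis[!grepl("Death", names(flat_pis))]
  tab <- make_flat_table(no_death)
  prof <- risk_profile()
  for (a1 in c(40, 55, 70)) {
    qf <- risk_query(prof, start_age = a1, end_age = 80)
    qm <- risk_query(prof, start_age = a1, end_age = 80, mode = "marginal")
    expect_gte(suppressWarnings(project_risk(tab, qm))$risk,
               project_risk(tab, qf)$risk - 1e-12)
  }
  # with death present the two modes are both available but neither bounds
  # the other; they must still agree on a one-year window
  tabd <- make_flat_table(flat_pis)
  q1 <- risk_query(prof, start_age = 40, end_age = 41)
  q1m <- risk_query(prof, start_age = 40, end_age = 41, mode = "marginal")
  expect_equal(suppressWarnings(project_risk(tabd, q1m))$risk,
               project_risk(tabd, q1)$risk, tolerance = 1e-12)
})

test_that("bootstrap projections are reproducible and quantify noise", {
  rec <- simulate_cohort(generator_config(n_persons = 600, seed = 13,
                                          coefs = default_truth(FALSE)))
  q <- risk_query(risk_profile(), start_age = 40, end_age = 50)
  b1 <- suppressWarnings(bootstrap_projection(
    rec, q, n_boot = 5, seed = 99, covariates = character(0)))
  b2 <- suppressWarnings(bootstrap_projection(
    rec, q, n_boot = 5, seed = 99, covariates = character(0)))
  expect_identical(b1$boot_mean, b2$boot_mean)
  expect_identical(b1$se, b2$se)
  expect_gt(b1$se, 0)
  expect_lte(b1$n_valid, 5)
  expect_equal(b1$risk, b2$risk)
})
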