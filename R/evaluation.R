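# Model-assessment battery: stratified calibration RMSE, net
# reclassification, threshold-age analysis, time-dependent concordance via
# interval expansion, cumulative AUC / precision-recall, and proportion
# standard errors.
#
# Comparator scores (e.g. 30-year Framingham, pooled cohort equations) are
# consumed as externally supplied per-person(-per-age) columns; their
# published equations are not re-implemented here.

#' Stratified calibration RMSE
#'
#' Persons are stratified by sex crossed with polygenic-score group
#' (below the 20th percentile, 20th-80th, above the 80th).  Within each
#' stratum the empirical incidence (mean outcome) is compared with the
#' mean predicted risk; the RMSE over strata is reported in percent.
#'
#' @param predicted Predicted risks in `[0, 1]`, one per person.
#' @param outcome Binary observed outcomes.
#' @param sex Binary sex values.
#' @param prs Polygenic score values.
#' @param prs_breaks Quantile cut points for the score groups (computed on
#'   `prs` itself by default; pass training-set quantiles for held-out
#'   evaluation).
#' @return List: `rmse_pct` (percent), `by_stratum` data frame, `sem_pct`
#'   (standard error of the mean stratum error, percent).
#' @export
stratified_rmse <- function(predicted, outcome, sex, prs,
                            prs_breaks = stats::quantile(prs, c(0.2, 0.8))) {
  stopifnot(length(predicted) == length(outcome),
            length(sex) == length(outcome), length(prs) == length(outcome))
  grp <- cut(prs, c(-Inf, prs_breaks, Inf),
             labels = c("low", "intermediate", "high"))
  strat <- interaction(sex, grp, drop = TRUE)
  if (nlevels(strat) < 1) stop("no non-empty strata")
  emp <- tapply(outcome, strat, mean)
  pred <- tapply(predicted, strat, mean)
  n <- tapply(outcome, strat, length)
  err <- 100 * (emp - pred)
  list(rmse_pct = sqrt(mean(err^2)),
       by_stratum = data.frame(stratum = names(emp), n = as.vector(n),
                               empirical_pct = 100 * as.vector(emp),
                               predicted_pct = 100 * as.vector(pred),
                               error_pct = as.vector(err)),
       sem_pct = stats::sd(err) / sqrt(length(err)))
}

#' Standard error of a sample proportion
#' @param p_hat Sample proportion.
#' @param n Sample size.
#' @return `sqrt(p_hat (1 - p_hat) / n)`.
#' @export
proportion_se <- function(p_hat, n) sqrt(p_hat * (1 - p_hat) / n)

#' Net reclassification components
#'
#' Event component: among persons who develop the outcome, the proportion
#' up-classified by the model (model lifetime risk above
#' `lifetime_threshold` while the comparator is below
#' `comparator_threshold`) minus the proportion down-classified.  Non-event
#' component: among persons who do not, the proportion correctly
#' down-classified minus the proportion up-classified.  Overall is their
#' sum.  By default the down-classification term of the event component
#' uses `down_threshold` = `comparator_threshold` (the printed set
#' algebra); set `symmetric = TRUE` to use `lifetime_threshold` on both
#' sides.
#'
#' @param model_risk,comparator_risk Aligned risk vectors in `[0, 1]`.
#' @param outcome Binary outcome vector.
#' @param lifetime_threshold Model threshold (default 0.10).
#' @param comparator_threshold Comparator threshold (default 0.05).
#' @param symmetric Use the model threshold symmetrically in the event
#'   down-classification term.
#' @return List: `nri_event`, `nri_nonevent`, `nri_overall`, each with a
#'   proportion standard error, and the counts used.
#' @export
nri_components <- function(model_risk, comparator_risk, outcome,
                           lifetime_threshold = 0.10,
                           comparator_threshold = 0.05,
                           symmetric = FALSE) {
  stopifnot(length(model_risk) == length(outcome),
            length(comparator_risk) == length(outcome))
  down_thr <- if (symmetric) lifetime_threshold else comparator_threshold
  ev <- outcome == 1
  n_ev <- sum(ev); n_ne <- sum(!ev)
  up <- model_risk > lifetime_threshold & comparator_risk < comparator_threshold
  down <- model_risk < down_thr & comparator_risk > comparator_threshold
  # non-event direction: correctly down-classified means model below its
  # threshold while comparator flags the person
  ne_down <- model_risk < lifetime_threshold &
    comparator_risk > comparator_threshold
  ne_up <- model_risk > lifetime_threshold &
    comparator_risk < comparator_threshold
  nri_event <- if (n_ev == 0) NA_real_ else
    (sum(up & ev) - sum(down & ev)) / n_ev
  nri_nonevent <- if (n_ne == 0) NA_real_ else
    (sum(ne_down & !ev) - sum(ne_up & !ev)) / n_ne
  overall <- if (is.na(nri_event) || is.na(nri_nonevent)) NA_real_ else
    nri_event + nri_nonevent
  list(nri_event = nri_event,
       nri_event_se = if (n_ev) proportion_se(abs(nri_event), n_ev) else NA_real_,
       nri_nonevent = nri_nonevent,
       nri_nonevent_se = if (n_ne) proportion_se(abs(nri_nonevent), n_ne) else NA_real_,
       nri_overall = overall, n_events = n_ev, n_nonevents = n_ne)
}

#' First age a score series exceeds a threshold
#'
#' @param ages Ages of the score observations.
#' @param scores Score values (same length).
#' @param threshold Threshold; exceedance is strict (`>`).
#' @return Smallest age with `score > threshold`, or `Inf` (the
#'   never-sentinel) if none.
#' @export
threshold_age <- function(ages, scores, threshold) {
  stopifnot(length(ages) == length(scores), length(ages) > 0)
  o <- order(ages)
  hit <- which(scores[o] > threshold)
  if (length(hit) == 0) return(Inf)
  ages[o][hit[1]]
}

#' Expand one person's trajectory into threshold intervals
#'
#' Cuts the observed trajectory at each score's threshold age and at the
#' event age, producing nonoverlapping consecutive intervals with constant
#' per-score exceedance flags; the event interval runs to `horizon_end`.
#' Intervals use inclusive integer year bounds (`[start, stop]`).  The
#' left floor is `max(obs_start, enroll_age)` (left-censoring at
#' enrollment); threshold ages before the floor enter with their flag
#' already set.
#'
#' @param obs_start,obs_end Observed age window.
#' @param threshold_ages Named numeric vector of per-score threshold ages
#'   (`Inf` for never).
#' @param event_age Event age or `NA`.
#' @param enroll_age Left-censoring floor (default `-Inf` = none).
#' @param horizon_end Evaluation horizon (default 80).
#' @return `data.frame` with `age_start`, `age_stop`, one logical flag
#'   column per score, and `event` (flag at interval end).
#' @export
expand_intervals <- function(obs_start, obs_end, threshold_ages,
                             event_age = NA, enroll_age = -Inf,
                             horizon_end = 80) {
  lo <- max(obs_start, enroll_age)
  if (!is.na(event_age) && event_age < lo) {
    stop("event before observation start")
  }
  hi <- if (!is.na(event_age)) horizon_end else min(obs_end, horizon_end)
  cuts <- threshold_ages[is.finite(threshold_ages) &
                           threshold_ages > lo & threshold_ages <= hi]
  if (!is.na(event_age)) cuts <- c(cuts, event = event_age)
  starts <- sort(unique(c(lo, unname(cuts))))
  stops <- c(starts[-1] - 1, hi)
  out <- data.frame(age_start = starts, age_stop = stops)
  for (nm in names(threshold_ages)) {
    out[[nm]] <- starts >= threshold_ages[[nm]]
  }
  out$event <- if (is.na(event_age)) FALSE else starts >= event_age
  out
}

#' Time-dependent concordance (Harrell's C on current scores)
#'
#' At each event age, the failing person's current score is compared with
#' the current scores of everyone still at risk (observed at that age,
#' event-free, past enrollment).  Concordant pairs (failing score higher)
#' count 1, ties 0.5.  The optional bootstrap resamples persons to give a
#' confidence interval, and two score series can be compared with a
#' normal-approximation two-sided Z test on the bootstrap difference.
#'
#' @param scores Long `data.frame` with columns `person_id`, `age`,
#'   `score` (one row per person per at-risk age).
#' @param events `data.frame` with columns `person_id`, `event_age`
#'   (`NA` if censored).
#' @param n_boot Bootstrap replicates (0 = point estimate only).
#' @param seed RNG seed for the bootstrap.
#' @return List: `c_index`, `n_pairs`, and with bootstrap `ci` (95%),
#'   `boot` (replicate values).
#' @export
time_dependent_concordance <- function(scores, events, n_boot = 0,
                                       seed = 1) {
  stopifnot(all(c("person_id", "age", "score") %in% names(scores)),
            all(c("person_id", "event_age") %in% names(events)))
  compute <- function(scores, events) {
    ev <- events[!is.na(events$event_age), , drop = FALSE]
    if (nrow(ev) == 0) return(list(c_index = NA_real_, n_pairs = 0))
    conc <- 0; pairs <- 0
    for (r in seq_len(nrow(ev))) {
      a <- ev$event_age[r]
      id <- ev$person_id[r]
      s_fail <- scores$score[scores$person_id == id & scores$age == a]
      if (length(s_fail) != 1) next
      # at risk: observed at age a, no event before or at a (other than the
      # failing subject)
      ids_at_a <- scores$person_id[scores$age == a]
      evage <- events$event_age[match(ids_at_a, events$person_id)]
      atrisk <- ids_at_a[ids_at_a != id & (is.na(evage) | evage > a)]
      if (length(atrisk) == 0) next
      s_others <- scores$score[scores$age == a &
                                 scores$person_id %in% atrisk]
      conc <- conc + sum(s_fail > s_others) + 0.5 * sum(s_fail == s_others)
      pairs <- pairs + length(s_others)
    }
    if (pairs == 0) return(list(c_index = NA_real_, n_pairs = 0))
    list(c_index = conc / pairs, n_pairs = pairs)
  }
  point <- compute(scores, events)
  out <- list(c_index = point$c_index, n_pairs = point$n_pairs)
  if (n_boot > 0) {
    set.seed(seed)
    ids <- unique(events$person_id)
    reps <- vapply(seq_len(n_boot), function(b) {
      samp <- sample(ids, length(ids), replace = TRUE)
      new_ids <- paste0(samp, "_", seq_along(samp))
      sc <- do.call(rbind, lapply(seq_along(samp), function(i) {
        s <- scores[scores$person_id == samp[i], , drop = FALSE]
        if (nrow(s)) s$person_id <- new_ids[i]
        s
      }))
      evs <- events[match(samp, events$person_id), , drop = FALSE]
      evs$person_id <- new_ids
      compute(sc, evs)$c_index
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    out$boot <- reps
    out$ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    out$se <- stats::sd(reps)
  }
  out
}

#' Compare two concordance bootstraps with a Z test
#'
#' @param boot1,boot2 Bootstrap replicate vectors of two C indices
#'   (paired by replicate when lengths match).
#' @return List: `z`, `p_value`, `delta`.
#' @export
concordance_z_test <- function(boot1, boot2) {
  if (length(boot1) == length(boot2)) {
    d <- boot1 - boot2
    z <- mean(d) / stats::sd(d)
  } else {
    z <- (mean(boot1) - mean(boot2)) /
      sqrt(stats::var(boot1) / length(boot1) +
             stats::var(boot2) / length(boot2))
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       delta = mean(boot1) - mean(boot2))
}

#' Cumulative AUROC and precision-recall area
#'
#' Rank-based AUROC (Mann-Whitney, ties 0.5) of a score against the
#' cumulative presence/absence of disease over observed time, and the
#' area under the precision-recall curve (average precision).
#'
#' @param scores Score values at one age.
#' @param outcome Binary cumulative outcome.
#' @return List: `auroc`, `pr_auc`, `n_pos`, `n_neg`; `NA` values if a
#'   class is absent.
#' @export
cumulative_auc_pr <- function(scores, outcome) {
  stopifnot(length(scores) == length(outcome))
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    return(list(auroc = NA_real_, pr_auc = NA_real_,
                n_pos = length(pos), n_neg = length(neg)))
  }
  r <- rank(c(pos, neg), ties.method = "average")
  auroc <- (sum(r[seq_along(pos)]) -
              length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  # average precision: mean of precision at each positive, scores
  # descending, ties broken pessimistically by outcome
  o <- order(scores, outcome, decreasing = TRUE)
  y <- outcome[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  pr_auc <- sum(prec[y == 1]) / length(pos)
  list(auroc = auroc, pr_auc = pr_auc,
       n_pos = length(pos), n_neg = length(neg))
}
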