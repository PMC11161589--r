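# Expansion of raw per-person longitudinal records into annual person-year
# rows (age, from-state, to-state, covariates, at-risk flag).
#
# Conventions:
#   * ages are discretized to integer years; a diagnosis at age 39.6 takes
#     effect at the transition into age 40 (half-open year [a, a+1));
#   * medication covariates statin_use(a) / antihtn_use(a) are 1 iff the
#     start age is <= a; prescriptions are treated as persistent;
#   * a year with two same-age diagnoses jumps more than one risk-factor
#     level; the row is emitted for trajectory bookkeeping but flagged
#     `skip = TRUE` and excluded from fitting the restricted topology.

#' Person-record column names
#'
#' Canonical column set of the long-format person-record table: one row per
#' person.  Missing values (no diagnosis, no death, no prescription) are
#' `NA`.
#' @return Character vector.
#' @export
person_record_columns <- function() {
  c("person_id", "sex", "prs", "birth_year", "first_obs_age", "smoker",
    "ht_dx_age", "hyperlip_dx_age", "dm_dx_age", "cad_dx_age",
    "death_age", "censor_age", "statin_start_age", "antihtn_start_age",
    "enroll_age")
}

#' Validate and normalize person records
#'
#' Checks the column set, coerces types, and enforces
#' `censor_age = min(censor_age, death_age)` so that death closes follow-up.
#'
#' @param df `data.frame` with the columns of [person_record_columns()].
#' @return A `data.frame` of validated records.
#' @export
person_records <- function(df) {
  need <- person_record_columns()
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("person records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$person_id <- as.character(df$person_id)
  for (col in setdiff(need, "person_id")) df[[col]] <- as.numeric(df[[col]])
  if (anyNA(df$censor_age)) stop("censor_age must be present for every person")
  if (any(df$first_obs_age > df$censor_age, na.rm = TRUE)) {
    stop("first_obs_age must not exceed censor_age")
  }
  has_death <- !is.na(df$death_age)
  df$censor_age[has_death] <- pmin(df$censor_age[has_death],
                                   df$death_age[has_death])
  df
}

# Vectorized state assignment over persons at one integer age.
.assign_state_vec <- function(records, age) {
  n <- nrow(records)
  out <- rep("Health", n)
  has <- function(col) !is.na(records[[col]]) & records[[col]] <= age
  ht <- has("ht_dx_age"); hl <- has("hyperlip_dx_age"); dm <- has("dm_dx_age")
  lab <- vapply(seq_len(n), function(i) {
    rfs <- c("Ht", "HyperLip", "Dm")[c(ht[i], hl[i], dm[i])]
    if (length(rfs) == 0) "Health" else rf_state_label(rfs)
  }, character(1))
  out <- lab
  out[has("cad_dx_age")] <- "CAD"
  out[has("death_age")] <- "Death"
  out
}

#' State of a person at an age
#'
#' Death dominates, then CAD, then the combination of risk factors
#' diagnosed at or before `age`; Health otherwise.
#'
#' @param record One-row `data.frame` of person-record columns.
#' @param age Integer age in years.
#' @return State label.
#' @export
#' @examples
#' rec <- data.frame(person_id = "p", sex = 1, prs = 0, birth_year = 1950,
#'   first_obs_age = 25, smoker = 0, ht_dx_age = 39, hyperlip_dx_age = NA,
#'   dm_dx_age = NA, cad_dx_age = NA, death_age = NA, censor_age = 60,
#'   statin_start_age = NA, antihtn_start_age = NA, enroll_age = 45)
#' assign_state(rec, 40)  # "Ht"
assign_state <- function(record, age) {
  stopifnot(age >= 0, nrow(record) == 1)
  .assign_state_vec(record, age)
}

#' Expand person records into annual person-year rows
#'
#' One row per person per integer age `a` in
#' `[max(age_lo, first_obs_age), min(age_hi, censor_age))`, with
#' `from_state` the state at `a` and `to_state` the state at `a + 1`.
#' Rows stop once the person enters Death; persons with CAD already at
#' `age_lo` are excluded entirely (risk reporting is on CAD-free
#' individuals).  For deaths, the year of death is included so the
#' terminal transition is observed; for plain censoring the final partial
#' year is dropped.
#'
#' @param records Person-record `data.frame` (validated by
#'   [person_records()]).
#' @param age_lo,age_hi Half-open modelling age window, default `[40, 80)`.
#' @return `data.table` with columns `person_id, age, from_state, to_state,
#'   sex, prs, smoker, statin_use, antihtn_use, enroll_age, at_risk, skip`.
#'   `skip` marks multi-event years whose to-state jumps more than one
#'   step; such rows are excluded from fitting.
#' @export
expand_person_years <- function(records, age_lo = 40, age_hi = 80) {
  if (!(age_lo < age_hi)) stop("age_lo must be < age_hi")
  records <- person_records(records)

  # drop persons with CAD at baseline or dead/censored before the window
  base_state <- .assign_state_vec(records, age_lo)
  keep <- !(base_state %in% c("CAD", "Death"))
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) return(.empty_person_years())

  start <- pmax(age_lo, ceiling(records$first_obs_age))
  is_death <- !is.na(records$death_age)
  end_excl <- ifelse(is_death,
                     pmin(age_hi, ceiling(records$censor_age)),
                     pmin(age_hi, floor(records$censor_age)))
  n_rows <- pmax(0L, as.integer(end_excl - start))
  idx <- rep.int(seq_len(nrow(records)), n_rows)
  if (length(idx) == 0) return(.empty_person_years())
  age <- unlist(lapply(seq_len(nrow(records)), function(i) {
    if (n_rows[i] <= 0L) integer(0) else seq.int(start[i], length.out = n_rows[i])
  }), use.names = FALSE)

  rec <- records[idx, , drop = FALSE]
  dt <- data.table::data.table(
    person_id = rec$person_id,
    age = as.integer(age),
    from_state = .state_at(rec, age),
    to_state = .state_at(rec, age + 1L),
    sex = rec$sex, prs = rec$prs, smoker = rec$smoker,
    statin_use = as.numeric(!is.na(rec$statin_start_age) &
                              rec$statin_start_age <= age),
    antihtn_use = as.numeric(!is.na(rec$antihtn_start_age) &
                               rec$antihtn_start_age <= age),
    enroll_age = rec$enroll_age
  )
  # truncate at absorbing entry: no rows from Death
  dt <- dt[dt$from_state != "Death", ]
  dt$at_risk <- TRUE
  dt$skip <- !.allowed_vec(dt$from_state, dt$to_state)
  data.table::setorderv(dt, c("person_id", "age"))
  dt[]
}

# risk-factor bitmask per state label (-1 CAD, -2 Death) for vectorized checks
.state_key <- c("Health" = 0L, "Ht" = 1L, "HyperLip" = 2L, "Ht&HyperLip" = 3L,
                "Dm" = 4L, "Ht&Dm" = 5L, "Dm&HyperLip" = 6L,
                "Ht&HyperLip&Dm" = 7L, "CAD" = -1L, "Death" = -2L)

# vectorized allowed(): self-loops, exits to CAD/Death, one-step supersets
.allowed_vec <- function(from, to) {
  kf <- .state_key[from]
  kt <- .state_key[to]
  lev <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L)
  self <- from == to & from != "Death"
  exits <- from != "Death" &
    ((to == "Death") | (to == "CAD" & kf >= 0L))
  kf_s <- pmax(kf, 0L)
  kt_s <- pmax(kt, 0L)
  step <- kf >= 0L & kt > 0L &
    bitwAnd(kf_s, kt_s) == kf_s &
    lev[kt_s + 1L] == lev[kf_s + 1L] + 1L
  unname(self | exits | step)
}

# state at arbitrary ages for pre-subset (repeated) records
.state_at <- function(rec, age) {
  n <- nrow(rec)
  has <- function(col) !is.na(rec[[col]]) & rec[[col]] <= age
  ht <- has("ht_dx_age"); hl <- has("hyperlip_dx_age"); dm <- has("dm_dx_age")
  cad <- has("cad_dx_age"); dead <- has("death_age")
  # label by bit pattern, fixed canonical spellings
  key <- ht + 2L * hl + 4L * dm
  lab <- c("Health", "Ht", "HyperLip", "Ht&HyperLip",
           "Dm", "Ht&Dm", "Dm&HyperLip", "Ht&HyperLip&Dm")[key + 1L]
  lab[cad] <- "CAD"
  lab[dead] <- "Death"
  lab
}

.empty_person_years <- function() {
  data.table::data.table(
    person_id = character(0), age = integer(0),
    from_state = character(0), to_state = character(0),
    sex = numeric(0), prs = numeric(0), smoker = numeric(0),
    statin_use = numeric(0), antihtn_use = numeric(0),
    enroll_age = numeric(0), at_risk = logical(0), skip = logical(0)
  )
}

#' At-risk set for a transition cell
#'
#' Person-year rows occupying `from_state` at `age` with `at_risk = TRUE`,
#' in deterministic person-id order.
#'
#' @param person_years `data.table` from [expand_person_years()].
#' @param from_state State label.
#' @param age Integer age.
#' @return Filtered `data.table`.
#' @export
at_risk_set <- function(person_years, from_state, age) {
  .check_state(from_state, "from_state")
  dt <- person_years[person_years$age == age &
                       person_years$from_state == from_state &
                       person_years$at_risk, ]
  data.table::setorderv(dt, "person_id")
  dt[]
}

#' Read / write person records and person-year rows
#'
#' Delimited UTF-8 text, comma separator, `"."` decimal mark, `NA` missing
#' token, deterministic column order.
#'
#' @param path File path.
#' @param records,person_years Tables to write.
#' @return The read table, or the path invisibly.
#' @export
read_person_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"))
  person_records(df)
}

#' @rdname read_person_records
#' @export
write_person_records <- function(records, path) {
  records <- person_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_person_records
#' @export
write_person_years <- function(person_years, path) {
  utils::write.csv(as.data.frame(person_years), path, row.names = FALSE,
                   quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_person_records
#' @export
read_person_years <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"))
  dt <- data.table::as.data.table(df)
  dt$age <- as.integer(dt$age)
  dt$at_risk <- as.logical(dt$at_risk)
  dt$skip <- as.logical(dt$skip)
  dt[]
}
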