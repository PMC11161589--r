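# Per-age logistic transition models.
#
# For each age a and each allowed non-self transition j -> k, the one-year
# transition indicator among persons at risk in j at age a is modelled as
#   logit P(to = k) = b0 + b1 x1 + ... + bp xp
# fitted independently per (j, k, a) by maximum likelihood.  The self
# transition j -> j is never fitted: it is the complement of the fitted
# destinations at projection time.  Degenerate cells (no events, no
# non-events, too few rows, separation, non-convergence) are recorded as
# "unfit" sentinels with beta = NA and se = Inf so the smoother assigns
# them weight exactly zero.

#' Default covariate specification
#' @return Character vector of covariate column names (intercept implicit).
#' @export
default_covariates <- function() {
  c("sex", "prs", "smoker", "statin_use", "antihtn_use")
}

.term_names <- function(covariates) c("intercept", covariates)

# design matrix for person-year rows
.design_matrix <- function(rows, covariates) {
  X <- cbind(intercept = rep(1, nrow(rows)))
  for (cv in covariates) X <- cbind(X, rows[[cv]])
  colnames(X) <- .term_names(covariates)
  X
}

.sentinel_fit <- function(covariates, n_at_risk, n_events) {
  terms <- .term_names(covariates)
  list(beta = stats::setNames(rep(NA_real_, length(terms)), terms),
       se = stats::setNames(rep(Inf, length(terms)), terms),
       n_at_risk = n_at_risk, n_events = n_events, fitted = FALSE)
}

#' Fit one transition cell
#'
#' Maximum-likelihood logistic fit of the indicator `to_state == k` on the
#' at-risk rows of one (from-state, age) cell.
#'
#' @param rows Person-year rows sharing one `from_state` and one `age`
#'   (skip-flagged rows should be removed by the caller).
#' @param to_state Destination state defining the outcome.
#' @param covariates Covariate names (see [default_covariates()]).
#' @return List with named `beta`, `se` (log-odds units), `n_at_risk`,
#'   `n_events`, `fitted`.  Degenerate cells return the unfit sentinel
#'   (`beta = NA`, `se = Inf`, `fitted = FALSE`).
#' @export
fit_transition_age <- function(rows, to_state,
                               covariates = default_covariates()) {
  .check_state(to_state, "to_state")
  y <- as.numeric(rows$to_state == to_state)
  n <- length(y)
  n_events <- sum(y)
  p <- length(covariates) + 1L
  if (n < p || n_events < 1 || n_events == n) {
    return(.sentinel_fit(covariates, n, n_events))
  }
  X <- .design_matrix(rows, covariates)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients) ||
      max(abs(fit$coefficients)) > 15) {
    if (!is.null(fit) && fit$converged &&
        !anyNA(fit$coefficients) && max(abs(fit$coefficients)) > 15) {
      warning(sprintf("possible separation fitting -> %s (n=%d, events=%d); cell marked unfit",
                      to_state, n, n_events), call. = FALSE)
    }
    return(.sentinel_fit(covariates, n, n_events))
  }
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(.sentinel_fit(covariates, n, n_events))
  se <- sqrt(pmax(diag(cov), 0))
  names(beta) <- names(se) <- .term_names(covariates)
  list(beta = beta, se = se, n_at_risk = n, n_events = n_events,
       fitted = TRUE)
}

#' Fit all transition cells over an age grid
#'
#' One logistic fit per allowed non-self transition and integer age in
#' `[age_range[1], age_range[2])`, on the at-risk, non-skip person-year
#' rows of each cell.  Each destination is fitted one-vs-rest among rows
#' currently in the from-state.
#'
#' @param person_years `data.table` from [expand_person_years()].
#' @param age_range Half-open integer age window, default `c(40, 80)`.
#' @param covariates Covariate names.
#' @param include_cad_death Also fit the CAD -> Death transition?  Off by
#'   default: risk is reported for CAD-free individuals.
#' @return A raw `coef_table`: `data.frame` with columns `from_state,
#'   to_state, age, term, beta, se, n_at_risk, n_events, variant`.
#' @export
fit_all <- function(person_years, age_range = c(40, 80),
                    covariates = default_covariates(),
                    include_cad_death = FALSE) {
  if (!(age_range[1] < age_range[2])) stop("age_range must be increasing")
  bad <- setdiff(covariates, default_covariates())
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  ts <- transition_set(include_cad_death)
  ts <- ts[ts$from_state != ts$to_state, , drop = FALSE]
  ages <- seq.int(age_range[1], age_range[2] - 1L)
  terms <- .term_names(covariates)

  py <- as.data.frame(person_years[person_years$at_risk & !person_years$skip, ])
  groups <- split(seq_len(nrow(py)), paste(py$from_state, py$age, sep = "."))

  out <- vector("list", nrow(ts) * length(ages))
  i <- 0L
  for (r in seq_len(nrow(ts))) {
    from <- ts$from_state[r]; to <- ts$to_state[r]
    for (a in ages) {
      key <- paste(from, a, sep = ".")
      ridx <- groups[[key]]
      fit <- if (is.null(ridx)) {
        .sentinel_fit(covariates, 0L, 0L)
      } else {
        fit_transition_age(py[ridx, , drop = FALSE], to, covariates)
      }
      i <- i + 1L
      out[[i]] <- data.frame(
        from_state = from, to_state = to, age = a, term = terms,
        beta = unname(fit$beta), se = unname(fit$se),
        n_at_risk = fit$n_at_risk, n_events = fit$n_events,
        variant = "raw", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("coef_table", class(tab))
  attr(tab, "covariates") <- covariates
  tab
}

#' Annual transition probability for one profile
#'
#' Inverse-logit of the linear predictor `X b`.
#'
#' @param beta Named coefficient vector (intercept first).
#' @param profile Named covariate values matching `beta` (intercept added
#'   automatically if absent).
#' @return Probability in (0, 1).
#' @export
predict_annual_probability <- function(beta, profile) {
  if (anyNA(beta)) {
    stop("missing coefficients (unfit cell); use a smoothed table",
         call. = FALSE)
  }
  terms <- names(beta)
  x <- stats::setNames(numeric(length(terms)), terms)
  x["intercept"] <- 1
  for (nm in setdiff(terms, "intercept")) {
    if (!nm %in% names(profile)) stop("profile missing covariate: ", nm)
    x[nm] <- as.numeric(profile[[nm]])
  }
  stats::plogis(sum(x * beta))
}

#' Serialize / deserialize a coefficient table
#'
#' Delimited text with columns `from_state, to_state, age, term, beta, se,
#' n_at_risk, n_events, variant`; numerics written with 17 significant
#' digits so the round trip is exact.
#'
#' @param tab Coefficient table.
#' @param path File path.
#' @return The read table, or the path invisibly.
#' @export
write_coef_table <- function(tab, path) {
  out <- as.data.frame(tab)
  for (col in c("beta", "se")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_coef_table
#' @export
read_coef_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$beta <- as.numeric(df$beta)
  df$se <- as.numeric(df$se)
  class(df) <- c("coef_table", class(df))
  attr(df, "covariates") <- setdiff(unique(df$term), "intercept")
  df
}
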