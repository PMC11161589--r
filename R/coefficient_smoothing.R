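# Locally weighted smoothing of age-varying coefficients.
#
# Each covariate's raw coefficient series across age is smoothed per
# transition by weighted least squares on a local polynomial basis, with
# weights combining a tricube-style distance taper and the inverse variance
# of each raw estimate.  Cells marked unfit (variance = Inf) get weight
# exactly zero, so sparse ages borrow strength from their neighbours
# without perturbing well-estimated ones.  Near the edges of the age grid
# the window is widened to mitigate boundary bias.

#' Smoother configuration
#'
#' @param window_width Half-width of the age window, years (> 0).
#' @param degree Local polynomial degree (>= 0).
#' @param boundary_extension Years added to the window when the target age
#'   is within this distance of the grid boundary.
#' @param classical_tricube Use the classical tricube `(1 - u^3)^3` taper
#'   instead of the default `1 - u^3`.
#' @return List of class `smoother_config`.
#' @export
smoother_config <- function(window_width = 10, degree = 2,
                            boundary_extension = 5,
                            classical_tricube = FALSE) {
  stopifnot(window_width > 0, degree >= 0, boundary_extension >= 0)
  structure(list(window_width = window_width, degree = as.integer(degree),
                 boundary_extension = boundary_extension,
                 classical_tricube = isTRUE(classical_tricube)),
            class = "smoother_config")
}

# effective window width at a target age
.adjusted_width <- function(target_age, grid_range, config) {
  near <- min(abs(target_age - grid_range)) <= config$boundary_extension
  config$window_width + if (near) config$boundary_extension else 0
}

#' Tricube-distance, inverse-variance weights
#'
#' `weight_i = taper(D_i / w_eff) / var_i` for neighbours with
#' `D_i = |target - age_i| <= w_eff`, zero elsewhere, where the taper is
#' `1 - u^3` (or classical tricube `(1 - u^3)^3`) and `w_eff` is the
#' window width, extended near the grid boundary.  Infinite-variance
#' (unfit) cells get weight exactly zero.
#'
#' @param target_age Age at which the smooth is evaluated.
#' @param neighbor_ages Ages of the raw estimates.
#' @param neighbor_variances Sampling variances of the raw estimates
#'   (`Inf` for unfit cells).
#' @param config `smoother_config`.
#' @param grid_range Range of the age grid (for boundary extension);
#'   defaults to the range of `neighbor_ages`.
#' @return Nonnegative weight vector aligned with `neighbor_ages` (zero
#'   outside the window).  Signals an error if no neighbour has positive
#'   weight.
#' @export
tricube_inverse_variance_weights <- function(target_age, neighbor_ages,
                                             neighbor_variances, config,
                                             grid_range = range(neighbor_ages)) {
  stopifnot(length(neighbor_ages) == length(neighbor_variances),
            all(neighbor_variances > 0))
  w_eff <- .adjusted_width(target_age, grid_range, config)
  D <- abs(target_age - neighbor_ages)
  u <- D / w_eff
  taper <- 1 - u^3
  if (config$classical_tricube) taper <- taper^3
  taper[D > w_eff] <- 0
  taper <- pmax(taper, 0)
  wt <- taper / neighbor_variances
  wt[!is.finite(neighbor_variances)] <- 0
  if (all(wt == 0)) {
    stop(sprintf("no neighbours with positive weight at age %s", target_age),
         call. = FALSE)
  }
  wt
}

#' Smooth one coefficient series across age
#'
#' At every target age, weighted least squares of the raw coefficients on
#' an age-centred polynomial basis up to `config$degree`, evaluated at the
#' target.  If the weighted design is rank deficient (all weight piled on
#' too few distinct ages) the degree is reduced for that target with a
#' warning.
#'
#' @param ages Integer age grid.
#' @param beta Raw coefficient values (`NA` at unfit cells).
#' @param variance Sampling variances (`Inf` at unfit cells).
#' @param config `smoother_config`.
#' @param grid_range Age-grid range for boundary extension.
#' @return List with `beta` (smoothed values) and `se` (approximate
#'   standard errors from the weighted normal equations).
#' @export
smooth_series <- function(ages, beta, variance, config = smoother_config(),
                          grid_range = range(ages)) {
  n <- length(ages)
  stopifnot(length(beta) == n, length(variance) == n)
  out_b <- numeric(n)
  out_se <- numeric(n)
  y_all <- beta
  for (i in seq_len(n)) {
    # sparse series: if no usable neighbour falls inside the window, widen
    # it (doubling) until one does, so every cell can borrow strength
    cfg_i <- config
    wt <- NULL
    repeat {
      wt <- tryCatch(
        tricube_inverse_variance_weights(ages[i], ages, variance, cfg_i,
                                         grid_range),
        error = function(e) NULL)
      if (!is.null(wt)) break
      if (cfg_i$window_width > diff(range(ages)) + 1) {
        stop(sprintf("no usable neighbours at age %s", ages[i]),
             call. = FALSE)
      }
      cfg_i$window_width <- cfg_i$window_width * 2
    }
    use <- wt > 0 & !is.na(y_all)
    deg <- min(config$degree, length(unique(ages[use])) - 1L)
    if (deg < config$degree) {
      warning(sprintf("degree reduced to %d at age %s (rank-deficient window)",
                      deg, ages[i]), call. = FALSE)
    }
    fit <- .wls_local(ages[use] - ages[i], y_all[use], wt[use], deg)
    out_b[i] <- fit$value
    out_se[i] <- fit$se
  }
  list(beta = out_b, se = out_se)
}

# weighted LS of y on centred polynomial basis; value at 0 is coef[1]
.wls_local <- function(x, y, w, degree) {
  X <- outer(x, 0:degree, `^`)
  sw <- sqrt(w)
  WX <- sw * X
  Wy <- sw * y
  XtX <- crossprod(WX)
  cf <- tryCatch(solve(XtX, crossprod(WX, Wy)), error = function(e) NULL)
  while (is.null(cf) && degree > 0) {
    degree <- degree - 1L
    X <- outer(x, 0:degree, `^`)
    WX <- sw * X
    XtX <- crossprod(WX)
    cf <- tryCatch(solve(XtX, crossprod(WX, Wy)), error = function(e) NULL)
  }
  if (is.null(cf)) stop("degenerate weighted design", call. = FALSE)
  cov1 <- tryCatch(solve(XtX)[1, 1], error = function(e) NA_real_)
  list(value = cf[1, 1], se = sqrt(max(cov1, 0)))
}

#' Smooth a raw coefficient table
#'
#' Applies [smooth_series()] independently to every (transition, term)
#' series of a raw table.  Sentinel cells are replaced by values borrowed
#' from neighbouring ages.  A transition with no successful fit at any age
#' is marked unavailable (dropped from the smoothed table and listed in
#' the `unavailable` attribute); the risk engine treats its probability as
#' zero with a warning.
#'
#' @param raw Raw `coef_table` from [fit_all()].
#' @param config `smoother_config`.
#' @return Smoothed `coef_table` (variant `"smoothed"`), with attribute
#'   `unavailable`: a `data.frame` of transitions that could not be
#'   smoothed.
#' @export
smooth_table <- function(raw, config = smoother_config()) {
  stopifnot(inherits(raw, "coef_table"))
  keys <- unique(raw[c("from_state", "to_state")])
  grid_range <- range(raw$age)
  pieces <- list()
  unavailable <- list()
  for (r in seq_len(nrow(keys))) {
    from <- keys$from_state[r]; to <- keys$to_state[r]
    sub <- raw[raw$from_state == from & raw$to_state == to, , drop = FALSE]
    if (all(!is.finite(sub$se))) {
      unavailable[[length(unavailable) + 1L]] <-
        data.frame(from_state = from, to_state = to)
      next
    }
    for (term in unique(sub$term)) {
      ss <- sub[sub$term == term, , drop = FALSE]
      ss <- ss[order(ss$age), , drop = FALSE]
      sm <- smooth_series(ss$age, ss$beta, ss$se^2, config, grid_range)
      ss$beta <- sm$beta
      ss$se <- sm$se
      ss$variant <- "smoothed"
      pieces[[length(pieces) + 1L]] <- ss
    }
  }
  tab <- if (length(pieces)) {
    do.call(rbind, pieces)
  } else {
    raw[0, , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("coef_table", "data.frame")
  attr(tab, "covariates") <- attr(raw, "covariates")
  attr(tab, "unavailable") <- if (length(unavailable)) {
    do.call(rbind, unavailable)
  } else {
    data.frame(from_state = character(0), to_state = character(0))
  }
  tab
}
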