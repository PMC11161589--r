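# State alphabet and one-year transition topology.
#
# Ten states: Health, the seven non-empty combinations of the three risk
# factors (hypertension Ht, hyperlipidemia HyperLip, diabetes Dm), CAD and
# Death.  Death is terminal-absorbing; CAD is quasi-absorbing (its only exit
# is CAD -> Death).  Risk factors accumulate monotonically: a state at
# risk-factor level m may move only to level-(m + 1) supersets of its own
# risk-factor set, to CAD, to Death, or stay put.

#' Canonical state labels
#'
#' The ten health states in canonical order.  Composite labels use the fixed
#' spellings `Ht&HyperLip`, `Ht&Dm`, `Dm&HyperLip`, `Ht&HyperLip&Dm` so that
#' serialized output is bit-stable.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' ms_states()
ms_states <- function() {
  c("Health", "Ht", "HyperLip", "Dm",
    "Ht&HyperLip", "Ht&Dm", "Dm&HyperLip", "Ht&HyperLip&Dm",
    "CAD", "Death")
}

#' Risk-factor names
#' @return Character vector `c("Ht", "HyperLip", "Dm")`.
#' @export
ms_risk_factors <- function() c("Ht", "HyperLip", "Dm")

# label -> risk-factor subset lookup (canonical label spellings)
.rf_sets <- list(
  "Health"         = character(0),
  "Ht"             = "Ht",
  "HyperLip"       = "HyperLip",
  "Dm"             = "Dm",
  "Ht&HyperLip"    = c("Ht", "HyperLip"),
  "Ht&Dm"          = c("Ht", "Dm"),
  "Dm&HyperLip"    = c("Dm", "HyperLip"),
  "Ht&HyperLip&Dm" = c("Ht", "HyperLip", "Dm"),
  "CAD"            = character(0),
  "Death"          = character(0)
)

.check_state <- function(label, arg = "state") {
  bad <- setdiff(label, ms_states())
  if (length(bad)) {
    stop(sprintf("unknown %s label: %s", arg,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(label)
}

#' Risk-factor set of a state
#'
#' @param label State label.
#' @return Character vector, subset of `ms_risk_factors()`; empty for
#'   Health, CAD and Death.
#' @export
state_rf_set <- function(label) {
  .check_state(label)
  .rf_sets[[label]]
}

#' Risk-factor level of a state
#'
#' Number of accumulated risk factors: 0 for Health, 1-3 for risk-factor
#' states, `NA` for CAD and Death (which are outside the accumulation
#' ladder).
#'
#' @param label State label (vectorized).
#' @return Integer vector.
#' @export
state_level <- function(label) {
  .check_state(label)
  vapply(label, function(l) {
    if (l %in% c("CAD", "Death")) return(NA_integer_)
    length(.rf_sets[[l]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Label of a risk-factor combination
#'
#' Maps a subset of risk factors to its canonical state label.
#'
#' @param rfs Character vector, subset of `ms_risk_factors()` (any order).
#' @return State label.
#' @export
rf_state_label <- function(rfs) {
  stopifnot(all(rfs %in% ms_risk_factors()))
  key <- paste(sort(rfs), collapse = "+")
  lab <- names(.rf_sets)[vapply(.rf_sets, function(s)
    identical(paste(sort(s), collapse = "+"), key), logical(1))]
  # Health shares the empty key with CAD/Death; take the first match (Health)
  lab[1]
}

#' Is a state absorbing?
#'
#' Only Death is terminal-absorbing.  CAD is quasi-absorbing: it persists
#' but still admits the CAD -> Death exit.
#'
#' @param label State label (vectorized).
#' @return Logical vector.
#' @export
state_absorbing <- function(label) {
  .check_state(label)
  label == "Death"
}

#' One-year transition set
#'
#' All legal (from, to) one-year transitions: self-loops for every
#' non-absorbing state; from each risk-factor level-m state, the
#' level-(m+1) supersets of its risk-factor set; CAD and Death reachable
#' from every non-CAD, non-Death state; CAD -> Death.
#'
#' @param include_cad_death Keep the CAD -> Death row (and the CAD
#'   self-loop)?  Risk reporting is on CAD-free individuals, so fitting this
#'   transition is optional, but the topology always contains it.
#' @return `data.frame` with columns `from_state`, `to_state`, ordered by
#'   from-state canonical order then to-state canonical order.
#' @export
transition_set <- function(include_cad_death = TRUE) {
  states <- ms_states()
  pairs <- list()
  for (from in states) {
    for (to in states) {
      if (.allowed_pair(from, to)) pairs[[length(pairs) + 1L]] <- c(from, to)
    }
  }
  out <- data.frame(
    from_state = vapply(pairs, `[`, character(1), 1L),
    to_state   = vapply(pairs, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  ord <- order(match(out$from_state, states), match(out$to_state, states))
  out <- out[ord, , drop = FALSE]
  if (!include_cad_death) {
    out <- out[out$from_state != "CAD", , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# core pair predicate, labels assumed valid
.allowed_pair <- function(from, to) {
  if (from == "Death") return(FALSE)
  if (from == to) return(TRUE)           # self-loop for every non-absorbing
  if (from == "CAD") return(to == "Death")
  # from is Health or a risk-factor state
  if (to %in% c("CAD", "Death")) return(TRUE)
  if (to == "Health") return(FALSE)
  to_rf <- .rf_sets[[to]]
  from_rf <- .rf_sets[[from]]
  length(to_rf) == length(from_rf) + 1L && all(from_rf %in% to_rf)
}

#' Is a one-year transition allowed?
#'
#' @param from_state,to_state State labels.
#' @return `TRUE` iff `(from_state, to_state)` is in the transition set.
#' @export
#' @examples
#' allowed("Health", "Ht")   # TRUE
#' allowed("Ht", "Health")   # FALSE (no recovery)
allowed <- function(from_state, to_state) {
  .check_state(from_state, "from_state")
  .check_state(to_state, "to_state")
  .allowed_pair(from_state, to_state)
}

#' Successor states of a state
#'
#' All states reachable in one year, self-loop included.  Death has no
#' successors.
#'
#' @param from_state State label.
#' @return Character vector in canonical order (possibly empty).
#' @export
successor_states <- function(from_state) {
  .check_state(from_state, "from_state")
  states <- ms_states()
  states[vapply(states, function(to) .allowed_pair(from_state, to),
                logical(1))]
}

#' Export the transition topology
#'
#' Writes the transition set as delimited text with columns
#' `from_state,to_state` for documentation and fixtures.
#'
#' @param path Output file path.
#' @param include_cad_death Passed to [transition_set()].
#' @return The path, invisibly.
#' @export
write_topology <- function(path, include_cad_death = TRUE) {
  utils::write.csv(transition_set(include_cad_death), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
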