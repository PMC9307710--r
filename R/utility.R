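#' Outcome utilities
#'
#' Utility values attached to the six lineup outcomes. The defaults follow
#' the convention that identifying an innocent suspect is by far the worst
#' outcome (-20), lure identifications that shield a guilty suspect are bad
#' (-5 in target-present lineups, -1 in target-absent ones), misses are
#' mildly bad (-1) and correct decisions are good (+2). These values are
#' deliberate but arbitrary weightings, not empirical quantities; users are
#' encouraged to substitute their own.
#'
#' @param TP1,TP2,TP3,TA1,TA2,TA3 Finite utility values for the six
#'   outcomes (hit; known-lure FA in target-present; miss; known-lure FA in
#'   target-absent; innocent-suspect FA; correct rejection).
#' @return An object of class `utility_spec` (named numeric vector).
#' @export
utility_spec <- function(TP1 = 2, TP2 = -5, TP3 = -1,
                         TA1 = -1, TA2 = -20, TA3 = 2) {
  u <- c(TP1 = TP1, TP2 = TP2, TP3 = TP3, TA1 = TA1, TA2 = TA2, TA3 = TA3)
  if (any(!is.finite(u))) stop("utilities must be finite")
  structure(u, class = "utility_spec")
}

#' Outcome profiles of identification procedures
#'
#' A procedure is summarised by its two outcome triples (target-present and
#' target-absent), each summing to 1. `procedure_outcomes()` builds one from
#' explicit proportions; structurally impossible outcomes (a showup has no
#' known lures) are entered as 0.
#'
#' `builtin_procedures()` returns the three published reference procedures
#' from the large no-stopping-rule experiment: the sequential lineup with
#' the stopping rule emulated (recomputed from the shipped frequency table
#' via [outcome_summary()]), the same lineup scored by the last "yes"
#' (stopping rule removed) and the showup, the latter two taken from the
#' published outcome percentages since their raw tables are not printed.
#'
#' @param label Procedure name.
#' @param tp,ta Length-3 probability triples (TP1..TP3, TA1..TA3).
#' @return An object of class `procedure_outcomes`.
#' @export
procedure_outcomes <- function(label, tp, ta) {
  stopifnot(length(tp) == 3L, length(ta) == 3L)
  if (abs(sum(tp) - 1) > 1e-9 || abs(sum(ta) - 1) > 1e-9)
    stop("outcome triples must each sum to 1")
  if (any(tp < 0) || any(ta < 0)) stop("outcome proportions must be nonnegative")
  structure(list(label = label,
                 tp = stats::setNames(tp, c("TP1", "TP2", "TP3")),
                 ta = stats::setNames(ta, c("TA1", "TA2", "TA3"))),
            class = "procedure_outcomes")
}

#' @rdname procedure_outcomes
#' @export
builtin_procedures <- function() {
  os <- outcome_summary(builtin_table("wilson"))
  list(
    lineup_sr = procedure_outcomes("Sequential lineup (stopping rule)",
                                   tp = unclass(os)[1:3], ta = unclass(os)[4:6]),
    lineup_nosr = procedure_outcomes("Sequential lineup (no stopping rule)",
                                     tp = c(.662, .249, .089),
                                     ta = unclass(os)[4:6]),
    showup = procedure_outcomes("Showup",
                                tp = c(.866, 0, .134),
                                ta = c(0, .264, .736)))
}

#' Expected utility of a procedure
#'
#' `U = P_guilty * sum(P_TPi * U_TPi) + (1 - P_guilty) * sum(P_TAi * U_TAi)`:
#' an affine function of the prior probability that the suspect is guilty.
#'
#' @param proc A [procedure_outcomes()].
#' @param spec A [utility_spec()].
#' @param p_guilty Probability (or vector of probabilities) in `[0, 1]`.
#' @return Expected utility value(s).
#' @export
expected_utility <- function(proc, spec = utility_spec(), p_guilty) {
  stopifnot(inherits(proc, "procedure_outcomes"))
  if (any(p_guilty < 0 | p_guilty > 1)) stop("'p_guilty' must lie in [0, 1]")
  u_tp <- sum(proc$tp * spec[1:3])
  u_ta <- sum(proc$ta * spec[4:6])
  p_guilty * u_tp + (1 - p_guilty) * u_ta
}

#' Probability-of-guilt crossover between two procedures
#'
#' Solves the linear equation `U_A(p) = U_B(p)` exactly. Because both
#' expected utilities are affine in `p_guilty` the crossover, when the
#' lines are not parallel, is unique.
#'
#' @param procA,procB [procedure_outcomes()] objects.
#' @param spec A [utility_spec()].
#' @return A list with `p_star` (the crossing point, possibly outside
#'   `[0, 1]`), `in_unit_interval`, and `status` (`"unique"`, `"parallel"`
#'   for distinct parallel lines, `"degenerate"` for identical lines).
#' @examples
#' pr <- builtin_procedures()
#' crossover(pr$lineup_sr, pr$showup)$p_star  # ~ 0.37
#' @export
crossover <- function(procA, procB, spec = utility_spec()) {
  a0 <- expected_utility(procA, spec, 0); a1 <- expected_utility(procA, spec, 1)
  b0 <- expected_utility(procB, spec, 0); b1 <- expected_utility(procB, spec, 1)
  slope_diff <- (a1 - a0) - (b1 - b0)
  inter_diff <- a0 - b0
  if (abs(slope_diff) < 1e-12) {
    status <- if (abs(inter_diff) < 1e-12) "degenerate" else "parallel"
    return(list(p_star = NA_real_, in_unit_interval = NA, status = status))
  }
  p <- -inter_diff / slope_diff
  list(p_star = p, in_unit_interval = p >= 0 && p <= 1, status = "unique")
}

#' Expected-utility curves over a guilt-probability grid
#'
#' Evaluates each procedure's expected utility across a grid of `p_guilty`
#' values and annotates which procedure dominates at each point.
#'
#' @param procs List of [procedure_outcomes()].
#' @param spec A [utility_spec()].
#' @param grid Numeric vector of probabilities in `[0, 1]`.
#' @return A data frame with one row per grid point: `p_guilty`, one
#'   utility column per procedure, and `best` (label of the maximiser).
#' @export
utility_curve <- function(procs, spec = utility_spec(),
                          grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(procs) >= 1L)
  if (any(grid < 0 | grid > 1)) stop("grid must lie within [0, 1]")
  u <- vapply(procs, expected_utility, numeric(length(grid)),
              spec = spec, p_guilty = grid)
  u <- matrix(u, nrow = length(grid))
  labels <- vapply(procs, function(p) p$label, "")
  colnames(u) <- labels
  data.frame(p_guilty = grid, u, best = labels[max.col(u, ties.method = "first")],
             check.names = FALSE)
}
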