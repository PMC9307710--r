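# Run code with a temporary RNG state so seeded routines neither depend on
# nor disturb the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic substream seed for unit j of a seeded computation; stays
# inside the 32-bit integer range.
derive_seed <- function(seed, j) {
  as.integer((as.double(seed) %% 65011 * 33013 + as.double(j) * 7919) %% 2147483629)
}

#' Multinomial G-squared badness of fit
#'
#' Deviance of observed counts against model cell probabilities, relative to
#' the saturated multinomial model: `2 * sum(O * log(O / E))` with expected
#' counts `E` equal to the condition total times the cell probability.
#' Zero-count cells contribute nothing; a zero expected count facing a
#' positive observed count is an infinite deviance and raises an error.
#'
#' @param observed A [lineup_table()].
#' @param expected Matrix of cell probabilities, categories by conditions,
#'   as returned by the probability functions (each column summing to 1).
#' @return The G-squared statistic.
#' @examples
#' tab <- builtin_table("wilson")
#' p <- sdt_params(mu_T = 1, tau0 = rep(0.2, 6))
#' g_squared(tab, cell_probabilities_by_condition(p, tab$design))
#' @export
g_squared <- function(observed, expected) {
  stopifnot(inherits(observed, "lineup_table"))
  expected <- as.matrix(expected)
  O <- observed$counts
  if (!all(dim(expected) == dim(O)))
    stop("expected probabilities must match the table's categories x conditions shape")
  E <- sweep(expected, 2L, observed$condition_totals, `*`)
  pos <- O > 0
  if (any(E[pos] <= 0))
    stop("expected count of 0 where observations are positive: infinite deviance")
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}

#' Cell probabilities for every lineup condition
#'
#' Convenience wrapper evaluating the appropriate probability function
#' (binary, confidence or mixture) for all `I + 1` conditions at once.
#'
#' @inheritParams censored_probabilities
#' @param mixture Logical; apply the serious/unserious mixture.
#' @return Matrix of probabilities, categories by conditions.
#' @export
cell_probabilities_by_condition <- function(params, design, mixture = FALSE) {
  cell_probability_matrix(params, design, mixture = mixture)
}

# Heuristic start: criteria from target-absent hazards, moderate
# discriminability, small positive shift kernel.
default_start <- function(layout, table) {
  design <- layout$design
  I <- design$I
  nm <- layout$par_names
  start <- stats::setNames(numeric(layout$n_free), nm)
  mu0 <- 1
  ta <- rowSums(matrix(table$counts[seq_len(I * design$K)], ncol = design$K,
                       byrow = TRUE) * 0) # placeholder, replaced below
  # collapse confidence bins to binary yes counts in the TA column
  ta_col <- table$counts[, I + 1L]
  yes_i <- if (design$K == 1L) ta_col[seq_len(I)] else
    colSums(matrix(ta_col[seq_len(I * design$K)], nrow = design$K))
  tot <- sum(ta_col)
  rem <- tot - c(0, cumsum(yes_i))[seq_len(I)]
  haz <- pmin(pmax(yes_i / pmax(rem, 1), 0.02), 0.98)
  tau_guess <- stats::qnorm(1 - haz) - mu0
  start["mu_T"] <- mu0
  if ("tau0" %in% nm) start["tau0"] <- mean(tau_guess)
  start[grep("^tau0_[0-9]$", nm)] <- tau_guess[seq_len(sum(grepl("^tau0_[0-9]$", nm)))]
  if ("tau0_1" %in% nm) start["tau0_1"] <- min(tau_guess)
  start[grep("^log_dtau_", nm)] <- log(0.05)
  if ("delta" %in% nm) start["delta"] <- 0.5
  if ("log_lambda" %in% nm) start["log_lambda"] <- log(0.5)
  start[grep("^log_kappa_", nm)] <- log(0.4)
  if ("logit_pi" %in% nm) start["logit_pi"] <- stats::qlogis(0.95)
  # log_sigma2_T, log_alpha*, log_xi*, log_omega, eta, gamma, log_zeta: 0
  start
}

#' Maximum-likelihood fit of an SDT model to a lineup table
#'
#' Minimises the negative multinomial log-likelihood over the model's
#' transformed (unbounded) free parameters with a quasi-Newton optimiser,
#' from a data-driven start plus seeded scattered restarts, and reports the
#' best local optimum. The criterion-shift kernel makes some models mildly
#' multimodal, so headline fits should use generous restarts.
#'
#' @param spec A [model_spec()].
#' @param table A [lineup_table()] whose design matches the spec (K = 1 for
#'   binary models, K >= 2 for confidence models).
#' @param restarts Number of additional randomised starts (>= 0).
#' @param seed Integer seed controlling the restart draws; the fit is a
#'   deterministic function of (spec, table, options).
#' @param tolerance Relative convergence tolerance on the objective.
#' @param start Optional free-vector start overriding the heuristic.
#' @return An object of class `sdt_fit`: the spec, `layout`, `estimates`
#'   ([sdt_params()]), `free` (free-vector optimum), `loglik`, `g_squared`,
#'   `df`, `p_value`, `aic`, `bic`, `n_restarts_used`, `converged` and
#'   `n_total`. AIC and BIC are on the G-squared scale
#'   (`AIC = G2 + 2p`, `BIC = G2 + p log(N)`).
#' @examples
#' \donttest{
#' fit <- fit_sdt(model_spec("tau1"), builtin_table("wilson"), restarts = 2)
#' round(fit$g_squared)  # 187
#' }
#' @export
fit_sdt <- function(spec, table, restarts = 10L, seed = 1L,
                    tolerance = 1e-10, start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(table, "lineup_table"))
  layout <- build_model(spec, table$design)
  design <- table$design
  O <- table$counts
  pos <- O > 0
  Opos <- O[pos]
  n_tot <- sum(table$condition_totals)
  ll_sat <- sum(Opos * log(Opos / rep(table$condition_totals, each = nrow(O))[pos]))
  nll <- make_nll(layout, table)
  starts <- list(if (is.null(start)) default_start(layout, table) else start)
  if (restarts > 0L) {
    jitter_mat <- with_seed(seed, matrix(stats::rnorm(restarts * layout$n_free,
                                                      sd = 0.6),
                                         nrow = restarts))
    for (j in seq_len(restarts))
      starts[[j + 1L]] <- starts[[1L]] + jitter_mat[j, ]
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(s, nll,
                    control = list(rel.tol = tolerance, iter.max = 1000L,
                                   eval.max = 4000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("optimisation failed from every start")
  est <- to_natural(layout, best$par)
  g2 <- 2 * (ll_sat + best$objective)
  p_count <- layout$n_free
  df <- (design$I + 1L) * design$I * design$K - p_count
  structure(list(spec = spec, layout = layout, estimates = est,
                 free = best$par, loglik = -best$objective,
                 g_squared = g2, df = df,
                 p_value = stats::pchisq(g2, df, lower.tail = FALSE),
                 aic = g2 + 2 * p_count,
                 bic = g2 + p_count * log(n_tot),
                 n_parameters = p_count,
                 n_restarts_used = length(starts) - 1L,
                 converged = any_conv, n_total = n_tot),
            class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("SDT fit:", format_model_spec(x$spec), "\n")
  cat(sprintf("  G2 = %.2f on %d df (p = %.3g), AIC = %.1f, BIC = %.1f\n",
              x$g_squared, x$df, x$p_value, x$aic, x$bic))
  cat(sprintf("  %d free parameters, N = %d, converged: %s\n",
              x$n_parameters, x$n_total, x$converged))
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' Compares a restricted model against the full model it is nested in on
#' the same data: the difference in G-squared is referred to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference.
#'
#' @param full,restricted `sdt_fit` objects on the same table.
#' @param check_nesting Verify the specs are nested (set `FALSE` only for
#'   custom nestings the rule-based check does not recognise).
#' @return A list with `delta_g2`, `df` and `p`.
#' @export
lr_test <- function(full, restricted, check_nesting = TRUE) {
  stopifnot(inherits(full, "sdt_fit"), inherits(restricted, "sdt_fit"))
  if (check_nesting && !is_nested_spec(restricted$spec, full$spec))
    stop("models are not nested: ", format_model_spec(restricted$spec),
         " vs ", format_model_spec(full$spec))
  d <- restricted$g_squared - full$g_squared
  if (d < -1e-6)
    warning("restricted model fits better than the full model; ",
            "refit with more restarts")
  df <- restricted$df - full$df
  list(delta_g2 = d, df = df,
       p = stats::pchisq(max(d, 0), df, lower.tail = FALSE))
}

#' The twenty binary models of the factorial family
#'
#' @return List of [model_spec()] objects in canonical order (criterion
#'   variant varying slowest, discriminability variant fastest).
#' @export
binary_family_specs <- function() {
  out <- list()
  for (crit in c("tau1", "tau2", "tau3", "tau4"))
    for (disc in c("null", "mu1", "sigma1", "mu2", "sigma2"))
      out[[length(out) + 1L]] <- model_spec(crit, disc)
  out
}

#' Model-selection table
#'
#' Fits a set of models to one table and tabulates parameter counts,
#' G-squared, AIC and BIC, flagging the AIC- and BIC-best models. Models
#' are reported in canonical order regardless of input order.
#'
#' @param specs List of [model_spec()] objects.
#' @param table A [lineup_table()].
#' @inheritParams fit_sdt
#' @return A data frame with one row per model and attribute `"fits"`
#'   holding the full `sdt_fit` objects.
#' @export
selection_table <- function(specs, table, restarts = 10L, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  crit_rank <- c(tau1 = 1L, tau2 = 2L, tau3 = 3L, tau4 = 4L)
  disc_rank <- c(null = 1L, mu1 = 2L, sigma1 = 3L, mu2 = 4L, sigma2 = 5L)
  ord <- order(vapply(specs, function(s) crit_rank[[s$criterion]], 1L),
               vapply(specs, function(s) disc_rank[[s$discriminability]], 1L),
               vapply(specs, format_model_spec, ""))
  specs <- specs[ord]
  fits <- vector("list", length(specs))
  for (i in seq_along(specs))
    fits[[i]] <- fit_sdt(specs[[i]], table, restarts = restarts,
                         seed = derive_seed(seed, i))
  df <- data.frame(
    model = vapply(specs, format_model_spec, ""),
    parameters = vapply(fits, function(f) f$n_parameters, 1L),
    g_squared = round(vapply(fits, function(f) f$g_squared, 1), 2),
    aic = round(vapply(fits, function(f) f$aic, 1), 2),
    bic = round(vapply(fits, function(f) f$bic, 1), 2),
    converged = vapply(fits, function(f) f$converged, TRUE))
  df$best_aic <- df$aic == min(df$aic)
  df$best_bic <- df$bic == min(df$bic)
  attr(df, "fits") <- fits
  df
}
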