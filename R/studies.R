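#' Published parameter estimates used as simulation defaults
#'
#' Point estimates from the reanalysis of the large no-stopping-rule study
#' that the simulation studies use as generating truths: the binary and the
#' confidence-rating fits of the position-varying-criteria model with the
#' target-rejection kernel (`tau4+null`), and the confidence fit of its
#' restricted mean-shift extension (`tau4+mu1`).
#'
#' The published confidence fits do not report the confidence-criterion
#' increments themselves, so confidence-generating parameter sets carry
#' equal increments (`kappa_default` in every cell), a package default
#' chosen to give a realistic spread of confidence responses; it is not an
#' estimate.
#'
#' @param set Which estimate set to return.
#' @param K Number of confidence levels for the confidence sets.
#' @param kappa_default Shared confidence increment for the confidence sets.
#' @return An [sdt_params()] object.
#' @export
reference_params <- function(set = c("wilson_binary_tau4",
                                     "wilson_confidence_tau4",
                                     "wilson_confidence_tau4_mu1"),
                             K = 4L, kappa_default = 0.5) {
  set <- match.arg(set)
  kap <- matrix(kappa_default, K - 1L, 6L)
  switch(set,
    wilson_binary_tau4 = sdt_params(
      mu_T = 0.91, sigma2_T = 1.03,
      tau0 = c(-0.01, 0.09, -0.07, -0.09, 0.06, 0.11),
      delta = 1.07, lambda = 0.50),
    wilson_confidence_tau4 = sdt_params(
      mu_T = 0.77, sigma2_T = 0.51,
      tau0 = c(0.13, 0.22, 0.08, 0.05, 0.20, 0.25),
      delta = 1.04, lambda = 0.49,
      kappa = kap, omega = 1.44, eta = -0.03, gamma = 0.12),
    wilson_confidence_tau4_mu1 = sdt_params(
      mu_T = 0.76, sigma2_T = 0.51, alpha = 1.02,
      tau0 = c(0.13, 0.21, 0.08, 0.05, 0.20, 0.25),
      delta = 1.05, lambda = 0.49,
      kappa = kap, omega = 1.37, eta = -0.04, gamma = 0.11))
}

#' Condition sample sizes of the large no-stopping-rule study
#'
#' @return Named vector of lineups per condition (tp1..tp6, ta).
#' @export
wilson_condition_totals <- function() {
  stats::setNames(c(709, 696, 691, 699, 696, 701, 4151),
                  condition_labels(lineup_design(6L)))
}

new_study_result <- function(study, replicates, summary, reps, seed, config) {
  structure(list(study = study, replicates = replicates, summary = summary,
                 reps = reps, seed = seed, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", x$study, sprintf("(%d replicates, seed %d)\n",
                                            x$reps, x$seed))
  print(x$summary)
  invisible(x)
}

#' Power to detect position effects on discriminability
#'
#' Simulates data from the mean-shift model (`tau4+mu1`) with the
#' discriminability factor `alpha` for positions 2..I fixed at each value
#' in `alpha_values` (1 is the null), fits the constant-discriminability
#' model and the mean-shift model to each replicate, and records the
#' likelihood-ratio deviance difference. The summary reports the percentage
#' of replicates significant at `p < .05` on the 1-df chi-squared
#' reference.
#'
#' @param alpha_values Generating values of the position-2+ mean factor.
#' @param reps Replicates per value.
#' @param n_per_condition Lineups per condition (scalar or length-7
#'   vector); defaults to the published study's condition totals.
#' @param seed Integer seed.
#' @param response_mode `"binary"` or `"confidence"` (K = 4) generation and
#'   fitting.
#' @param restarts Optimiser restarts per fit.
#' @return A `study_result`; `replicates` has one row per (alpha, rep) with
#'   the deviance difference and p-value.
#' @export
dfd_power_study <- function(alpha_values = c(1, 1.05, 1.10), reps = 200L,
                            n_per_condition = wilson_condition_totals(),
                            seed = 1L,
                            response_mode = c("confidence", "binary"),
                            restarts = 1L) {
  response_mode <- match.arg(response_mode)
  conf <- response_mode == "confidence"
  design <- lineup_design(6L, K = if (conf) 4L else 1L)
  base <- reference_params("wilson_confidence_tau4_mu1")
  if (!conf) base$kappa <- NULL
  spec0 <- model_spec("tau4", "null", confidence = conf)
  spec1 <- model_spec("tau4", "mu1", confidence = conf)
  rows <- list()
  for (a in alpha_values) {
    gen <- base
    gen$alpha <- c(1, rep(a, 5L))
    for (r in seq_len(reps)) {
      s <- derive_seed(seed, length(rows) + 1L)
      tab <- simulate_table(gen, design, n_per_condition, seed = s)
      f0 <- fit_sdt(spec0, tab, restarts = restarts, seed = s)
      f1 <- fit_sdt(spec1, tab, restarts = restarts, seed = s,
                    start = c(f0$free[1:2], 0, f0$free[-(1:2)]))
      d <- max(f0$g_squared - f1$g_squared, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, rep = r, delta_g2 = d,
        p = stats::pchisq(d, 1L, lower.tail = FALSE))
    }
  }
  repl <- do.call(rbind, rows)
  summ <- stats::aggregate(p ~ alpha, repl, function(p) 100 * mean(p < 0.05))
  names(summ)[2L] <- "pct_significant"
  new_study_result("DFD power", repl, summ, reps, seed,
                   list(alpha_values = alpha_values, mode = response_mode,
                        n_per_condition = n_per_condition))
}

#' Recovery of discriminability from binary judgments
#'
#' Draws per-replicate `(mu_T, sigma2_T)` from independent uniforms,
#' simulates a binary table from the `tau4+null` model (other parameters at
#' the published confidence-fit estimates), refits the model and compares
#' the true and estimated discriminability index [d_a()] by Spearman rank
#' correlation.
#'
#' @param mu_range,sigma2_range Uniform ranges for the generating draws.
#' @param reps Number of replicates.
#' @param n_per_condition Lineups per condition.
#' @inheritParams dfd_power_study
#' @return A `study_result`; `summary` holds the rank correlation.
#' @export
da_recovery_study <- function(mu_range = c(0.2, 1.40),
                              sigma2_range = c(0.3, 1.2),
                              reps = 200L, n_per_condition = 100L,
                              seed = 1L, restarts = 1L) {
  stopifnot(reps > 1L)
  design <- lineup_design(6L)
  base <- reference_params("wilson_confidence_tau4")
  base$kappa <- NULL
  spec <- model_spec("tau4", "null")
  draws <- with_seed(derive_seed(seed, 0L), cbind(
    mu = stats::runif(reps, mu_range[1L], mu_range[2L]),
    s2 = stats::runif(reps, sigma2_range[1L], sigma2_range[2L])))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    gen <- base
    gen$mu_T <- draws[r, "mu"]
    gen$sigma2_T <- draws[r, "s2"]
    s <- derive_seed(seed, r)
    tab <- simulate_table(gen, design, n_per_condition, seed = s)
    fit <- fit_sdt(spec, tab, restarts = restarts, seed = s)
    rows[[r]] <- data.frame(rep = r, true_da = d_a(gen),
                            est_da = d_a(fit$estimates),
                            converged = fit$converged)
  }
  repl <- do.call(rbind, rows)
  rho <- stats::cor(repl$true_da, repl$est_da, method = "spearman")
  new_study_result("d_a recovery", repl,
                   data.frame(rank_correlation = rho), reps, seed,
                   list(mu_range = mu_range, sigma2_range = sigma2_range,
                        n_per_condition = n_per_condition))
}

# Joint two-group fit of tau4+null with the discriminability block
# (mu_T, sigma2_T) and/or the criteria block (tau0, delta, lambda) shared.
fit_two_groups <- function(tabA, tabB, share_disc, share_crit,
                           restarts = 1L, seed = 1L) {
  design <- tabA$design
  lay <- build_model(model_spec("tau4"), design)
  n_d <- 2L; n_c <- 8L
  n_free <- n_d * (2L - share_disc) + n_c * (2L - share_crit)
  split_free <- function(v) {
    dA <- v[1:2]
    i <- 2L
    dB <- if (share_disc) dA else { i <- 4L; v[3:4] }
    cA <- v[(i + 1L):(i + 8L)]
    cB <- if (share_crit) cA else v[(i + 9L):(i + 16L)]
    list(A = c(dA, cA), B = c(dB, cB))
  }
  nllA <- make_nll(lay, tabA); nllB <- make_nll(lay, tabB)
  nll <- function(v) { f <- split_free(v); nllA(f$A) + nllB(f$B) }
  sA <- default_start(lay, tabA); sB <- default_start(lay, tabB)
  start <- c(sA[1:2], if (!share_disc) sB[1:2],
             sA[3:10], if (!share_crit) sB[3:10])
  starts <- list(start)
  if (restarts > 0L) {
    jit <- with_seed(seed, matrix(stats::rnorm(restarts * n_free, sd = 0.5),
                                  nrow = restarts))
    for (j in seq_len(restarts)) starts[[j + 1L]] <- start + jit[j, ]
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(stats::nlminb(s, nll,
                                  control = list(rel.tol = 1e-10,
                                                 iter.max = 1000L,
                                                 eval.max = 4000L)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  sat <- function(tab) {
    O <- tab$counts; pos <- O > 0
    sum(O[pos] * log(O[pos] / rep(tab$condition_totals, each = nrow(O))[pos]))
  }
  list(g_squared = 2 * (sat(tabA) + sat(tabB) + best$objective),
       n_parameters = n_free, free = best$par)
}

#' Identifying the source of a difference between two groups
#'
#' For each scenario, simulates binary lineup data for groups A and B from
#' the `tau4+null` model (generating truths at the published confidence-fit
#' estimates), with group B optionally 10% lower in `mu_T`
#' (discriminability scenarios) and/or shifted by 0.20 in every response
#' criterion (criteria scenarios; `plus` = more lenient, i.e. criteria
#' lowered, `minus` = stricter). Four joint models -- sharing or freeing
#' the discriminability block `(mu_T, sigma2_T)` and the criteria block
#' `(tau0, delta, lambda)` -- are fitted to each replicate, and the
#' equal-discriminability (2 df) and equal-criteria (8 df) hypotheses are
#' tested by likelihood ratio at `p < .05`.
#'
#' @param scenarios Character vector drawn from `"none"`,
#'   `"discriminability"`, `"criteria_plus"`, `"criteria_minus"`,
#'   `"both_plus"`, `"both_minus"`.
#' @param reps Replicates per scenario.
#' @param n_per_condition Lineups per condition in each group.
#' @inheritParams dfd_power_study
#' @return A `study_result`; `summary` reports the rejection percentages of
#'   both equality hypotheses per scenario.
#' @export
group_difference_study <- function(scenarios = c("none", "discriminability",
                                                 "criteria_minus", "criteria_plus",
                                                 "both_minus", "both_plus"),
                                   reps = 200L, n_per_condition = 500L,
                                   seed = 1L, restarts = 1L) {
  stopifnot(length(scenarios) >= 1L)
  design <- lineup_design(6L)
  base <- reference_params("wilson_confidence_tau4")
  base$kappa <- NULL
  rows <- list()
  for (sc in scenarios) {
    genB <- base
    if (grepl("discriminability|both", sc)) genB$mu_T <- 0.9 * base$mu_T
    if (grepl("plus", sc)) genB$tau0 <- base$tau0 - 0.20
    if (grepl("minus", sc)) genB$tau0 <- base$tau0 + 0.20
    for (r in seq_len(reps)) {
      s <- derive_seed(seed, length(rows) + 1L)
      tabA <- simulate_table(base, design, n_per_condition, seed = s)
      tabB <- simulate_table(genB, design, n_per_condition,
                             seed = derive_seed(s, 99L))
      both <- fit_two_groups(tabA, tabB, FALSE, FALSE, restarts, s)
      crit_only <- fit_two_groups(tabA, tabB, TRUE, FALSE, restarts, s)
      disc_only <- fit_two_groups(tabA, tabB, FALSE, TRUE, restarts, s)
      d_disc <- max(crit_only$g_squared - both$g_squared, 0)
      d_crit <- max(disc_only$g_squared - both$g_squared, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, rep = r,
        delta_g2_disc = d_disc,
        p_disc = stats::pchisq(d_disc, 2L, lower.tail = FALSE),
        delta_g2_crit = d_crit,
        p_crit = stats::pchisq(d_crit, 8L, lower.tail = FALSE))
    }
  }
  repl <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(repl, repl$scenario), function(d)
    data.frame(scenario = d$scenario[1L],
               pct_reject_discriminability = 100 * mean(d$p_disc < 0.05),
               pct_reject_criteria = 100 * mean(d$p_crit < 0.05))))
  summ <- summ[match(unique(repl$scenario), summ$scenario), ]
  rownames(summ) <- NULL
  new_study_result("two-group hypothesis identification", repl, summ, reps,
                   seed, list(scenarios = scenarios,
                              n_per_condition = n_per_condition))
}

#' The three reference heterogeneous populations
#'
#' Population specifications for the selection-bias simulations: (1) only
#' the criterion varies (`tau0 ~ U[-0.25, 1]`, `mu_T = 0.75`); (2) both
#' vary (`mu_T ~ U[0.10, 1.40]`); (3) criteria follow per-witness
#' likelihood ratios (`LR ~ U[0.75, 2]`) with `mu_T` as in (2). All use
#' unit variances and the fixed-criterion model within witness.
#'
#' @return Named list of three [population_spec()] objects.
#' @export
selection_bias_specs <- function() {
  list(sim1 = population_spec(mu_T = 0.75, tau0 = c(-0.25, 1)),
       sim2 = population_spec(mu_T = c(0.10, 1.40), tau0 = c(-0.25, 1)),
       sim3 = population_spec(mu_T = c(0.10, 1.40), lr_range = c(0.75, 2)))
}

#' Can aggregation mimic target-rejection effects?
#'
#' Simulates each heterogeneous population, aggregates the censored
#' responses and computes the target-rejection hazard contrasts of
#' [hazard_differences()]. Since no simulated witness ever shifts their
#' criterion, any nonzero pattern is pure aggregation (selection) bias.
#'
#' @param pop_specs List of [population_spec()] objects.
#' @param n_witnesses Total synthetic witnesses per population, split
#'   equally across the `I + 1` conditions.
#' @param seed Integer seed.
#' @param design A binary [lineup_design()].
#' @return A `study_result`; `summary` gives each population's mean hazard
#'   difference, and `replicates` holds the full difference matrices.
#' @export
selection_bias_study <- function(pop_specs = selection_bias_specs(),
                                 n_witnesses = 100000L, seed = 1L,
                                 design = lineup_design(6L)) {
  n_cond <- design$I + 1L
  n_each <- floor(n_witnesses / n_cond)
  mats <- vector("list", length(pop_specs))
  for (k in seq_along(pop_specs)) {
    tab <- simulate_population(pop_specs[[k]], design, n_each,
                               seed = derive_seed(seed, k))
    mats[[k]] <- hazard_differences(tab)
  }
  names(mats) <- names(pop_specs)
  summ <- data.frame(
    population = names(mats),
    mean_difference = vapply(mats, function(m) mean(m, na.rm = TRUE), 1))
  rownames(summ) <- NULL
  new_study_result("selection bias", mats, summ, 1L, seed,
                   list(n_witnesses = n_witnesses))
}

# History strata: which of the 2^I sequences share the first i-1 responses.
history_key <- function(seqs, i) {
  if (i == 1L) rep("", nrow(seqs))
  else apply(seqs[, seq_len(i - 1L), drop = FALSE], 1L, paste, collapse = "")
}

#' Test the i.i.d. assumption at one sequence position
#'
#' Tests whether the probability of a "yes" at position `i` is the same
#' across all `2^(i-1)` preceding response histories, using uncensored
#' sequence counts: a G-squared independence test of response by history.
#' Marginal-response analyses assume this invariance implicitly; censored
#' analyses never need it.
#'
#' @param seq_counts Uncensored sequence counts as from
#'   [simulate_uncensored()].
#' @param i Sequence position (>= 2 for a nontrivial test).
#' @param face_type `"target"` (uses the condition with the target at `i`)
#'   or `"lure"` (uses the target-absent condition).
#' @return A list with `g2`, `df`, `p` and `proportions` (per-history "yes"
#'   rates). Empty history strata are dropped with a warning and the
#'   degrees of freedom adjusted.
#' @export
iid_position_test <- function(seq_counts, i, face_type = c("target", "lure")) {
  face_type <- match.arg(face_type)
  I <- as.integer(log2(nrow(seq_counts)))
  stopifnot(i >= 1L, i <= I)
  seqs <- uncensored_sequences(I)
  col <- if (face_type == "target") i else I + 1L
  key <- history_key(seqs, i)
  yes <- tapply(seq_counts[, col] * (seqs[, i] == 1L), key, sum)
  tot <- tapply(seq_counts[, col], key, sum)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sum(!keep), " empty history stratum(ta) dropped; df adjusted")
    yes <- yes[keep]; tot <- tot[keep]
  }
  prop <- yes / tot
  phat <- sum(yes) / sum(tot)
  terms <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g2 <- 2 * sum(terms(yes, tot * phat) + terms(tot - yes, tot * (1 - phat)))
  df <- length(tot) - 1L
  list(g2 = g2, df = df,
       p = stats::pchisq(g2, df, lower.tail = FALSE),
       proportions = prop)
}

#' Pre/post-first-"yes" signal detection analysis
#'
#' Pairs the "yes" rates to targets (condition with the target at position
#' `i`) and to lures (target-absent condition) at each position `i = 2..I`,
#' split by whether at least one "yes" was made before `i`, and fits a
#' conventional unequal-variance yes/no SDT model: lures `N(0, 1)`, targets
#' `N(mu_s, sigma2_s)` with separate `(mu, sigma2)` per stratum and a
#' criterion per (position, stratum). Likelihood-ratio tests compare the
#' full model against equal discriminability across strata (2 df) and
#' equal criteria (5 df for I = 6).
#'
#' @param seq_counts Uncensored sequence counts as from
#'   [simulate_uncensored()].
#' @param restarts Optimiser restarts.
#' @param seed Integer seed for the restarts.
#' @return A list with per-stratum `d_a`, their difference, mean criterion
#'   difference, the full fit's `g2`/`df`/`p`, both LR tests and the
#'   underlying rate table.
#' @export
prepost_binary_sdt <- function(seq_counts, restarts = 2L, seed = 1L) {
  I <- as.integer(log2(nrow(seq_counts)))
  seqs <- uncensored_sequences(I)
  positions <- 2:I
  cell <- function(i, stratum, col) {
    key <- history_key(seqs, i)
    prior_yes <- vapply(strsplit(key, ""), function(k) any(k == "1"), TRUE)
    pick <- if (stratum == "post") prior_yes else !prior_yes
    c(yes = sum(seq_counts[pick & seqs[, i] == 1L, col]),
      n = sum(seq_counts[pick, col]))
  }
  rows <- list()
  for (i in positions) for (s in c("pre", "post")) {
    hit <- cell(i, s, i); fa <- cell(i, s, I + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      position = i, stratum = s,
      hit_yes = hit["yes"], hit_n = hit["n"],
      fa_yes = fa["yes"], fa_n = fa["n"])
  }
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  if (any(rates$hit_n == 0 | rates$fa_n == 0))
    stop("every (position, stratum) cell needs observations in both lineup types")
  np <- length(positions)
  # free vector: mu_pre, log s2_pre, mu_post, log s2_post, tau[np x 2]
  nll_full <- function(v) nll_generic(v[1:2], v[3:4], v[5:(4 + np)],
                                      v[(5 + np):(4 + 2 * np)])
  nll_generic <- function(dpre, dpost, tau_pre, tau_post) {
    tot <- 0
    for (r in seq_len(nrow(rates))) {
      post <- rates$stratum[r] == "post"
      d <- if (post) dpost else dpre
      tau <- (if (post) tau_post else tau_pre)[rates$position[r] - 1L]
      p_hit <- stats::pnorm((tau - d[1L]) / sqrt(exp(d[2L])), lower.tail = FALSE)
      p_fa <- stats::pnorm(tau, lower.tail = FALSE)
      ll <- function(y, n, p) {
        p <- min(max(p, 1e-12), 1 - 1e-12)
        y * log(p) + (n - y) * log(1 - p)
      }
      tot <- tot + ll(rates$hit_yes[r], rates$hit_n[r], p_hit) +
        ll(rates$fa_yes[r], rates$fa_n[r], p_fa)
    }
    -tot
  }
  fit_nll <- function(fn, n_free, start) {
    starts <- list(start)
    if (restarts > 0L) {
      jit <- with_seed(seed, matrix(stats::rnorm(restarts * n_free, sd = 0.4),
                                    nrow = restarts))
      for (j in seq_len(restarts)) starts[[j + 1L]] <- start + jit[j, ]
    }
    best <- NULL
    for (s in starts) {
      o <- tryCatch(stats::nlminb(s, fn, control = list(rel.tol = 1e-12,
                                                        iter.max = 1000L)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$objective < best$objective))
        best <- o
    }
    best
  }
  st_full <- c(1, 0, 1, 0, rep(0.5, 2 * np))
  full <- fit_nll(nll_full, 4L + 2L * np, st_full)
  # saturated binomial loglik
  ll_sat <- sum(apply(rates, 1L, function(r) {
    r <- as.list(r)
    f <- function(y, n) {
      y <- as.numeric(y); n <- as.numeric(n)
      p <- (y + 0.5) / (n + 1) # continuity guard only for degenerate cells
      if (y > 0 && y < n) p <- y / n
      y * log(p) + (n - y) * log(1 - p)
    }
    f(r$hit_yes, r$hit_n) + f(r$fa_yes, r$fa_n)
  }))
  g2_of <- function(opt) 2 * (ll_sat + opt$objective)
  # equal discriminability: shared (mu, s2)
  nll_eqd <- function(v) nll_generic(v[1:2], v[1:2], v[3:(2 + np)],
                                     v[(3 + np):(2 + 2 * np)])
  eqd <- fit_nll(nll_eqd, 2L + 2L * np, c(1, 0, rep(0.5, 2 * np)))
  # equal criteria: shared tau across strata
  nll_eqc <- function(v) nll_generic(v[1:2], v[3:4], v[5:(4 + np)],
                                     v[5:(4 + np)])
  eqc <- fit_nll(nll_eqc, 4L + np, c(1, 0, 1, 0, rep(0.5, np)))
  da_of <- function(mu, ls2) mu / sqrt((1 + exp(ls2)) / 2)
  v <- full$par
  tau_pre <- v[5:(4 + np)]; tau_post <- v[(5 + np):(4 + 2 * np)]
  g2_full <- g2_of(full)
  df_full <- 4L * np - (4L + 2L * np)
  d_disc <- max(g2_of(eqd) - g2_full, 0)
  d_crit <- max(g2_of(eqc) - g2_full, 0)
  list(d_a_pre = da_of(v[1L], v[2L]), d_a_post = da_of(v[3L], v[4L]),
       d_a_difference = da_of(v[1L], v[2L]) - da_of(v[3L], v[4L]),
       mean_tau_difference = mean(tau_post) - mean(tau_pre),
       g2 = g2_full, df = df_full,
       p = stats::pchisq(g2_full, df_full, lower.tail = FALSE),
       lr_discriminability = list(delta_g2 = d_disc, df = 2L,
                                  p = stats::pchisq(d_disc, 2L, lower.tail = FALSE)),
       lr_criteria = list(delta_g2 = d_crit, df = np,
                          p = stats::pchisq(d_crit, np, lower.tail = FALSE)),
       rates = rates)
}
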