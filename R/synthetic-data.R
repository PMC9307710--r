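#' Simulate a censored lineup table from a model
#'
#' Draws independent multinomial samples of censored responses for every
#' lineup condition from the exact cell probabilities of a parameter set.
#' Each condition uses its own deterministic substream of the seed, so
#' enlarging the design does not perturb earlier conditions.
#'
#' @param params An [sdt_params()] set.
#' @param design A [lineup_design()].
#' @param n_per_condition Number of lineups per condition: a scalar or a
#'   length-`I + 1` vector ordered `tp1..tpI, ta`.
#' @param seed Integer seed; the result is a pure function of
#'   (params, design, n, seed).
#' @param mixture Logical; sample from [mixture_probabilities()].
#' @return A [lineup_table()].
#' @examples
#' p <- sdt_params(mu_T = 0.9, tau0 = rep(0.2, 6), delta = 1, lambda = 0.5)
#' simulate_table(p, lineup_design(6), 500, seed = 1)
#' @export
simulate_table <- function(params, design, n_per_condition, seed,
                           mixture = FALSE) {
  stopifnot(inherits(params, "sdt_params"), inherits(design, "lineup_design"))
  n_cond <- design$I + 1L
  n <- rep_len(n_per_condition, n_cond)
  if (any(n < 0)) stop("'n_per_condition' must be nonnegative")
  P <- cell_probability_matrix(params, design, mixture = mixture)
  counts <- matrix(0, nrow(P), n_cond)
  for (j in seq_len(n_cond)) {
    if (n[j] > 0)
      counts[, j] <- with_seed(derive_seed(seed, j),
                               stats::rmultinom(1L, n[j], P[, j])[, 1L])
  }
  lineup_table(counts, design)
}

#' Specify a heterogeneous witness population
#'
#' Describes per-witness parameter distributions for aggregation and
#' selection-bias simulations. Each witness holds one discriminability and
#' one criterion throughout their lineup (the fixed-criterion,
#' fixed-discriminability model); heterogeneity lives across witnesses.
#'
#' @param mu_T Either a single value or a range `c(a, b)` for a uniform
#'   per-witness draw of the target mean.
#' @param tau0 Either a single value or a range `c(a, b)` for a uniform
#'   per-witness criterion; ignored when `lr_range` is given.
#' @param lr_range Optional range `c(a, b)` (> 0) of per-witness likelihood
#'   ratios; each witness places their criterion where the target/lure
#'   density ratio equals their LR (closed form `log(LR) / (2 mu_T)` under
#'   equal unit variances).
#' @param sigma2_T,sigma2_L Fixed variances (defaults 1, 1).
#' @param contamination Optional `c(pi, zeta)`: with probability `1 - pi` a
#'   witness always identifies the first face.
#' @param stopping_rule Logical; censor at the first "yes" (the default
#'   observable).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(mu_T, tau0 = 0, lr_range = NULL,
                            sigma2_T = 1, sigma2_L = 1,
                            contamination = NULL, stopping_rule = TRUE) {
  chk_range <- function(x, what) {
    if (!length(x) %in% 1:2 || any(!is.finite(x)))
      stop("'", what, "' must be a finite value or range")
    if (length(x) == 2L && x[2L] < x[1L]) stop("'", what, "' range reversed")
    x
  }
  mu_T <- chk_range(mu_T, "mu_T")
  tau0 <- chk_range(tau0, "tau0")
  if (!is.null(lr_range)) {
    lr_range <- chk_range(lr_range, "lr_range")
    if (any(lr_range <= 0)) stop("likelihood ratios must be positive")
  }
  if (!is.null(contamination)) {
    stopifnot(length(contamination) == 2L,
              contamination[1L] >= 0, contamination[1L] <= 1,
              contamination[2L] >= 0)
  }
  structure(list(mu_T = mu_T, tau0 = tau0, lr_range = lr_range,
                 sigma2_T = sigma2_T, sigma2_L = sigma2_L,
                 contamination = contamination,
                 stopping_rule = stopping_rule),
            class = "population_spec")
}

draw_uniform <- function(x, n) if (length(x) == 1L) rep(x, n) else stats::runif(n, x[1L], x[2L])

# Criterion placed where f_T(x)/f_L(x) = LR. With equal variances this is
# log(LR)/(2 mu_T); otherwise the root of the quadratic density-ratio
# equation on the rising segment between the means.
lr_criterion <- function(lr, mu_T, sigma2_T = 1, sigma2_L = 1) {
  if (any(mu_T == 0)) stop("likelihood-ratio placement is undefined at mu_T = 0")
  if (sigma2_T == sigma2_L) return(sigma2_T * log(lr) / (2 * mu_T))
  out <- numeric(length(lr))
  for (i in seq_along(lr)) {
    g <- function(x) stats::dnorm(x, mu_T[i], sqrt(sigma2_T)) /
      stats::dnorm(x, -mu_T[i], sqrt(sigma2_L)) - lr[i]
    out[i] <- stats::uniroot(g, lower = -mu_T[i], upper = mu_T[i],
                             extendInt = "upX", tol = 1e-10)$root
  }
  out
}

#' Simulate an aggregate table from a heterogeneous population
#'
#' Generates individual witnesses with private (`mu_T`, `tau0`) draws, lets
#' each respond to one lineup under the fixed-criterion SDT model (latent
#' strengths compared to the private criterion, censored at the first "yes"
#' when the stopping rule is on), and aggregates the censored responses into
#' a table. This is the machinery behind the selection-bias analyses: even
#' though no individual shifts their criterion after rejecting the target,
#' aggregation over heterogeneous witnesses can distort conditional rates.
#'
#' @param pop A [population_spec()].
#' @param design A binary [lineup_design()].
#' @param n_witnesses_per_condition Witnesses per lineup condition.
#' @param seed Integer seed.
#' @return A [lineup_table()] of aggregate censored counts.
#' @export
simulate_population <- function(pop, design, n_witnesses_per_condition, seed) {
  stopifnot(inherits(pop, "population_spec"), inherits(design, "lineup_design"))
  if (design$K != 1L) stop("population simulation generates binary tables")
  I <- design$I
  n <- n_witnesses_per_condition
  counts <- matrix(0, I + 1L, I + 1L)
  for (j in seq_len(I + 1L)) {
    h <- if (j <= I) j else NA_integer_
    counts[, j] <- with_seed(derive_seed(seed, j), {
      mu <- draw_uniform(pop$mu_T, n)
      tau <- if (is.null(pop$lr_range)) draw_uniform(pop$tau0, n)
             else lr_criterion(draw_uniform(pop$lr_range, n), mu,
                               pop$sigma2_T, pop$sigma2_L)
      # latent strengths: lures at -mu, the target (column h) at +mu
      means <- matrix(-mu, n, I)
      sds <- matrix(sqrt(pop$sigma2_L), n, I)
      if (!is.na(h)) { means[, h] <- mu; sds[, h] <- sqrt(pop$sigma2_T) }
      strength <- matrix(stats::rnorm(n * I), n, I) * sds + means
      yes <- strength > tau
      first <- apply(yes, 1L, function(r) { w <- which(r); if (length(w)) w[1L] else I + 1L })
      if (!is.null(pop$contamination)) {
        unserious <- stats::runif(n) >= pop$contamination[1L]
        first[unserious] <- 1L
      }
      tabulate(first, nbins = I + 1L)
    })
  }
  lineup_table(counts, design)
}

#' Simulate uncensored response sequences
#'
#' Samples full yes/no sequences (no stopping rule) from
#' [uncensored_probabilities()]: multinomial draws over the `2^I` sequences,
#' independently per condition with deterministic substreams.
#'
#' @inheritParams uncensored_probabilities
#' @inheritParams simulate_table
#' @return Integer matrix of sequence counts, `2^I` rows (named by response
#'   string) by `I + 1` condition columns.
#' @export
simulate_uncensored <- function(pre, post = pre, design, n_per_condition, seed) {
  stopifnot(inherits(design, "lineup_design"))
  I <- design$I
  n <- rep_len(n_per_condition, I + 1L)
  conds <- c(seq_len(I), NA)
  out <- matrix(0L, 2^I, I + 1L,
                dimnames = list(rownames(uncensored_sequences(I)),
                                condition_labels(design)))
  for (j in seq_along(conds)) {
    p <- uncensored_probabilities(pre, post, design, conds[j])
    if (n[j] > 0)
      out[, j] <- with_seed(derive_seed(seed, j),
                            stats::rmultinom(1L, n[j], p)[, 1L])
  }
  out
}

#' Censor uncensored sequence counts at the first "yes"
#'
#' Collapses a matrix of full-sequence counts (as produced by
#' [simulate_uncensored()]) to the censored observable: first-"yes" position
#' or "reject all".
#'
#' @param seq_counts Matrix of sequence counts, `2^I` by `I + 1`, with
#'   response-string row names.
#' @param design The matching binary [lineup_design()].
#' @return A [lineup_table()].
#' @export
censor_sequences <- function(seq_counts, design) {
  I <- design$I
  seqs <- uncensored_sequences(I)
  first <- apply(seqs, 1L, function(r) { w <- which(r == 1L); if (length(w)) w[1L] else I + 1L })
  counts <- matrix(0, I + 1L, ncol(seq_counts))
  for (k in seq_len(I + 1L))
    counts[k, ] <- colSums(seq_counts[first == k, , drop = FALSE])
  lineup_table(counts, design)
}
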