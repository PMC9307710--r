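#' Parameter set for the sequential-lineup SDT model
#'
#' Collects every quantity of the Gaussian signal-detection model of
#' sequential lineup responses. Latent strengths are Gaussian: the face at
#' position `i` is drawn from the target distribution `N(mu_T * alpha_i,
#' xi_i * sigma2_T)` when it is the target and from the lure distribution
#' `N(-mu_T * alpha_i, xi_i)` otherwise -- target and lure means sit
#' symmetrically around the origin and the lure variance anchors the scale
#' at 1. A "yes" at position `i` occurs when the latent strength exceeds the
#' effective criterion for that position (see [effective_criterion()]).
#'
#' @param mu_T Base target mean (latent-strength units).
#' @param sigma2_T Base target variance (> 0); the lure variance is fixed at
#'   1 as the reference.
#' @param tau0 Binary response criteria, a scalar (shared across positions)
#'   or a length-`I` vector.
#' @param delta Criterion shift induced by a previous target rejection
#'   (any sign).
#' @param lambda Decay rate (>= 0) of the target-rejection shift with lag.
#' @param alpha Per-position multipliers on the target mean; `alpha[1]` must
#'   be 1. A scalar is expanded to positions 2..I with `alpha[1] = 1`.
#' @param xi Per-position multipliers (> 0) on both variances; `xi[1]` must
#'   be 1. A scalar is expanded like `alpha`.
#' @param kappa Nonnegative confidence-criterion increments: a `(K-1) x I`
#'   matrix, a length-`K-1` vector (shared across positions) or `NULL` for a
#'   binary-only model.
#' @param omega,eta,gamma Modulation of the confidence increments after a
#'   target rejection: increments are scaled by
#'   `omega * exp(eta * (h - i)) * exp(-gamma * m)` for increment `m` at lag
#'   `i - h`. `omega >= 0`.
#' @param pi_serious Mixture weight in `[0, 1]` of "serious" witnesses; the
#'   remaining `1 - pi_serious` always identify the first face.
#' @param zeta Decay rate (> 0; 0 gives the uniform limit) of the unserious
#'   witnesses' confidence distribution, see [unserious_confidence_pmf()].
#' @param I Sequence length; defaults to `length(tau0)`.
#' @return An object of class `sdt_params`.
#' @examples
#' p <- sdt_params(mu_T = 0.91, sigma2_T = 1.03,
#'                 tau0 = c(-0.01, 0.09, -0.07, -0.09, 0.06, 0.11),
#'                 delta = 1.07, lambda = 0.50)
#' @export
sdt_params <- function(mu_T, sigma2_T = 1, tau0 = 0, delta = 0, lambda = 0,
                       alpha = 1, xi = 1, kappa = NULL,
                       omega = 1, eta = 0, gamma = 0,
                       pi_serious = 1, zeta = 1,
                       I = max(length(tau0), 2L)) {
  I <- as.integer(I)
  expand_factor <- function(x, what) {
    if (length(x) == 1L) x <- c(1, rep(x, I - 1L))
    if (length(x) != I) stop("'", what, "' must have length 1 or I")
    if (abs(x[1L] - 1) > 1e-12) stop("'", what, "[1]' must equal 1 (anchor)")
    x
  }
  tau0 <- if (length(tau0) == 1L) rep(tau0, I) else tau0
  if (length(tau0) != I) stop("'tau0' must have length 1 or I")
  alpha <- expand_factor(alpha, "alpha")
  xi <- expand_factor(xi, "xi")
  if (sigma2_T <= 0) stop("'sigma2_T' must be positive")
  if (any(xi <= 0)) stop("'xi' must be positive")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  if (omega < 0) stop("'omega' must be nonnegative")
  if (pi_serious < 0 || pi_serious > 1) stop("'pi_serious' must lie in [0, 1]")
  if (zeta < 0) stop("'zeta' must be nonnegative")
  if (!is.null(kappa)) {
    if (!is.matrix(kappa)) kappa <- matrix(kappa, nrow = length(kappa), ncol = I)
    if (ncol(kappa) != I) stop("'kappa' must have I columns")
    if (any(kappa < 0)) stop("'kappa' increments must be nonnegative")
  }
  structure(list(mu_T = mu_T, sigma2_T = sigma2_T, tau0 = tau0,
                 delta = delta, lambda = lambda, alpha = alpha, xi = xi,
                 kappa = kappa, omega = omega, eta = eta, gamma = gamma,
                 pi_serious = pi_serious, zeta = zeta, I = I),
            class = "sdt_params")
}

#' @export
print.sdt_params <- function(x, digits = 3, ...) {
  cat("Sequential-lineup SDT parameters (I =", x$I, ")\n")
  cat("  mu_T =", round(x$mu_T, digits), " sigma2_T =", round(x$sigma2_T, digits), "\n")
  cat("  tau0 =", paste(round(x$tau0, digits), collapse = " "), "\n")
  cat("  delta =", round(x$delta, digits), " lambda =", round(x$lambda, digits), "\n")
  if (any(x$alpha != 1)) cat("  alpha =", paste(round(x$alpha, digits), collapse = " "), "\n")
  if (any(x$xi != 1)) cat("  xi =", paste(round(x$xi, digits), collapse = " "), "\n")
  if (!is.null(x$kappa)) {
    cat("  kappa (rows = increments):\n"); print(round(x$kappa, digits))
    cat("  omega =", round(x$omega, digits), " eta =", round(x$eta, digits),
        " gamma =", round(x$gamma, digits), "\n")
  }
  if (x$pi_serious < 1)
    cat("  pi_serious =", round(x$pi_serious, digits), " zeta =", round(x$zeta, digits), "\n")
  invisible(x)
}

# Per-position means / sds for one condition (target at h, NA = absent).
position_moments <- function(params, h) {
  I <- params$I
  mu <- -params$mu_T * params$alpha
  sd_ <- sqrt(params$xi) # lure sd, sigma2_L = 1
  sd_t <- sqrt(params$xi * params$sigma2_T)
  if (!is.na(h)) {
    mu[h] <- params$mu_T * params$alpha[h]
    sd_[h] <- sd_t[h]
  }
  list(mu = mu, sd = sd_)
}

#' Effective binary criterion at a sequence position
#'
#' The binary criterion actually applied at position `i`: the baseline
#' `tau0[i]`, shifted by `delta * exp(lambda * (h - i))` when the target was
#' encountered (and rejected) at an earlier position `h`. The shift decays
#' geometrically with the lag `i - h` at rate `lambda`.
#'
#' @param params An [sdt_params()] object.
#' @param i Sequence position, 1..I.
#' @param h Target position, or `NA` when no target precedes position `i`.
#' @return The criterion value.
#' @examples
#' p <- sdt_params(mu_T = 1, tau0 = rep(0, 6), delta = 1.07, lambda = 0.5)
#' effective_criterion(p, i = 4, h = 3)  # 1.07 * exp(-0.5)
#' @export
effective_criterion <- function(params, i, h = NA) {
  stopifnot(inherits(params, "sdt_params"))
  if (i < 1L || i > params$I) stop("'i' must lie in 1..I")
  if (is.na(h)) return(params$tau0[i])
  if (h >= i) stop("a criterion shift can only follow a target rejection: need h < i")
  params$tau0[i] + params$delta * exp(params$lambda * (h - i))
}

# Vector of effective binary criteria across positions for one condition.
# At the target position itself the baseline criterion applies.
effective_criteria_vec <- function(params, h) {
  tau <- params$tau0
  if (!is.na(h) && h < params$I) {
    i_later <- (h + 1L):params$I
    tau[i_later] <- tau[i_later] + params$delta * exp(params$lambda * (h - i_later))
  }
  tau
}

#' Censored response-category probabilities
#'
#' Exact probabilities of the `I + 1` censored response categories ("yes" at
#' position 1..I, "reject all") for one lineup condition. The probability of
#' a first "yes" at position `i` is the upper-tail mass above the effective
#' criterion at `i` times the product of "no" probabilities at every earlier
#' position; "reject all" is the full product of "no" probabilities. Tail
#' products are accumulated in log space.
#'
#' @inheritParams effective_criterion
#' @param design A binary [lineup_design()] (K = 1).
#' @param condition Target position 1..I, `NA` for target-absent, or a
#'   condition label ("tp3", "ta").
#' @return Named probability vector over the `I + 1` categories (sums to 1).
#' @examples
#' p <- sdt_params(mu_T = 0, sigma2_T = 1, tau0 = rep(0, 6))
#' censored_probabilities(p, lineup_design(6), "ta")  # 0.5^i chain
#' @export
censored_probabilities <- function(params, design, condition) {
  stopifnot(inherits(params, "sdt_params"), inherits(design, "lineup_design"))
  if (design$K != 1L)
    stop("use censored_confidence_probabilities() for K > 1 designs")
  if (design$I != params$I) stop("design and parameter sequence lengths differ")
  h <- target_position_of(condition, design$I)
  mom <- position_moments(params, h)
  z <- (effective_criteria_vec(params, h) - mom$mu) / mom$sd
  log_no <- stats::pnorm(z, log.p = TRUE)
  log_yes_tail <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  log_surv <- c(0, cumsum(log_no)) # survival to position i (exclusive)
  p <- c(exp(log_yes_tail + log_surv[seq_len(design$I)]),
         exp(log_surv[design$I + 1L]))
  names(p) <- category_labels(design)
  p
}

#' Ordered confidence criteria at a sequence position
#'
#' The full criterion vector `(tau_0, ..., tau_{K-1})` partitioning the
#' "yes" region into K confidence levels at position `i`. Before the target
#' is encountered the criteria are the baseline `tau0[i]` plus cumulative
#' nonnegative increments `kappa[m, i]`. After a target rejection at `h`,
#' the baseline shifts by the binary kernel and each increment `m` is
#' rescaled by `omega * exp(eta * (h - i)) * exp(-gamma * m)`.
#'
#' @inheritParams effective_criterion
#' @return Nondecreasing numeric vector of length K (the number of
#'   confidence levels implied by `nrow(kappa) + 1`).
#' @export
confidence_criteria <- function(params, i, h = NA) {
  stopifnot(inherits(params, "sdt_params"))
  if (is.null(params$kappa)) stop("parameter set has no confidence increments")
  if (!is.na(h) && h >= i)
    stop("a criterion shift can only follow a target rejection: need h < i")
  kap <- params$kappa[, i]
  m <- seq_along(kap)
  base <- effective_criterion(params, i, h)
  if (!is.na(h)) {
    rho <- params$omega * exp(params$eta * (h - i))
    kap <- kap * rho * exp(-params$gamma * m)
  }
  cumsum(c(base, kap))
}

#' Censored category probabilities with confidence levels
#'
#' Splits each first-"yes" probability of [censored_probabilities()] into K
#' confidence bins (ordered low to high) using the ordered criteria of
#' [confidence_criteria()]. Marginalising over bins reproduces the binary
#' probabilities exactly.
#'
#' @inheritParams censored_probabilities
#' @param design A [lineup_design()] with `K >= 2`.
#' @return Named probability vector over the `I * K + 1` categories.
#' @export
censored_confidence_probabilities <- function(params, design, condition) {
  stopifnot(inherits(params, "sdt_params"), inherits(design, "lineup_design"))
  if (design$K < 2L) stop("K = 1: use censored_probabilities()")
  if (is.null(params$kappa) || nrow(params$kappa) != design$K - 1L)
    stop("parameter set must carry K - 1 rows of confidence increments")
  h <- target_position_of(condition, design$I)
  mom <- position_moments(params, h)
  z0 <- (effective_criteria_vec(params, h) - mom$mu) / mom$sd
  log_no <- stats::pnorm(z0, log.p = TRUE)
  log_surv <- c(0, cumsum(log_no))
  I <- design$I; K <- design$K
  p <- numeric(I * K + 1L)
  for (i in seq_len(I)) {
    crit <- confidence_criteria(params, i, if (!is.na(h) && h < i) h else NA)
    zc <- (crit - mom$mu[i]) / mom$sd[i]
    tail_mass <- stats::pnorm(zc, lower.tail = FALSE) # above tau_0..tau_{K-1}
    bins <- c(tail_mass[-K] - tail_mass[-1L], tail_mass[K])
    p[(i - 1L) * K + seq_len(K)] <- bins * exp(log_surv[i])
  }
  p[I * K + 1L] <- exp(log_surv[I + 1L])
  names(p) <- category_labels(design)
  p
}

#' Confidence distribution of unserious respondents
#'
#' Probability of each confidence level `k = 1..K` (low to high) for a
#' witness who always identifies the first face: a geometric decay
#' `exp(-zeta * k)` normalised over the K levels. `zeta = 0` gives the
#' uniform distribution.
#'
#' @param zeta Decay rate, >= 0.
#' @param K Number of confidence levels, >= 1.
#' @return Probability vector of length K.
#' @examples
#' round(unserious_confidence_pmf(0.89, 4), 2)  # 0.61 0.25 0.10 0.04
#' @export
unserious_confidence_pmf <- function(zeta, K) {
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  if (zeta < 0) stop("'zeta' must be nonnegative")
  w <- exp(-zeta * seq_len(K))
  w / sum(w)
}

#' Mixture of serious and unserious witnesses
#'
#' Two-component mixture over response categories: with probability
#' `pi_serious` the witness follows the SDT model; otherwise they always
#' identify the first face, spreading confidence (when K > 1) according to
#' [unserious_confidence_pmf()].
#'
#' @inheritParams censored_probabilities
#' @param design A [lineup_design()]; both binary and confidence designs are
#'   supported.
#' @return Named probability vector over the `I * K + 1` categories.
#' @export
mixture_probabilities <- function(params, design, condition) {
  base <- if (design$K == 1L) censored_probabilities(params, design, condition)
          else censored_confidence_probabilities(params, design, condition)
  pi_s <- params$pi_serious
  contam <- numeric(length(base))
  if (design$K == 1L) {
    contam[1L] <- 1
  } else {
    contam[seq_len(design$K)] <- unserious_confidence_pmf(params$zeta, design$K)
  }
  p <- pi_s * base + (1 - pi_s) * contam
  names(p) <- names(base)
  p
}

#' Discriminability index d_a
#'
#' Unequal-variance discriminability at sequence position `i`: the distance
#' between the target and lure means in units of their root-mean-square
#' standard deviation, `(mu_T,i - mu_L,i) / sqrt((sigma2_T,i + sigma2_L,i)/2)`.
#'
#' @inheritParams effective_criterion
#' @return Numeric d_a value.
#' @examples
#' d_a(sdt_params(mu_T = 0.91, sigma2_T = 1.03, tau0 = rep(0, 6)), 1) # ~1.81
#' @export
d_a <- function(params, i = 1L) {
  stopifnot(inherits(params, "sdt_params"))
  2 * params$mu_T * params$alpha[i] /
    sqrt(params$xi[i] * (params$sigma2_T + 1) / 2)
}

#' Predicted confidence-rating ROC family
#'
#' For each target position `h`, the cumulative (false alarm, hit) operating
#' points obtained by sweeping the confidence criteria from the strictest
#' down: hits accumulate the confidence mass of "yes" at position `h` in the
#' target-at-`h` condition, false alarms the matching mass at position `h`
#' in the target-absent condition. Sequential lineups yield one ROC per
#' target position rather than a single curve.
#'
#' @inheritParams censored_confidence_probabilities
#' @return A list of `I` data frames (one per target position) with columns
#'   `criterion_level` (K down to 1), `fa` and `hit`, each cumulative and
#'   nondecreasing.
#' @export
predicted_rocs <- function(params, design) {
  stopifnot(inherits(design, "lineup_design"))
  if (design$K < 2L) stop("confidence ROCs require K >= 2")
  I <- design$I; K <- design$K
  ta <- censored_confidence_probabilities(params, design, NA)
  out <- vector("list", I)
  for (h in seq_len(I)) {
    tp <- censored_confidence_probabilities(params, design, h)
    idx <- (h - 1L) * K + seq_len(K)
    hit <- rev(cumsum(rev(tp[idx])))
    fa <- rev(cumsum(rev(ta[idx])))
    out[[h]] <- data.frame(criterion_level = K:1, fa = rev(fa), hit = rev(hit))
  }
  names(out) <- paste0("tp", seq_len(I))
  out
}

# Enumerate all 2^I uncensored response sequences as a 0/1 matrix.
uncensored_sequences <- function(I) {
  m <- as.matrix(expand.grid(rep(list(c(0L, 1L)), I))[, I:1, drop = FALSE])
  dimnames(m) <- list(apply(m, 1L, paste, collapse = ""), NULL)
  m
}

#' Probabilities of full (uncensored) response sequences
#'
#' When no stopping rule is imposed the witness judges all I faces and the
#' observable is one of the `2^I` yes/no sequences. Responses up to and
#' including the first "yes" are governed by the `pre` parameter set (the
#' censored model); all later responses by the `post` set, which defaults to
#' `pre`. Target-rejection criterion shifts apply in either phase whenever
#' the target occupied an earlier position and was answered "no".
#' Marginalising to the first-"yes" position (or all-"no") reproduces
#' [censored_probabilities()] with the `pre` parameters exactly.
#'
#' @param pre,post [sdt_params()] sets governing responses before/at and
#'   after the first "yes".
#' @inheritParams censored_probabilities
#' @return Named probability vector over the `2^I` sequences (names are
#'   response strings such as `"010010"`), summing to 1.
#' @export
uncensored_probabilities <- function(pre, post = pre, design, condition) {
  stopifnot(inherits(pre, "sdt_params"), inherits(post, "sdt_params"),
            inherits(design, "lineup_design"))
  if (design$K != 1L) stop("uncensored sequences are modelled for binary designs")
  I <- design$I
  h <- target_position_of(condition, I)
  seqs <- uncensored_sequences(I)
  mom_pre <- position_moments(pre, h)
  mom_post <- position_moments(post, h)
  p <- numeric(nrow(seqs))
  for (r in seq_len(nrow(seqs))) {
    resp <- seqs[r, ]
    lp <- 0
    yes_seen <- FALSE
    for (i in seq_len(I)) {
      act <- if (yes_seen) post else pre
      mom <- if (yes_seen) mom_post else mom_pre
      tau <- act$tau0[i]
      if (!is.na(h) && h < i && resp[h] == 0L)
        tau <- tau + act$delta * exp(act$lambda * (h - i))
      z <- (tau - mom$mu[i]) / mom$sd[i]
      lp <- lp + stats::pnorm(z, lower.tail = resp[i] == 0L, log.p = TRUE)
      if (resp[i] == 1L) yes_seen <- TRUE
    }
    p[r] <- exp(lp)
  }
  names(p) <- rownames(seqs)
  p
}

# Cell-probability matrix over all conditions, dispatching on design and
# model extensions; the fitting workhorse.
cell_probability_matrix <- function(params, design, mixture = FALSE) {
  conds <- c(seq_len(design$I), NA)
  fun <- if (mixture) {
    function(cond) mixture_probabilities(params, design, cond)
  } else if (design$K == 1L) {
    function(cond) censored_probabilities(params, design, cond)
  } else {
    function(cond) censored_confidence_probabilities(params, design, cond)
  }
  m <- vapply(conds, fun, numeric(design$I * design$K + 1L))
  dimnames(m) <- list(category_labels(design), condition_labels(design))
  m
}
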