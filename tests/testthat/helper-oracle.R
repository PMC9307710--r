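# Independent Monte-Carlo oracles: simulate the decision process described
# by the model directly (latent Gaussian draws, sequential comparison to
# criteria), without calling the package's analytic probability code. Used
# to validate the closed-form category probabilities.

# Censored responses: returns category proportions (yes@1..I split into K
# bins when K > 1, then reject).
mc_censored_oracle <- function(params, I, K, h, n, seed) {
  set.seed(seed)
  mu <- -params$mu_T * params$alpha
  sd_ <- sqrt(params$xi)
  if (!is.na(h)) {
    mu[h] <- params$mu_T * params$alpha[h]
    sd_[h] <- sqrt(params$xi[h] * params$sigma2_T)
  }
  # effective binary criteria: reaching i > h implies the target was rejected
  tau <- params$tau0
  if (!is.na(h) && h < I) {
    i <- (h + 1L):I
    tau[i] <- tau[i] + params$delta * exp(params$lambda * (h - i))
  }
  x <- matrix(rnorm(n * I), n, I) * rep(sd_, each = n) + rep(mu, each = n)
  yes <- x > rep(tau, each = n)
  first <- apply(yes, 1L, function(r) { w <- which(r); if (length(w)) w[1L] else I + 1L })
  if (K == 1L) return(tabulate(first, I + 1L) / n)
  counts <- numeric(I * K + 1L)
  for (i in seq_len(I)) {
    idx <- which(first == i)
    if (!length(idx)) next
    crit <- confidence_criteria(params, i, if (!is.na(h) && h < i) h else NA)
    bin <- findInterval(x[idx, i], crit) # in 1..K since x > crit[1]
    counts[(i - 1L) * K + seq_len(K)] <- tabulate(bin, K)
  }
  counts[I * K + 1L] <- sum(first == I + 1L)
  counts / n
}

# Uncensored sequences: two-phase per-witness simulation; returns the 2^I
# sequence proportions in the row order of the package's enumeration.
mc_uncensored_oracle <- function(pre, post, I, h, n, seed) {
  set.seed(seed)
  resp <- matrix(0L, n, I)
  yes_seen <- rep(FALSE, n)
  for (i in seq_len(I)) {
    act_mu <- function(p) {
      m <- rep(-p$mu_T * p$alpha[i], n)
      s <- rep(sqrt(p$xi[i]), n)
      if (!is.na(h) && h == i) {
        m[] <- p$mu_T * p$alpha[i]
        s[] <- sqrt(p$xi[i] * p$sigma2_T)
      }
      cbind(m, s)
    }
    ms_pre <- act_mu(pre); ms_post <- act_mu(post)
    m <- ifelse(yes_seen, ms_post[, 1L], ms_pre[, 1L])
    s <- ifelse(yes_seen, ms_post[, 2L], ms_pre[, 2L])
    tau <- ifelse(yes_seen, post$tau0[i], pre$tau0[i])
    if (!is.na(h) && h < i) {
      rejected <- resp[, h] == 0L
      shift_pre <- pre$delta * exp(pre$lambda * (h - i))
      shift_post <- post$delta * exp(post$lambda * (h - i))
      tau <- tau + ifelse(rejected, ifelse(yes_seen, shift_post, shift_pre), 0)
    }
    x <- rnorm(n, m, s)
    resp[, i] <- as.integer(x > tau)
    yes_seen <- yes_seen | resp[, i] == 1L
  }
  key <- apply(resp, 1L, paste, collapse = "")
  all_keys <- apply(seqsdt:::uncensored_sequences(I), 1L, paste, collapse = "")
  tab <- table(factor(key, levels = all_keys))
  as.numeric(tab) / n
}

# Three-standard-error comparison of empirical proportions vs probabilities.
expect_within_3se <- function(phat, p, n) {
  se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
  expect_true(all(abs(phat - p) <= 3 * se + 1e-9),
              label = sprintf("max |phat - p| / se = %.2f",
                              max(abs(phat - p) / pmax(se, 1e-12))))
}

# Random admissible parameter draw for property tests.
random_params <- function(I = 6L, K = 1L, kernel = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdt_params(
    mu_T = runif(1, 0.3, 1.3),
    sigma2_T = runif(1, 0.4, 1.5),
    tau0 = runif(I, -0.3, 0.6),
    delta = if (kernel) runif(1, -0.5, 1.2) else 0,
    lambda = if (kernel) runif(1, 0, 1) else 0,
    kappa = if (K > 1L) matrix(runif((K - 1L) * I, 0.1, 0.6), K - 1L, I),
    omega = if (K > 1L) runif(1, 0.5, 1.5) else 1,
    eta = if (K > 1L) runif(1, -0.3, 0.3) else 0,
    gamma = if (K > 1L) runif(1, -0.2, 0.2) else 0,
    I = I)
}
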