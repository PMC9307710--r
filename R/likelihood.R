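# Fast likelihood machinery. The public probability functions in
# sdt-core.R are the readable reference; fitting uses the evaluators below,
# which compute the same cell probabilities with preresolved parameter
# indices and whole-matrix pnorm calls. Agreement between the two routes is
# asserted in the test suite.

# Resolve, once per layout, where each natural block lives in the free
# vector; returns a closure mapping free -> parameter blocks without any
# validation overhead.
build_natural_extractor <- function(layout) {
  spec <- layout$spec
  I <- layout$design$I
  K <- layout$design$K
  r <- spec$restrictions
  nm <- layout$par_names
  ix <- function(x) match(x, nm)
  i_mu <- ix("mu_T")
  i_s2 <- ix("log_sigma2_T")
  crit_mode <-
    if (!(spec$criterion %in% c("tau2", "tau4")) || "fixed_tau0" %in% r) "scalar"
    else if ("monotone_increasing_tau0" %in% r) "mono_inc"
    else if ("monotone_decreasing_tau0" %in% r) "mono_dec"
    else "free"
  i_tau <- switch(crit_mode,
                  scalar = ix("tau0"),
                  free = ix(paste0("tau0_", seq_len(I))),
                  ix(c("tau0_1", paste0("log_dtau_", 2:I))))
  has_kernel <- spec$criterion %in% c("tau3", "tau4")
  i_delta <- if (has_kernel) ix("delta") else NA_integer_
  i_lambda <- if (has_kernel && !"lambda_zero" %in% r) ix("log_lambda") else NA_integer_
  disc <- spec$discriminability
  i_disc <- switch(disc, null = NULL, mu1 = ix("log_alpha"),
                   sigma1 = ix("log_xi"),
                   mu2 = ix(paste0("log_alpha_", 2:I)),
                   sigma2 = ix(paste0("log_xi_", 2:I)))
  shared_kappa <- "shared_kappa_across_positions" %in% r
  i_kappa <- if (spec$confidence) {
    if (shared_kappa) ix(paste0("log_kappa_", seq_len(K - 1L)))
    else ix(paste0("log_kappa_", rep(seq_len(K - 1L), I), "_",
                   rep(seq_len(I), each = K - 1L)))
  }
  oeg_free <- spec$confidence && !"omega_eta_gamma_fixed" %in% r
  i_oeg <- if (oeg_free) ix(c("log_omega", "eta", "gamma"))
  i_pi <- if (spec$mixture) ix("logit_pi") else NA_integer_
  i_zeta <- if (spec$mixture && spec$confidence) ix("log_zeta") else NA_integer_
  ones <- rep(1, I)
  function(free) {
    tau0 <- switch(crit_mode,
                   scalar = rep(free[i_tau], I),
                   free = free[i_tau],
                   mono_inc = cumsum(c(free[i_tau[1L]], exp(free[i_tau[-1L]]))),
                   mono_dec = cumsum(c(free[i_tau[1L]], -exp(free[i_tau[-1L]]))))
    alpha <- ones; xi <- ones
    if (disc == "mu1") alpha <- c(1, rep(exp(free[i_disc]), I - 1L))
    else if (disc == "sigma1") xi <- c(1, rep(exp(free[i_disc]), I - 1L))
    else if (disc == "mu2") alpha <- c(1, exp(free[i_disc]))
    else if (disc == "sigma2") xi <- c(1, exp(free[i_disc]))
    list(mu_T = free[i_mu],
         s2 = if (is.na(i_s2)) 1 else exp(free[i_s2]),
         tau0 = tau0,
         delta = if (is.na(i_delta)) 0 else free[i_delta],
         lambda = if (is.na(i_lambda)) 0 else exp(free[i_lambda]),
         alpha = alpha, xi = xi,
         kappa = if (spec$confidence)
           matrix(exp(free[i_kappa]), K - 1L, I) else NULL,
         omega = if (oeg_free) exp(free[i_oeg[1L]]) else 1,
         eta = if (oeg_free) free[i_oeg[2L]] else 0,
         gamma = if (oeg_free) free[i_oeg[3L]] else 0,
         pi_serious = if (is.na(i_pi)) 1 else stats::plogis(free[i_pi]),
         zeta = if (is.na(i_zeta)) 1 else exp(free[i_zeta]))
  }
}

# Strictly-lower-triangular ones matrix: (L %*% x)[i, ] = colwise partial
# sums of x up to row i - 1.
strict_lower_ones <- function(n) {
  L <- matrix(0, n, n)
  L[lower.tri(L)] <- 1
  L
}

# Log cell-probability matrix (categories x conditions) from parameter
# blocks; binary designs.
binary_log_probs <- function(b, I, Lstrict = strict_lower_ones(I)) {
  ncond <- I + 1L
  pos <- seq_len(I)
  # criterion shift cells: condition j (target at j), positions i > j
  TAU <- matrix(b$tau0, I, ncond)
  if (b$delta != 0) {
    for (j in seq_len(I - 1L)) {
      i <- (j + 1L):I
      TAU[i, j] <- TAU[i, j] + b$delta * exp(b$lambda * (j - i))
    }
  }
  muL <- -b$mu_T * b$alpha
  MU <- matrix(muL, I, ncond)
  SD <- matrix(sqrt(b$xi), I, ncond)
  dg <- cbind(pos, pos)
  MU[dg] <- b$mu_T * b$alpha
  SD[dg] <- sqrt(b$xi * b$s2)
  Z <- (TAU - MU) / SD
  logno <- stats::pnorm(Z, log.p = TRUE)
  logtail <- stats::pnorm(Z, lower.tail = FALSE, log.p = TRUE)
  rbind(logtail + Lstrict %*% logno, colSums(logno))
}

# Log cell probabilities for confidence designs (K >= 2).
confidence_log_probs <- function(b, I, K,
                                 Lk = 1 * lower.tri(diag(K), diag = TRUE)) {
  ncond <- I + 1L
  gfac <- exp(-b$gamma * seq_len(K - 1L))
  out <- matrix(NA_real_, I * K + 1L, ncond)
  muL <- -b$mu_T * b$alpha
  sdL <- sqrt(b$xi)
  sdT <- sqrt(b$xi * b$s2)
  for (j in seq_len(ncond)) {
    h <- if (j <= I) j else NA_integer_
    tau0 <- b$tau0
    KAP <- b$kappa
    if (!is.na(h) && h < I) {
      i_sh <- (h + 1L):I
      tau0[i_sh] <- tau0[i_sh] + b$delta * exp(b$lambda * (h - i_sh))
      rho <- b$omega * exp(b$eta * (h - i_sh))
      KAP[, i_sh] <- KAP[, i_sh, drop = FALSE] *
        rep(rho, each = K - 1L) * gfac
    }
    mu <- muL
    sd_ <- sdL
    if (!is.na(h)) {
      mu[h] <- b$mu_T * b$alpha[h]
      sd_[h] <- sdT[h]
    }
    crit <- Lk %*% rbind(tau0, KAP) # K x I ordered criteria
    Zc <- (crit - rep(mu, each = K)) / rep(sd_, each = K)
    tails <- stats::pnorm(Zc, lower.tail = FALSE) # mass above each criterion
    bins <- rbind(tails[-K, , drop = FALSE] - tails[-1L, , drop = FALSE],
                  tails[K, ])
    z0 <- (tau0 - mu) / sd_
    logno <- stats::pnorm(z0, log.p = TRUE)
    surv <- exp(c(0, cumsum(logno))[seq_len(I)])
    out[, j] <- c(log(bins * rep(surv, each = K)), sum(logno))
  }
  out
}

# Negative log-likelihood closure for a (layout, table) pair; handles
# binary, confidence and mixture models. Returns 1e10 on invalid regions.
make_nll <- function(layout, table) {
  design <- layout$design
  I <- design$I; K <- design$K
  extract <- build_natural_extractor(layout)
  O <- table$counts
  pos <- O > 0
  Opos <- O[pos]
  mixture <- layout$spec$mixture
  Lstrict <- strict_lower_ones(I)
  Lk <- if (K > 1L) 1 * lower.tri(diag(K), diag = TRUE)
  function(free) {
    if (any(!is.finite(free)) || any(abs(free) > 50)) return(1e10)
    b <- extract(free)
    LM <- if (K == 1L) binary_log_probs(b, I, Lstrict)
          else confidence_log_probs(b, I, K, Lk)
    if (mixture) {
      P <- exp(LM) * b$pi_serious
      contam <- if (K == 1L) 1 else {
        w <- exp(-b$zeta * seq_len(K)); w / sum(w)
      }
      P[seq_len(K), ] <- P[seq_len(K), , drop = FALSE] +
        (1 - b$pi_serious) * contam
      LM <- log(P)
    }
    lv <- LM[pos]
    if (any(!is.finite(lv))) return(1e10)
    -sum(Opos * lv)
  }
}
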