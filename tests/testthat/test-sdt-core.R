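test_that("effective criterion applies the decaying shift kernel", {
  p <- sdt_params(mu_T = 1, tau0 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                  delta = 1.07, lambda = 0.50)
  expect_equal(effective_criterion(p, 4, NA), 0.4)
  expect_equal(effective_criterion(p, 4, 3), 0.4 + 1.07 * exp(-0.5))
  p0 <- p; p0$delta <- 0
  expect_equal(effective_criterion(p0, 4, 2), 0.4)
  pl <- p; pl$lambda <- 0
  expect_equal(effective_criterion(pl, 6, 1) - pl$tau0[6], 1.07)
  expect_equal(effective_criterion(pl, 2, 1) - pl$tau0[2], 1.07)
  expect_error(effective_criterion(p, 3, 3), "h < i")
})

test_that("censored probabilities form the exact stopping-rule chain", {
  des <- lineup_design(6)
  p <- sdt_params(mu_T = 0, sigma2_T = 1, tau0 = rep(0, 6))
  pr <- censored_probabilities(p, des, NA)
  expect_equal(unname(pr), c(0.5^(1:6), 0.5^6), tolerance = 1e-12)

  p_lib <- sdt_params(mu_T = 0.5, tau0 = c(-30, rep(0, 5)))
  pr2 <- censored_probabilities(p_lib, des, 2)
  expect_equal(unname(pr2[1]), 1, tolerance = 1e-10)
  expect_true(all(pr2[-1] < 1e-10))
})

test_that("analytic probabilities agree with the Monte-Carlo decision-process oracle", {
  des <- lineup_design(6)
  n <- 2e5
  for (s in 1:3) {
    p <- random_params(seed = 100 + s)
    for (h in c(1L, 4L, NA)) {
      cond <- if (is.na(h)) NA else h
      expect_within_3se(mc_censored_oracle(p, 6, 1, h, n, seed = 200 + s),
                        unname(censored_probabilities(p, des, cond)), n)
    }
  }
  # confidence variant
  desK <- lineup_design(6, 4)
  pk <- random_params(K = 4, seed = 7)
  for (h in c(2L, NA)) {
    cond <- if (is.na(h)) NA else h
    expect_within_3se(mc_censored_oracle(pk, 6, 4, h, n, seed = 9),
                      unname(censored_confidence_probabilities(pk, desK, cond)), n)
  }
})

test_that("confidence criteria cumulate increments and modulate after rejection", {
  p <- sdt_params(mu_T = 1, tau0 = c(0.1, rep(0.2, 5)),
                  kappa = matrix(c(0.2, 0.3, 0.4), 3, 6), delta = 0.5,
                  lambda = 0.4, omega = 1, eta = 0, gamma = 0)
  expect_equal(confidence_criteria(p, 1, NA), c(0.1, 0.3, 0.6, 1.0))
  # neutral modulation: rigid shift of the whole criterion vector
  shift <- 0.5 * exp(0.4 * (1 - 3))
  expect_equal(confidence_criteria(p, 3, 1),
               c(0.2, 0.4, 0.7, 1.1) + shift)
  # nondecreasing for random admissible parameters
  for (s in 1:5) {
    pk <- random_params(K = 4, seed = 300 + s)
    expect_true(all(diff(confidence_criteria(pk, 5, 2)) >= 0))
  }
})

test_that("confidence bins partition the binary yes mass exactly", {
  desK <- lineup_design(6, 4)
  des <- lineup_design(6)
  pk <- random_params(K = 4, seed = 11)
  for (cond in c(1, 3, NA)) {
    pc <- censored_confidence_probabilities(pk, desK, cond)
    pb <- censored_probabilities(pk, des, cond)
    collapsed <- c(colSums(matrix(pc[1:24], 4)), pc[25])
    expect_equal(unname(collapsed), unname(pb), tolerance = 1e-12)
  }
  # zero increments push all mass into the top bin
  p0 <- random_params(K = 4, seed = 12)
  p0$kappa[] <- 0
  pc0 <- censored_confidence_probabilities(p0, desK, NA)
  expect_equal(sum(pc0[seq(1, 21, by = 4)]), 0) # bins 1 of each position
  expect_equal(sum(pc0[seq(2, 22, by = 4)]), 0)
})

test_that("unserious confidence distribution is the normalised geometric decay", {
  expect_equal(round(unserious_confidence_pmf(0.89, 4), 2),
               c(0.61, 0.25, 0.10, 0.04))
  expect_equal(unserious_confidence_pmf(0, 4), rep(0.25, 4))
  e1 <- exp(-1)
  expect_equal(unserious_confidence_pmf(1, 2),
               c(1 / (1 + e1), e1 / (1 + e1)))
  expect_error(unserious_confidence_pmf(1, 0))
})

test_that("the serious/unserious mixture is the stated convex combination", {
  des <- lineup_design(6)
  p <- random_params(seed = 21)
  p$pi_serious <- 1
  expect_equal(mixture_probabilities(p, des, 2),
               censored_probabilities(p, des, 2))
  p$pi_serious <- 0
  m0 <- mixture_probabilities(p, des, 2)
  expect_equal(unname(m0[1]), 1)
  p$pi_serious <- 0.95
  base <- censored_probabilities(p, des, NA)
  mix <- mixture_probabilities(p, des, NA)
  expect_equal(unname(mix[1] - base[1]), 0.05 * (1 - unname(base[1])),
               tolerance = 1e-12)
})

test_that("d_a is the unequal-variance distance in RMS-sd units", {
  expect_equal(d_a(sdt_params(mu_T = 0, tau0 = rep(0, 6))), 0)
  expect_equal(d_a(sdt_params(mu_T = 0.7, sigma2_T = 1, tau0 = rep(0, 6))), 1.4)
  p <- sdt_params(mu_T = 0.91, sigma2_T = 1.03, tau0 = rep(0, 6))
  expect_equal(d_a(p, 1), 2 * 0.91 / sqrt(2.03 / 2), tolerance = 1e-12)
  expect_equal(d_a(p, 1), 1.79, tolerance = 0.02) # published rounded value
})

test_that("predicted ROC families are cumulative and ordered by target position", {
  desK <- lineup_design(6, 4)
  null <- sdt_params(mu_T = 0, sigma2_T = 1, tau0 = rep(0.2, 6),
                     kappa = matrix(0.3, 3, 6))
  rocs <- predicted_rocs(null, desK)
  for (r in rocs) expect_equal(r$fa, r$hit, tolerance = 1e-10)

  pk <- reference_params("wilson_confidence_tau4")
  rocs2 <- predicted_rocs(pk, desK)
  for (r in rocs2) {
    expect_true(all(diff(r$fa) >= 0))
    expect_true(all(diff(r$hit) >= 0))
  }
  # position 1 dominates position 6 at matched criterion levels
  expect_true(all(rocs2$tp1$hit > rocs2$tp6$hit))
})

test_that("uncensored sequence probabilities extend the censored model coherently", {
  des2 <- lineup_design(2)
  p2 <- sdt_params(mu_T = 0, sigma2_T = 1, tau0 = c(0, 0), I = 2)
  u2 <- uncensored_probabilities(p2, p2, des2, NA)
  expect_equal(unname(u2), rep(0.25, 4))

  des <- lineup_design(6)
  pre <- random_params(seed = 31)
  post <- random_params(seed = 32)
  for (cond in c(3, NA)) {
    u <- uncensored_probabilities(pre, post, des, cond)
    expect_equal(sum(u), 1, tolerance = 1e-10)
    # marginal first-yes distribution is the censored pre model, exactly
    seqs <- seqsdt:::uncensored_sequences(6)
    first <- apply(seqs, 1, function(r) {
      w <- which(r == 1); if (length(w)) w[1] else 7})
    marg <- as.numeric(tapply(u, first, sum))
    expect_equal(marg, unname(censored_probabilities(pre, des, cond)),
                 tolerance = 1e-12)
  }
  # stopping-rule emulation: post criteria at +Inf leave at most one yes
  stopper <- post; stopper$tau0 <- rep(40, 6)
  u1 <- uncensored_probabilities(pre, stopper, des, 2)
  seqs <- seqsdt:::uncensored_sequences(6)
  multi <- rowSums(seqs) > 1
  expect_true(all(u1[multi] < 1e-12))
  # agreement with the two-phase Monte-Carlo oracle
  n <- 2e5
  expect_within_3se(mc_uncensored_oracle(pre, post, 6, 3L, n, seed = 77),
                    unname(uncensored_probabilities(pre, post, des, 3)), n)
})

test_that("raising one criterion moves mass later and into rejection", {
  des <- lineup_design(6)
  p <- random_params(seed = 41)
  p2 <- p; p2$tau0[3] <- p2$tau0[3] + 0.5
  for (cond in c(1, 5, NA)) {
    a <- censored_probabilities(p, des, cond)
    b <- censored_probabilities(p2, des, cond)
    expect_lte(b[3], a[3])
    expect_true(all(b[4:7] >= a[4:7] - 1e-12))
  }
})

test_that("model reductions collapse exactly onto their nested special cases", {
  des <- lineup_design(6)
  # tau4 with delta = 0 is tau2; tau2 with equal criteria is tau1
  p <- random_params(seed = 51)
  p$delta <- 0
  p_t2 <- sdt_params(mu_T = p$mu_T, sigma2_T = p$sigma2_T, tau0 = p$tau0)
  for (cond in c(2, NA))
    expect_equal(censored_probabilities(p, des, cond),
                 censored_probabilities(p_t2, des, cond))
  # mu1 with alpha = 1 is the fixed-discriminability model
  pa <- random_params(seed = 52); pa$alpha <- rep(1, 6)
  pb <- sdt_params(mu_T = pa$mu_T, sigma2_T = pa$sigma2_T, tau0 = pa$tau0,
                   delta = pa$delta, lambda = pa$lambda)
  expect_equal(censored_probabilities(pa, des, 4),
               censored_probabilities(pb, des, 4))
  # under criterion models without the kernel, hazard contrasts vanish
  p0 <- random_params(kernel = FALSE, seed = 53)
  pr_ta <- censored_probabilities(p0, des, NA)
  for (h in c(1, 3)) {
    pr_tp <- censored_probabilities(p0, des, h)
    for (i in (h + 1):6) {
      haz_tp <- pr_tp[i] / (1 - sum(pr_tp[seq_len(i - 1)]))
      haz_ta <- pr_ta[i] / (1 - sum(pr_ta[seq_len(i - 1)]))
      expect_equal(unname(haz_tp - haz_ta), 0, tolerance = 1e-12)
    }
  }
})
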