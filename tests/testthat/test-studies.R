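test_that("the i.i.d. position test has the right null behaviour and df accounting", {
  des <- lineup_design(6)
  p <- random_params(kernel = FALSE, seed = 91)
  # under pre = post and no kernel, responses are position-independent:
  # strata proportions are equal in expectation
  sc <- simulate_uncensored(p, p, des, 4e4, seed = 9)
  t3 <- iid_position_test(sc, 3, "lure")
  expect_equal(t3$df, 3) # 2^(3-1) - 1
  expect_length(t3$proportions, 4)
  expect_gt(t3$p, 0.01)
  # exact-zero statistic when strata are literally identical
  m <- matrix(0, 64, 7, dimnames = dimnames(sc))
  seqs <- seqsdt:::uncensored_sequences(6)
  m[, 7] <- 10 # every sequence equally often: all strata identical
  tt <- iid_position_test(m, 4, "lure")
  expect_equal(tt$g2, 0, tolerance = 1e-10)
  expect_equal(tt$p, 1)
  # post-first-yes parameter change is detected at scale
  post <- p; post$tau0 <- p$tau0 + 0.6
  sc2 <- simulate_uncensored(p, post, des, 4e4, seed = 10)
  expect_lt(iid_position_test(sc2, 3, "lure")$p, 1e-4)
})

test_that("pre/post SDT analysis recovers generating differences and their absence", {
  des <- lineup_design(6)
  # criteria vary across positions so the unequal-variance parameters are
  # identified from the spread of per-position operating points
  taus <- seq(-0.1, 0.5, length.out = 6)
  pre <- sdt_params(mu_T = 0.887, sigma2_T = 1, tau0 = taus)
  # post phase: d_a lower by 0.35 and criteria stricter by 0.39
  post <- sdt_params(mu_T = 0.712, sigma2_T = 1, tau0 = taus + 0.39)
  true_diff_da <- d_a(pre) - d_a(post)
  sc <- simulate_uncensored(pre, post, des, 5e4, seed = 11)
  fit <- prepost_binary_sdt(sc, restarts = 4, seed = 1)
  # within ~3 standard errors of the simulation at this sample size
  expect_lt(abs(fit$d_a_difference - true_diff_da), 0.09)
  # fitted criteria are anchored at the lure mean, so the recovered shift is
  # the criterion shift plus the lure-mean displacement mu_pre - mu_post
  expect_equal(fit$mean_tau_difference, 0.39 + (post$mu_T - pre$mu_T),
               tolerance = 0.06)
  expect_lt(fit$lr_discriminability$p, 0.01)
  expect_lt(fit$lr_criteria$p, 0.001)
  expect_equal(fit$lr_criteria$df, 5)
  expect_equal(fit$lr_discriminability$df, 2)
  # null generation: no spurious differences
  sc0 <- simulate_uncensored(pre, pre, des, 5e4, seed = 12)
  fit0 <- prepost_binary_sdt(sc0, restarts = 2, seed = 1)
  expect_lt(abs(fit0$d_a_difference), 0.08)
  expect_gt(fit0$lr_discriminability$p, 0.01)
})

test_that("study drivers run end to end, are seeded and expose replicate records", {
  r1 <- dfd_power_study(alpha_values = 1.5, reps = 1, n_per_condition = 300,
                        seed = 3, response_mode = "binary", restarts = 0)
  expect_equal(nrow(r1$replicates), 1)
  expect_gte(r1$replicates$delta_g2, 0)
  r2 <- dfd_power_study(alpha_values = 1.5, reps = 1, n_per_condition = 300,
                        seed = 3, response_mode = "binary", restarts = 0)
  expect_identical(r1$replicates, r2$replicates)

  g <- group_difference_study(scenarios = "none", reps = 2,
                              n_per_condition = 200, seed = 2, restarts = 0)
  expect_equal(nrow(g$replicates), 2)
  expect_true(all(g$replicates$delta_g2_disc >= 0))
  expect_true(all(c("pct_reject_discriminability", "pct_reject_criteria")
                  %in% names(g$summary)))

  d <- da_recovery_study(reps = 5, n_per_condition = 200, seed = 4,
                         restarts = 0)
  expect_equal(nrow(d$replicates), 5)
  # replacing estimates by the truth gives perfect rank correlation
  expect_equal(cor(d$replicates$true_da, d$replicates$true_da,
                   method = "spearman"), 1)
  expect_true(abs(d$summary$rank_correlation) <= 1)
})

test_that("identical groups give near-zero deviance differences", {
  des <- lineup_design(6)
  gen <- reference_params("wilson_confidence_tau4")
  gen$kappa <- NULL
  tab <- simulate_table(gen, des, 500, seed = 21)
  both <- seqsdt:::fit_two_groups(tab, tab, FALSE, FALSE, restarts = 1, seed = 1)
  shared <- seqsdt:::fit_two_groups(tab, tab, TRUE, TRUE, restarts = 1, seed = 1)
  expect_lt(shared$g_squared - both$g_squared, 0.05)
})
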