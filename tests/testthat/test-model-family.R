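test_that("free-parameter counts match the published model table", {
  des <- lineup_design(6)
  counts <- unlist(lapply(binary_family_specs(), parameter_count, design = des))
  expect_equal(counts, c(3, 4, 4, 8, 8,
                         8, 9, 9, 13, 13,
                         5, 6, 6, 10, 10,
                         10, 11, 11, 15, 15))
  desK <- lineup_design(6, 4)
  conf <- model_spec("tau4", confidence = TRUE)
  expect_equal(parameter_count(conf, desK), 31) # 10 + 6*(K-1) + 3
  expect_equal(parameter_count(conf, desK, published_count_mode = TRUE), 30)
  mix <- model_spec("tau4", confidence = TRUE, mixture = TRUE)
  expect_equal(parameter_count(mix, desK) - parameter_count(conf, desK), 2)
  expect_equal(parameter_count(model_spec("tau4", mixture = TRUE), des) -
                 parameter_count(model_spec("tau4"), des), 1)
  expect_equal(parameter_count(model_spec("tau1",
                                          restrictions = "equal_variance"),
                               des), 2)
  expect_equal(parameter_count(model_spec("tau4", confidence = TRUE,
                 restrictions = "shared_kappa_across_positions"), desK),
               10 + 3 + 3)
})

test_that("inconsistent specs and restriction combinations are rejected", {
  expect_error(model_spec("tau1", restrictions = "monotone_increasing_tau0"),
               "tau2 or tau4")
  expect_error(model_spec("tau2", restrictions = "lambda_zero"), "kernel")
  expect_error(model_spec("tau4", restrictions = c("monotone_increasing_tau0",
                                                   "monotone_decreasing_tau0")))
  expect_error(model_spec("tau4", restrictions = "omega_eta_gamma_fixed"),
               "confidence")
  expect_error(model_spec("tau4", restrictions = "nonsense"), "unknown")
  expect_error(build_model(model_spec("tau4", confidence = TRUE),
                           lineup_design(6)), "K >= 2")
})

test_that("free/natural transforms round-trip and always land in the admissible set", {
  des <- lineup_design(6)
  desK <- lineup_design(6, 4)
  specs <- list(
    list(model_spec("tau1"), des),
    list(model_spec("tau4", "mu2"), des),
    list(model_spec("tau4", "sigma1",
                    restrictions = c("lambda_zero", "equal_variance")), des),
    list(model_spec("tau2", restrictions = "monotone_increasing_tau0"), des),
    list(model_spec("tau4", restrictions = "monotone_decreasing_tau0"), des),
    list(model_spec("tau4", "mu1", confidence = TRUE, mixture = TRUE), desK),
    list(model_spec("tau4", confidence = TRUE,
                    restrictions = "shared_kappa_across_positions"), desK))
  set.seed(1)
  for (sd_ in specs) {
    lay <- build_model(sd_[[1]], sd_[[2]])
    for (r in 1:3) {
      v <- rnorm(lay$n_free)
      p <- to_natural(lay, v)
      expect_s3_class(p, "sdt_params") # constructor enforces invariants
      expect_equal(from_natural(lay, p), v, tolerance = 1e-10)
    }
  }
  lay <- build_model(model_spec("tau4",
                                restrictions = "monotone_increasing_tau0"), des)
  for (r in 1:5)
    expect_true(!is.unsorted(to_natural(lay, rnorm(lay$n_free))$tau0))
  expect_error(to_natural(lay, rnorm(3)), "length")
})

test_that("restricted layouts reproduce parent-model probabilities at shared points", {
  des <- lineup_design(6)
  pairs <- list(
    c("tau2", "tau4"), # delta = 0 embeds tau2 in tau4
    c("lambda_zero", "full"))
  set.seed(2)
  # tau2 point inside tau4: same probabilities with delta = 0
  lay2 <- build_model(model_spec("tau2"), des)
  lay4 <- build_model(model_spec("tau4"), des)
  v2 <- rnorm(lay2$n_free)
  p2 <- to_natural(lay2, v2)
  v4 <- c(v2[1:8], 0, log(0.5)) # delta = 0, lambda arbitrary
  expect_equal(cell_probabilities_by_condition(to_natural(lay4, v4), des),
               cell_probabilities_by_condition(p2, des))
  # lambda-zero layout point inside the full kernel layout
  layz <- build_model(model_spec("tau4", restrictions = "lambda_zero"), des)
  vz <- rnorm(layz$n_free)
  pz <- to_natural(layz, vz)
  vf <- c(vz, -30) # lambda = exp(-30) ~ 0
  expect_equal(cell_probabilities_by_condition(to_natural(lay4, vf), des),
               cell_probabilities_by_condition(pz, des), tolerance = 1e-8)
  # monotone layout point inside the unrestricted layout
  laym <- build_model(model_spec("tau4",
                                 restrictions = "monotone_increasing_tau0"), des)
  vm <- rnorm(laym$n_free)
  pm <- to_natural(laym, vm)
  expect_equal(cell_probabilities_by_condition(
    to_natural(lay4, from_natural(lay4, pm)), des),
    cell_probabilities_by_condition(pm, des))
})

test_that("model-spec strings serialise and parse", {
  sp <- model_spec("tau4", "mu1", confidence = TRUE, mixture = TRUE,
                   restrictions = c("lambda_zero", "equal_variance"))
  s <- format_model_spec(sp)
  expect_match(s, "^tau4\\+mu1")
  expect_equal(parse_model_spec(s), sp)
  expect_equal(parse_model_spec("tau3+sigma2"), model_spec("tau3", "sigma2"))
})
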