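test_that("packaged tables match the published frequencies", {
  w <- builtin_table("wilson")
  expect_equal(unname(w$condition_totals),
               c(709, 696, 691, 699, 696, 701, 4151))
  expect_equal(sum(w$counts), 8343)
  expect_equal(w$counts["yes@1", "tp1"], 579)
  expect_equal(w$counts["yes@6", "tp6"], 214)
  expect_equal(w$counts["reject", "ta"], 1267)

  d <- builtin_table("dunn")
  expect_equal(d$counts["reject", "ta"], 790)
  expect_equal(d$counts["yes@1", "tp1"], 701)
  # totals derived from cells; published cells in the tp6 column sum to 939
  expect_equal(unname(d$condition_totals),
               c(983, 974, 1007, 970, 911, 939, 1420))
  expect_equal(sum(d$counts), 7204)
  expect_error(builtin_table("nosuch"))
})

test_that("CSV round trip is exact and validation names offending cells", {
  des <- lineup_design(6)
  w <- builtin_table("wilson")
  path <- withr::local_tempfile(fileext = ".csv")
  write_lineup_table(w, path)
  w2 <- read_lineup_table(path, des)
  expect_identical(w2$counts, w$counts)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_lineup_table(w2, path2)
  expect_identical(readLines(path), readLines(path2))

  # degenerate all-reject table
  m <- matrix(0, 7, 7); m[7, ] <- 5
  tab0 <- lineup_table(m, des)
  expect_equal(sum(tab0$counts[1:6, ]), 0)

  bad <- w$counts; bad["yes@2", "tp3"] <- -1
  expect_error(lineup_table(bad, des), "yes@2.*tp3")
  badf <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(category = rownames(w$counts), w$counts, check.names = FALSE)
  names(df)[3] <- "tpX"
  utils::write.csv(df, badf, row.names = FALSE)
  expect_error(read_lineup_table(badf, des), "header")
  expect_error(lineup_table(w$counts[1:6, ], des), "categories")
})

test_that("outcome summary reproduces the published percentages and hand arithmetic", {
  os <- outcome_summary(builtin_table("wilson"))
  expect_equal(round(100 * unclass(os), 1),
               c(TP1 = 52.3, TP2 = 38.8, TP3 = 8.9,
                 TA1 = 57.9, TA2 = 11.6, TA3 = 30.5))
  expect_equal(sum(os[1:3]), 1, tolerance = 1e-12)
  expect_equal(sum(os[4:6]), 1, tolerance = 1e-12)

  # toy two-face lineup, hand-computed
  des2 <- lineup_design(2)
  toy <- lineup_table(matrix(c(8, 1, 1, 0, 0, 0, 3, 0, 7), 3, 3), des2)
  expect_equal(unname(unclass(outcome_summary(toy))),
               c(0.8, 0.1, 0.1, 0.15, 0.15, 0.7))

  # pure-hit table
  m <- matrix(0, 7, 7)
  m[cbind(1:6, 1:6)] <- 10; m[7, 7] <- 10
  os2 <- outcome_summary(lineup_table(m, lineup_design(6)))
  expect_equal(unname(os2[c("TP1", "TA3")]), c(1, 1))
  expect_error(outcome_summary(simulate_table(random_params(K = 4, seed = 1),
                                              lineup_design(6, 4), 10, 1)),
               "binary")
})

test_that("hazard differences match direct computation and flag zero denominators", {
  hd <- hazard_differences(builtin_table("wilson"))
  expect_equal(hd["h=1", "i=2"], 2 / 130 - 539 / 3385, tolerance = 1e-12)
  expect_true(all(is.na(hd[lower.tri(hd)])))

  # identical hazards in all lure cells -> all differences zero
  m <- matrix(0, 7, 7)
  m[7, ] <- 50
  for (i in 1:6) m[i, ] <- 2^(6 - i) * 10 # same geometric chain everywhere
  m[cbind(1:6, 1:6)] <- m[cbind(1:6, 1:6)] # targets equal lures here
  tab <- lineup_table(m, lineup_design(6))
  expect_true(all(abs(hazard_differences(tab)) < 1e-12, na.rm = TRUE))

  # zero conditional denominator is NaN, not zero
  m2 <- matrix(0, 7, 7)
  m2[1, ] <- 10 # everyone says yes at position 1
  hd2 <- hazard_differences(lineup_table(m2, lineup_design(6)))
  expect_true(is.nan(hd2["h=1", "i=2"]))
})

test_that("target-rejection shifts leave a negative hazard signature; none without them", {
  des <- lineup_design(6)
  p_shift <- sdt_params(mu_T = 0.8, sigma2_T = 1, tau0 = rep(0.1, 6),
                        delta = 1, lambda = 0.5)
  tab <- simulate_table(p_shift, des, 2e5, seed = 42)
  hd <- hazard_differences(tab)
  expect_true(all(hd < 0, na.rm = TRUE))

  p_null <- sdt_params(mu_T = 0.8, sigma2_T = 1, tau0 = seq(0, 0.5, 0.1))
  tab0 <- simulate_table(p_null, des, 2e5, seed = 43)
  hd0 <- hazard_differences(tab0)
  expect_true(all(abs(hd0) < 0.02, na.rm = TRUE)) # Monte-Carlo error only
})
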