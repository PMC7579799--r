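test_that("null datasets preserve structure and follow the fitted model", {
  sc <- preset_scenarios(400)
  m <- generate_dyads(sc$null, seed = 91)
  calib <- fit_grm(m)
  s1 <- simulate_null_dataset(calib, m, seed = 7)
  s2 <- simulate_null_dataset(calib, m, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(s1$group, m$group)
  expect_identical(s1$respondent_id, m$respondent_id)
  # expected category frequencies match GRM probabilities averaged over
  # the conditioning theta pool, within multinomial error
  th <- calib$theta$theta
  for (j in c(1L, 4L)) {
    p <- calib$params[[j]]
    expected <- colMeans(grm_category_prob(th, p$a, p$b))
    observed <- tabulate(as.data.frame(s1)[[calib$items[j]]] + 1L,
                         length(expected)) / nrow(s1)
    se <- sqrt(expected * (1 - expected) / nrow(s1))
    expect_true(all(abs(observed - expected) < 4 * se + 1e-3))
  }
  # a group-specific calibration is not a valid null generator
  split <- fit_grm(m, dif_items = "it1")
  expect_error(simulate_null_dataset(split, m), "group-specific")
})

test_that("threshold tables are reproducible order statistics", {
  sc <- preset_scenarios(250)
  m <- generate_dyads(sc$null, seed = 92)
  t1 <- empirical_thresholds(m, subscale = "scale1", nrep = 40,
                             alpha = 0.05, seed = 13)
  t2 <- empirical_thresholds(m, subscale = "scale1", nrep = 40,
                             alpha = 0.05, seed = 13)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(attr(t1, "order_stat"), floor(0.05 * 41))
  draws <- attr(t1, "null_draws")
  expect_length(draws, 40L)
  # thresholds are the k-th order statistics of the stored null draws
  pu <- vapply(draws, function(d) d$p_uniform[d$item_id == "it2"], 0)
  expect_equal(t1$p_uniform[t1$item_id == "it2"],
               sort(pu)[attr(t1, "order_stat")])
  du <- vapply(draws, function(d) d$dr2_uniform[d$item_id == "it2"], 0)
  expect_equal(t1$dr2_uniform[t1$item_id == "it2"],
               sort(du, decreasing = TRUE)[attr(t1, "order_stat")])
  # smaller alpha: smaller p-value thresholds, larger statistic ones
  t3 <- empirical_thresholds(m, subscale = "scale1", nrep = 40,
                             alpha = 0.025, seed = 13)
  expect_true(all(t3$p_uniform <= t1$p_uniform))
  expect_true(all(t3$dr2_uniform >= t1$dr2_uniform))
  expect_true(all(t3$dbeta1 >= t1$dbeta1))
  # nrep must support the requested alpha
  expect_error(empirical_thresholds(m, subscale = "scale1", nrep = 40,
                                    alpha = 0.01, seed = 1),
               "nrep too small")
})

test_that("null traits can be drawn fresh instead of conditioning", {
  sc <- preset_scenarios(150)
  m <- generate_dyads(sc$null, seed = 93)
  t1 <- empirical_thresholds(m, subscale = "scale1", nrep = 20,
                             alpha = 0.05, seed = 3,
                             theta_source = "normal")
  expect_s3_class(t1, "threshold_table")
  expect_true(all(t1$p_uniform > 0 & t1$p_uniform < 1))
  expect_true(all(t1$dr2_uniform > 0))
})
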