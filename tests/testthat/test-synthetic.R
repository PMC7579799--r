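test_that("generation is reproducible and shaped as specified", {
  sc <- preset_scenarios()
  m1 <- generate_dyads(sc$null, seed = 4)
  m2 <- generate_dyads(sc$null, seed = 4)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_false(identical(as.data.frame(m1),
                         as.data.frame(generate_dyads(sc$null, seed = 5))))
  expect_equal(nrow(m1), 1000L)
  expect_equal(sort(unique(m1$group)), c("child", "parent"))
  p <- generate_dyads(sc$pedsql_like, seed = 1)
  expect_equal(nrow(p), 2L * 573L)
  expect_equal(ncol(p), 3L + 23L)
  expect_equal(unname(table(p$group)["child"]), 573L)
})

test_that("members are exchangeable when rho = 1 with no shift or DIF", {
  five <- toy_instrument(5)
  spec <- dyad_sim_spec(3000, five, rho = 1, group_trait_shift = 0)
  m <- generate_dyads(spec, seed = 21)
  y <- as.matrix(as.data.frame(m)[, paste0("q", 1:5)])
  for (j in 1:5) {
    tab <- table(m$group, factor(y[, j], levels = 0:4))
    # identical category distributions within multinomial error
    expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-4)
  }
})

test_that("marginal category frequencies match integrated GRM curves", {
  five <- toy_instrument(5)
  spec <- dyad_sim_spec(5000, five, rho = 0.5, group_trait_shift = 0)
  m <- generate_dyads(spec, seed = 31)
  grid <- seq(-6, 6, length.out = 601)
  w <- dnorm(grid); w <- w / sum(w)
  y <- as.matrix(as.data.frame(m)[, paste0("q", 1:5)])
  for (j in c(1L, 3L, 5L)) {
    p <- spec$item_params[[j]]
    expected <- colSums(w * grm_category_prob(grid, p$a, p$b))
    observed <- tabulate(y[, j] + 1L, 5L) / nrow(y)
    se <- sqrt(expected * (1 - expected) / nrow(y))
    expect_true(all(abs(observed - expected) < 3.5 * se + 1e-4))
  }
})

test_that("a threshold shift displaces only the targeted item", {
  five <- toy_instrument(5)
  n <- 4000
  spec <- dyad_sim_spec(n, five, rho = 1, group_trait_shift = 0,
                        dif = data.frame(item_id = "q3", delta = 0.6))
  m <- generate_dyads(spec, seed = 41)
  th <- attr(m, "theta")
  y <- as.matrix(as.data.frame(m)[, paste0("q", 1:5)])
  # rho = 1, no shift: both members share the same theta, so raw group
  # mean differences estimate the DIF effect at matched trait
  d <- vapply(1:5, function(j)
    mean(y[m$group == "parent", j]) - mean(y[m$group == "child", j]), 0)
  # conditional-mean oracle: E[Y|theta] under base vs shifted thresholds
  p3 <- spec$item_params[[3]]
  grid <- seq(-6, 6, length.out = 601)
  w <- dnorm(grid); w <- w / sum(w)
  ey <- function(b) sum(w * grm_category_prob(grid, p3$a, b) %*% 0:4)
  oracle_gap <- ey(p3$b) - ey(p3$b + 0.6)
  expect_equal(d[3], oracle_gap, tolerance = 0.08)
  expect_gt(d[3], 0.2)
  expect_true(all(abs(d[-3]) < 0.08))
})

test_that("sim specs validate their inputs", {
  five <- toy_instrument(5)
  expect_error(dyad_sim_spec(100, five,
                             dif = data.frame(item_id = "zz", delta = 1)),
               "unknown item")
  expect_error(dyad_sim_spec(100, five, rho = 1.2), "rho")
  sc <- dyad_sim_spec(50, five, missing_rate = 0.1)
  m <- generate_dyads(sc, seed = 3)
  frac <- mean(is.na(as.matrix(as.data.frame(m)[, paste0("q", 1:5)])))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.16)
})
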