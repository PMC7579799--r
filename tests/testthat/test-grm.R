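test_that("GRM curves have the logistic form and sum to one", {
  b <- c(-2, -1, 0, 1)
  expect_equal(grm_cumulative_prob(b[3], 1.7, b, 3), 0.5)
  # direct logistic evaluation oracle at a = 1.7, theta = 0
  expect_equal(grm_cumulative_prob(0, 1.7, b, 1), plogis(1.7 * 2))
  pk <- grm_category_prob(0, 1.7, b)
  cum <- plogis(1.7 * (0 - b))
  expect_equal(unname(pk[1, ]), c(1 - cum[1], cum[1] - cum[2],
                                  cum[2] - cum[3], cum[3] - cum[4],
                                  cum[4]))
  for (th in c(-3, -0.4, 0, 2.2))
    expect_equal(sum(grm_category_prob(th, 1.3, b)), 1)
})

test_that("EAP scores behave like posterior means", {
  sym <- lapply(1:5, function(j) list(a = 1.5, b = c(-1.5, -0.5, 0.5, 1.5)))
  # symmetric thresholds + middle category everywhere -> theta = 0
  e_mid <- eap_score(rep(2L, 5), sym)
  expect_equal(e_mid$theta, 0, tolerance = 1e-10)
  # top categories -> larger theta; shrinkage keeps posterior SD below 1
  e_top <- eap_score(rep(4L, 5), sym)
  expect_gt(e_top$theta, e_mid$theta)
  expect_gt(e_top$theta, 0)
  expect_lt(e_mid$se, 1)
  expect_lt(e_top$se, 1)
})

test_that("EAP matches brute-force integration on a 10x finer grid", {
  params <- list(list(a = 1.7, b = c(-2, -1, 0, 1)),
                 list(a = 1.2, b = c(-1.5, -0.5, 0.5, 1.5)),
                 list(a = 2.0, b = c(-1, -0.2, 0.8, 2)),
                 list(a = 1.5, b = c(-2.2, -1, 0.3, 1.2)),
                 list(a = 1.1, b = c(-0.8, 0, 0.9, 1.9)))
  pat <- c(4L, 2L, 1L, 3L, 0L)
  e <- eap_score(pat, params)
  grid <- seq(-4, 4, length.out = 481)
  w <- dnorm(grid); w <- w / sum(w)
  lik <- rep(1, length(grid))
  for (j in seq_along(params))
    lik <- lik * grm_category_prob(grid, params[[j]]$a,
                                   params[[j]]$b)[, pat[j] + 1]
  post <- lik * w / sum(lik * w)
  expect_equal(e$theta, sum(post * grid), tolerance = 5e-4)
  expect_equal(e$se, sqrt(sum(post * grid^2) - sum(post * grid)^2),
               tolerance = 5e-4)
})

test_that("simulate-then-refit recovers generating parameters", {
  set.seed(101)
  ids <- paste0("q", 1:10)
  inst <- instrument_spec("ten", data.frame(item_id = ids,
                                            subscale_id = "s"))
  truth <- default_item_params(ids)
  th <- rnorm(1000)
  y <- simulate_grm_responses(th, truth)
  df <- data.frame(respondent_id = paste0("r", 1:1000),
                   dyad_id = paste0("r", 1:1000), group = "g")
  df[ids] <- as.data.frame(y)
  fit <- fit_grm(response_matrix(df, inst))
  expect_true(fit$converged)
  # marginal log-likelihood is non-decreasing across EM iterations
  expect_true(all(diff(fit$loglik) > -1e-6 * abs(fit$loglik[-1])))
  pt <- grm_params_table(fit)
  true_a <- vapply(truth, `[[`, 0, "a")
  true_b <- t(vapply(truth, `[[`, numeric(4), "b"))
  expect_lt(mean(abs(pt$a - true_a)), 0.10)
  expect_lt(mean(abs(as.matrix(pt[, paste0("b_", 1:4)]) - true_b)), 0.12)
  # scale identification: EAP mean near 0, SD at most ~1 (shrinkage)
  expect_lt(abs(mean(fit$theta$theta)), 0.05)
  expect_lt(sd(fit$theta$theta), 1)
  expect_gt(sd(fit$theta$theta), 0.7)
})

test_that("group-specific calibration of identical groups matches pooled", {
  set.seed(55)
  ids <- paste0("q", 1:4)
  inst <- instrument_spec("four", data.frame(item_id = ids,
                                             subscale_id = "s"))
  truth <- default_item_params(ids)
  y <- simulate_grm_responses(rnorm(400), truth)
  m <- dyad_responses(y, y, inst)       # both groups see identical tables
  pooled <- fit_grm(m)
  split <- fit_grm(m, dif_items = ids)
  expect_length(split$params, 8L)
  for (id in ids) {
    ps <- Filter(function(p) p$item_id == id, split$params)
    expect_equal(ps[[1]]$a, ps[[2]]$a, tolerance = 1e-3)
    expect_equal(ps[[1]]$b, ps[[2]]$b, tolerance = 1e-3)
    pp <- Filter(function(p) p$item_id == id, pooled$params)
    expect_equal(ps[[1]]$a, pp[[1]]$a, tolerance = 5e-3)
    expect_equal(ps[[1]]$b, pp[[1]]$b, tolerance = 5e-3)
  }
  # empty dif set is a plain pooled calibration
  expect_equal(length(fit_grm(m, dif_items = character())$params), 4L)
})

test_that("sparse categories are collapsed with a retained mapping", {
  set.seed(8)
  ids <- paste0("q", 1:3)
  inst <- instrument_spec("three", data.frame(item_id = ids,
                                              subscale_id = "s"))
  # top category out at b = 3 is observed fewer than 5 times per group
  truth <- lapply(ids, function(id)
    list(item_id = id, a = 1.5, b = c(-1, 3)))
  names(truth) <- ids
  y <- simulate_grm_responses(rnorm(300), truth)
  m <- dyad_responses(y[1:150, , drop = FALSE], y[151:300, , drop = FALSE],
                      inst)
  fit <- fit_grm(m)
  expect_true(all(vapply(fit$collapse, max, 0L) <= 1L))  # 3 -> 2 levels
  expect_true(all(vapply(fit$params, function(p) length(p$b), 0L) == 1L))
})
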