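make_item_data <- function(n = 200, seed = 42, beta2 = 0, beta3 = 0) {
  set.seed(seed)
  th <- rnorm(n)
  g <- rep(c("a", "b"), length.out = n)
  gi <- as.numeric(g == "b")
  eta <- 1.3 * th + beta2 * gi + beta3 * th * gi
  b <- c(-1.5, -0.5, 0.5, 1.5)
  u <- runif(n)
  cum <- vapply(b, function(bk) plogis(eta - bk), numeric(n))
  y <- as.integer(rowSums(u <= cum))
  list(y = y, th = th, g = g)
}

test_that("intercept-only fit equals empirical cumulative log-odds", {
  d <- make_item_data()
  m0 <- fit_polr(d$y, d$th, d$g, 0)
  emp <- vapply(1:4, function(k) qlogis(mean(d$y >= k)), 0)
  expect_equal(m0$alpha, emp, tolerance = 1e-6)
  # trait constant at 0 reduces Model 1 to the intercept-only model
  m1c <- fit_polr(d$y, rep(0, length(d$y)), d$g, 1)
  expect_equal(m1c$alpha, emp, tolerance = 1e-6)
  expect_equal(m1c$loglik, m0$loglik, tolerance = 1e-8)
})

test_that("nested model log-likelihoods are monotone", {
  d <- make_item_data(seed = 7)
  lls <- vapply(0:3, function(k) fit_polr(d$y, d$th, d$g, k)$loglik, 0)
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("coefficients match an independent optimizer to 4 decimals", {
  skip_if_not_installed("MASS")
  d <- make_item_data(seed = 11, beta2 = 0.4, beta3 = 0.3)
  gi <- as.numeric(d$g == "b")
  for (mid in 1:3) {
    ours <- fit_polr(d$y, d$th, d$g, mid)
    form <- switch(mid, y ~ th, y ~ th + gi, y ~ th + gi + th:gi)
    dat <- data.frame(y = factor(d$y), th = d$th, gi = gi)
    mas <- MASS::polr(form, data = dat, method = "logistic")
    expect_equal(ours$loglik, as.numeric(logLik(mas)), tolerance = 1e-6)
    cf <- unname(coef(mas))
    expect_equal(ours$beta1, cf[1], tolerance = 1e-4)
    if (mid >= 2) expect_equal(ours$beta2, cf[2], tolerance = 1e-4)
    if (mid >= 3) expect_equal(ours$beta3, cf[3], tolerance = 1e-4)
    # alpha_k for P(Y >= k) is minus the P(Y <= k-1) cutpoint
    expect_equal(ours$alpha, unname(-mas$zeta), tolerance = 1e-4)
  }
})

test_that("likelihood-ratio p-values follow the chi-square(1) tail", {
  f <- function(ll) structure(list(loglik = ll), class = "polr_fit")
  expect_equal(lrt_chi2(f(-100), f(-100)),
               list(chi2 = 0, p = 1))
  expect_equal(lrt_chi2(f(-100), f(-100 + 6.635 / 2))$p, 0.01,
               tolerance = 1e-3)
  expect_equal(lrt_chi2(f(-100), f(-100 + 3.841 / 2))$p, 0.05,
               tolerance = 1e-3)
  expect_error(lrt_chi2(f(-99), f(-100)), "negative")
})

test_that("McFadden pseudo-R2 difference follows its definition", {
  f <- function(ll) structure(list(loglik = ll), class = "polr_fit")
  expect_equal(mcfadden_delta_r2(f(-80), f(-80), f(-100)), 0)
  expect_equal(mcfadden_delta_r2(f(-80), f(-75), f(-100)), 0.05)
  expect_error(mcfadden_delta_r2(f(-80), f(-75), f(0)), "degenerate")
})

test_that("CvBL beta1 change is the absolute proportionate change", {
  f <- function(b1, mid) structure(list(beta1 = b1, model_id = mid),
                                   class = "polr_fit")
  expect_equal(cvbl_delta_beta1(f(1, 1L), f(1, 2L)), 0)
  expect_equal(cvbl_delta_beta1(f(1.00, 1L), f(0.90, 2L)), 0.10)
  expect_equal(cvbl_delta_beta1(f(2.0, 1L), f(2.5, 2L)), 0.25)
  expect_true(is.na(cvbl_delta_beta1(f(0, 1L), f(1, 2L))))
})

test_that("classification applies non-uniform precedence and thresholds", {
  thr <- list(p_uniform = 0.0141, p_nonuniform = 0.0107,
              dr2_uniform = 0.0114, dr2_nonuniform = 0.0117,
              dbeta1 = 0.0391)
  # uniform only (a published physical-scale pattern)
  c1 <- classify_item(2e-04, 0.3156, dr2_uniform = 0.0243,
                      dr2_nonuniform = 0.0018, dbeta1 = 0.0135, thr)
  expect_equal(c1$flag, "uniform")
  expect_true(c1$practically_important)
  expect_false(c1$dbeta1_exceeds)
  # non-uniform subsumes a concurrent uniform signal
  thr2 <- list(p_uniform = 0.0110, p_nonuniform = 0.0327,
               dr2_uniform = 0.0063, dr2_nonuniform = 0.0046,
               dbeta1 = 0.0188)
  c2 <- classify_item(0.0000, 0.0029, dr2_uniform = 0.0155,
                      dr2_nonuniform = 0.0080, dbeta1 = 0.0187, thr2)
  expect_equal(c2$flag, "nonuniform")
  expect_true(c2$practically_important)
  # neither test fires
  c3 <- classify_item(0.5, 0.5, 0.001, 0.001, 0.001, thr)
  expect_equal(c3$flag, "none")
  # nominal-alpha mode leaves practical importance unassessed
  c4 <- classify_item(0.002, 0.5, 0.01, 0.001, 0.02,
                      list(p_uniform = 0.01, p_nonuniform = 0.01))
  expect_equal(c4$flag, "uniform")
  expect_true(is.na(c4$practically_important))
})

test_that("larger uniform chi2 implies larger uniform delta-R2", {
  # same null deviance links the LRT and the pseudo-R2 orderings
  d0 <- make_item_data(seed = 1, beta2 = 0)
  d1 <- make_item_data(seed = 1, beta2 = 0.8)
  s0 <- item_dif_stats(d0$y, d0$th, d0$g)
  s1 <- item_dif_stats(d1$y, d1$th, d1$g)
  expect_gt(s1$chi2_uniform, s0$chi2_uniform)
  expect_gt(s1$dr2_uniform, s0$dr2_uniform)
  expect_equal(s0$dr2_uniform > 0, s0$chi2_uniform > 0)
})

test_that("null uniform-DIF p-values are uniform (KS at 2000 reps)", {
  set.seed(77)
  ps <- numeric(2000)
  b <- c(-1.5, 0, 1.5)
  item <- list(list(a = 1.5, b = b))
  g <- rep(c("a", "b"), each = 100)
  for (r in seq_along(ps)) {
    th <- rnorm(200)
    y <- simulate_grm_responses(th, item)[, 1]
    m1 <- fit_polr(y, th, g, 1)
    m2 <- fit_polr(y, th, g, 2)
    ps[r] <- lrt_chi2(m1, m2)$p
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
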