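test_that("pooled-SD effect size reproduces published scale summaries", {
  expect_equal(round(cohen_effect_size(76.67, 13.90, 78.58, 13.52), 2),
               0.14)
  expect_equal(round(cohen_effect_size(78.11, 13.41, 81.20, 11.86), 2),
               0.24)
  expect_equal(cohen_effect_size(50, 10, 50, 12), 0)
  # symmetric in the two informants
  expect_equal(cohen_effect_size(70, 12, 75, 15),
               cohen_effect_size(75, 15, 70, 12))
  expect_true(is.na(cohen_effect_size(70, 0, 75, 0)))
})

test_that("effect-size and ICC labels are total with documented cutoffs", {
  expect_equal(es_label(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 2)),
               c("negligible", "negligible", "small", "small", "medium",
                 "medium", "large", "large"))
  expect_equal(icc_label(c(-0.1, 0.39, 0.40, 0.60, 0.61, 0.80, 0.81)),
               c("poor", "poor", "moderate", "moderate", "good", "good",
                 "excellent"))
})

test_that("paired t-test matches the textbook formula", {
  x <- c(72, 80, 65, 90, 84, 77, 69, 88, 75, 81)
  y <- c(70, 85, 60, 88, 80, 80, 65, 85, 70, 83)
  got <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  p_hand <- 2 * pt(-abs(t_hand), df = 9)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  expect_equal(got$mean_diff, mean(d))
  # degenerate conventions
  expect_equal(paired_t(x, x)$p, 1)
  expect_equal(paired_t(x, x)$mean_diff, 0)
  expect_equal(paired_t(c(1, 2, 3, 4), c(0, 1, 2, 3))$p, 0)
})

test_that("agreement ICC matches an ANOVA mean-squares hand computation", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  n <- 6; k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  msr <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(dat) - grand)^2) / (k - 1)
  mse <- (sum((dat - grand)^2) - msr * (n - 1) - msc * (k - 1)) /
    ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc_agreement(x, y), icc_hand, tolerance = 1e-12)
  # perfect agreement
  expect_equal(icc_agreement(x, x), 1)
  # a pure offset hurts agreement but not consistency
  expect_equal(icc_agreement(x, x + 3, type = "consistency"), 1)
  expect_lt(icc_agreement(x, x + 3), 1)
  # independent raters at large n give ICC near zero
  set.seed(12)
  expect_lt(abs(icc_agreement(rnorm(4000), rnorm(4000))), 0.05)
})

test_that("cancellation pairs opposite-direction uniform items greedily", {
  tab <- data.frame(
    item_id = c("a", "b", "c", "d", "e"),
    flag = c("uniform", "uniform", "uniform", "nonuniform", "none"),
    beta2 = c(0.8, -0.5, 0.3, 1.2, 0.9),
    stringsAsFactors = FALSE)
  part <- cancellation_partition(tab)
  expect_equal(part$cancelled_pairs, list(c("a", "b")))
  expect_equal(part$removed, "c")      # unpaired uniform item
  # two opposite items cancel completely; non-uniform never removed
  tab2 <- tab[tab$item_id %in% c("a", "b", "d"), ]
  expect_equal(cancellation_partition(tab2)$removed, character(0))
  # single uniform item stays uncancelled
  expect_equal(cancellation_partition(tab[1, ])$removed, "a")
  # no uniform items: nothing to do
  expect_equal(cancellation_partition(tab[4:5, ])$removed, character(0))
})

test_that("corrected agreement equals raw when nothing is flagged", {
  sc <- preset_scenarios(150)
  m <- generate_dyads(sc$null, seed = 71)
  noflag <- data.frame(item_id = paste0("it", 1:5), flag = "none",
                       beta2 = 0, stringsAsFactors = FALSE)
  tab <- corrected_agreement_table(m, list(scale1 = noflag),
                                   c("parent", "child"))
  raw <- tab[!tab$corrected, setdiff(names(tab), c("corrected", "note"))]
  corr <- tab[tab$corrected, setdiff(names(tab), c("corrected", "note"))]
  rownames(raw) <- rownames(corr) <- NULL
  expect_equal(raw, corr)
})

test_that("a fully uniform-flagged subscale has no corrected score", {
  sc <- preset_scenarios(120)
  m <- generate_dyads(sc$null, seed = 72)
  allu <- data.frame(item_id = paste0("it", 1:5), flag = "uniform",
                     beta2 = 0.5, stringsAsFactors = FALSE)
  tab <- corrected_agreement_table(m, list(scale1 = allu),
                                   c("parent", "child"))
  row <- tab[tab$corrected & tab$subscale == "scale1", ]
  expect_true(is.na(row$effect_size))
  expect_true(is.na(row$icc))
  expect_match(row$note, "no corrected score")
  # the raw block is still reported
  raw <- tab[!tab$corrected & tab$subscale == "scale1", ]
  expect_false(is.na(raw$effect_size))
})
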