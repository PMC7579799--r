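#' Fit one of the nested proportional-odds DIF models
#'
#' Cumulative-logit models for a single ordinal item, parameterised as
#' printed in DIF work:
#' `logit P(Y >= k) = alpha_k + beta1*trait + beta2*group +
#' beta3*trait*group`, with Model 1 containing only the trait term,
#' Model 2 adding the group main effect (uniform DIF) and Model 3 adding
#' the trait-by-group interaction (non-uniform DIF).  `model_id = 0` fits
#' the intercept-only null used by the McFadden pseudo-R2.  The group is
#' coded 0/1 with the reference level (coded 0) the first label
#' alphabetically unless `ref` pins it, so `beta2 > 0` means the non-
#' reference group endorses higher categories at equal trait.
#'
#' Fitting is by Newton-Raphson on the exact multinomial log-likelihood
#' with analytic gradient and Hessian and step-halving.  Unobserved
#' response categories are densified away before fitting; rows with a
#' missing response or trait are dropped.
#'
#' @param y Integer ordinal responses.
#' @param trait Matching trait values (typically EAP scores).
#' @param group Two-level factor/character/0-1 vector.
#' @param model_id 0, 1, 2 or 3.
#' @param ref Optional reference group label (coded 0).
#' @return A `polr_fit`: `model_id`, `alpha` (decreasing intercepts),
#'   `beta1`, `beta2`, `beta3` (`NA` when absent from the model),
#'   `loglik`, `converged`, `n`, `K`, `ref`.
#' @export
fit_polr <- function(y, trait, group, model_id = 1L, ref = NULL) {
  stopifnot(model_id %in% 0:3)
  n <- length(y)
  if (length(trait) != n || length(group) != n)
    stop("y, trait and group must have equal length", call. = FALSE)
  g <- as.character(group)
  glev <- sort(unique(g[!is.na(g)]))
  if (length(glev) != 2L)
    stop("group must have exactly 2 observed levels", call. = FALSE)
  if (is.null(ref)) ref <- glev[1] else stopifnot(ref %in% glev)
  gi <- as.numeric(g != ref)
  keep <- !is.na(y) & is.finite(trait) & !is.na(gi)
  y <- y[keep]; trait <- trait[keep]; gi <- gi[keep]

  lev <- sort(unique(y))
  if (length(lev) < 2L)
    stop("item has fewer than 2 observed response levels", call. = FALSE)
  yd <- match(y, lev) - 1L
  K <- length(lev)

  X <- switch(as.character(model_id),
              "0" = matrix(numeric(0), nrow = length(yd), ncol = 0L),
              "1" = cbind(trait),
              "2" = cbind(trait, gi),
              "3" = cbind(trait, gi, trait * gi))
  p <- ncol(X)
  alpha0 <- qlogis(pmin(pmax(
    vapply(seq_len(K - 1L), function(k) mean(yd >= k), 0),
    1e-4), 1 - 1e-4))
  fit <- .polr_newton_cpp(as.integer(yd), X, rep(1, length(yd)),
                          as.integer(K), c(alpha0, rep(0, p)))
  if (!fit$converged)
    stop("proportional-odds fit did not converge (model ", model_id, ")",
         call. = FALSE)
  structure(list(
    model_id = model_id,
    alpha = fit$alpha,
    beta1 = if (model_id >= 1) fit$beta[1] else NA_real_,
    beta2 = if (model_id >= 2) fit$beta[2] else NA_real_,
    beta3 = if (model_id >= 3) fit$beta[3] else NA_real_,
    loglik = fit$loglik, converged = fit$converged,
    n = length(yd), K = K, ref = ref), class = "polr_fit")
}

#' Likelihood-ratio chi-square between two nested fits
#'
#' `chi2 = 2 * (loglik_big - loglik_small)` referred to a chi-square
#' distribution with one degree of freedom (the nested DIF models differ
#' by one parameter).
#'
#' @param small,big Nested `polr_fit` objects (`big` has one extra
#'   parameter).
#' @return List with `chi2` and two-sided `p`.
#' @export
lrt_chi2 <- function(small, big) {
  chi2 <- 2 * (big$loglik - small$loglik)
  if (chi2 < -1e-6)
    stop("negative LRT chi-square: models not nested or fit failed",
         call. = FALSE)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' McFadden pseudo-R2 difference between nested fits
#'
#' McFadden's R2 is `1 - loglik(model)/loglik(null)`; the DIF magnitude
#' measure is its difference between the larger and the smaller nested
#' model, `(loglik_small - loglik_big) / loglik_null >= 0`.
#'
#' @param small,big Nested `polr_fit`s.
#' @param null Intercept-only `polr_fit` on the same data
#'   (`model_id = 0`).
#' @return Non-negative scalar.
#' @export
mcfadden_delta_r2 <- function(small, big, null) {
  if (abs(null$loglik) < .Machine$double.eps)
    stop("degenerate null model (zero log-likelihood)", call. = FALSE)
  (small$loglik - big$loglik) / null$loglik
}

#' Crane-van Belle-Larson proportionate beta1 change
#'
#' `|(beta1(Model 1) - beta1(Model 2)) / beta1(Model 1)|`: how much the
#' trait coefficient moves when the uniform group effect is added.
#'
#' @param m1,m2 `polr_fit`s for Models 1 and 2 of the same item.
#' @return Non-negative scalar; `NA` when `beta1(Model 1)` is 0.
#' @export
cvbl_delta_beta1 <- function(m1, m2) {
  stopifnot(m1$model_id == 1L, m2$model_id == 2L)
  if (m1$beta1 == 0) return(NA_real_)
  abs((m1$beta1 - m2$beta1) / m1$beta1)
}

#' Classify an item's DIF status from its p-values and thresholds
#'
#' Non-uniform DIF takes precedence: when the non-uniform test fires, the
#' item is classified non-uniform even if the uniform test also fires.
#' Practical importance compares the flag-matching pseudo-R2 difference
#' with its (Monte Carlo) threshold; for uniform flags the beta1-change
#' criterion is additionally reported against its threshold but does not
#' gate the flag.
#'
#' @param p_uniform,p_nonuniform LRT p-values.
#' @param dr2_uniform,dr2_nonuniform McFadden pseudo-R2 differences.
#' @param dbeta1 CvBL proportionate beta1 change.
#' @param thresholds Named list/row with `p_uniform`, `p_nonuniform` and
#'   optionally `dr2_uniform`, `dr2_nonuniform`, `dbeta1` (statistic
#'   thresholds may be `NA` when only nominal alpha testing is wanted).
#' @param gate_dbeta1 If `TRUE`, a uniform flag is kept only when the
#'   CvBL change also exceeds its threshold (default `FALSE`:
#'   descriptive reporting only).
#' @return List with `flag` (`"none"`, `"uniform"` or `"nonuniform"`),
#'   `practically_important` (logical, `NA` without statistic thresholds)
#'   and `dbeta1_exceeds` (uniform flags only).
#' @export
classify_item <- function(p_uniform, p_nonuniform,
                          dr2_uniform = NA_real_,
                          dr2_nonuniform = NA_real_,
                          dbeta1 = NA_real_, thresholds,
                          gate_dbeta1 = FALSE) {
  thr <- function(nm) {
    v <- thresholds[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  flag <- if (!is.na(p_nonuniform) && p_nonuniform < thr("p_nonuniform"))
    "nonuniform"
  else if (!is.na(p_uniform) && p_uniform < thr("p_uniform"))
    "uniform"
  else "none"
  if (flag == "uniform" && gate_dbeta1 && !is.na(thr("dbeta1")) &&
      !isTRUE(dbeta1 > thr("dbeta1")))
    flag <- "none"
  pi <- switch(flag,
    nonuniform = if (is.na(thr("dr2_nonuniform"))) NA
                 else isTRUE(dr2_nonuniform > thr("dr2_nonuniform")),
    uniform = if (is.na(thr("dr2_uniform"))) NA
              else isTRUE(dr2_uniform > thr("dr2_uniform")),
    "none" = NA)
  dbx <- if (flag == "uniform" && !is.na(thr("dbeta1")))
    isTRUE(dbeta1 > thr("dbeta1")) else NA
  list(flag = flag, practically_important = pi, dbeta1_exceeds = dbx)
}

#' All five DIF statistics for one item
#'
#' Fits the intercept-only null and Models 1-3, then computes the two
#' likelihood-ratio p-values, the two McFadden pseudo-R2 differences and
#' the CvBL beta1 change.
#'
#' @inheritParams fit_polr
#' @return One-row data frame: `p_uniform`, `p_nonuniform`,
#'   `chi2_uniform`, `chi2_nonuniform`, `dr2_uniform`, `dr2_nonuniform`,
#'   `dbeta1`, `beta1_m1`, `beta1_m2`, `beta2`, `beta3`, `loglik_0..3`.
#' @export
item_dif_stats <- function(y, trait, group, ref = NULL) {
  m0 <- fit_polr(y, trait, group, 0L, ref)
  m1 <- fit_polr(y, trait, group, 1L, ref)
  m2 <- fit_polr(y, trait, group, 2L, ref)
  m3 <- fit_polr(y, trait, group, 3L, ref)
  lu <- lrt_chi2(m1, m2)
  ln <- lrt_chi2(m2, m3)
  data.frame(
    p_uniform = lu$p, p_nonuniform = ln$p,
    chi2_uniform = lu$chi2, chi2_nonuniform = ln$chi2,
    dr2_uniform = mcfadden_delta_r2(m1, m2, m0),
    dr2_nonuniform = mcfadden_delta_r2(m2, m3, m0),
    dbeta1 = cvbl_delta_beta1(m1, m2),
    beta1_m1 = m1$beta1, beta1_m2 = m2$beta1,
    beta2 = m2$beta2, beta3 = m3$beta3,
    loglik_0 = m0$loglik, loglik_1 = m1$loglik,
    loglik_2 = m2$loglik, loglik_3 = m3$loglik)
}
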