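#' Simulate one no-DIF dataset matched to an observed calibration
#'
#' Draws, for every real respondent, item responses from the graded
#' response model at that respondent's EAP trait estimate, using the
#' pooled (shared, hence DIF-free by construction) item parameters of a
#' calibration fit.  Group labels, group sizes and the groups' trait
#' distributions are thereby preserved, which is the point of the Monte
#' Carlo calibration: logistic-regression DIF tests inflate their type-I
#' error exactly when the groups differ on the trait.
#'
#' @param fit A `grm_fit` from [fit_grm()] with no group-specific items
#'   (shared parameters).
#' @param m The [response_matrix()] the calibration was fitted to.
#' @param seed Optional seed (an already-seeded RNG stream is used when
#'   `NULL`, as inside [empirical_thresholds()]).
#' @param theta Optional trait values to condition on instead of the
#'   calibration's EAP estimates (e.g. fresh standard-normal draws).
#' @return A [response_matrix()] over the calibrated items, on their
#'   (possibly collapsed) category scale.
#' @export
simulate_null_dataset <- function(fit, m, seed = NULL, theta = NULL) {
  stopifnot(inherits(fit, "grm_fit"), inherits(m, "response_matrix"))
  if (length(fit$dif_items))
    stop("calibration has group-specific items; refit with dif_items ",
         "empty to obtain a DIF-free generating model", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(identical(fit$theta$respondent_id, m$respondent_id))
  if (is.null(theta)) theta <- fit$theta$theta
  stopifnot(length(theta) == nrow(m))
  y <- simulate_grm_responses(theta, fit$params)
  spec <- attr(m, "instrument")
  df <- data.frame(respondent_id = m$respondent_id, dyad_id = m$dyad_id,
                   group = m$group, stringsAsFactors = FALSE)
  df[fit$items] <- as.data.frame(y)
  response_matrix(df, restrict_instrument(spec, fit$items))
}

#' Per-item empirical DIF thresholds by Monte Carlo simulation
#'
#' Calibrates a pooled graded response model on the observed data, then
#' repeatedly (a) simulates a no-DIF dataset at the observed EAP traits
#' via [simulate_null_dataset()], (b) re-estimates the trait on the
#' simulated data (single pass, no purification: the null has nothing to
#' purify) and (c) computes all five per-item DIF statistics.  The
#' decision thresholds are order statistics of the null draws chosen so
#' that a fresh null statistic exceeds them with probability
#' `k / (nrep + 1)` where `k = floor(alpha * (nrep + 1))`: the k-th
#' smallest null p-value for the two chi-square tests and the k-th
#' largest null draw for the two pseudo-R2 differences and the beta1
#' change.  With `nrep = 1000` and `alpha = 0.01` this is the 10th order
#' statistic (attained level 10/1001).
#'
#' @param m A [response_matrix()] with exactly two group labels,
#'   restricted to one informant pair.
#' @param subscale Subscale to calibrate (default: all instrument items,
#'   for single-scale data).
#' @param nrep Number of null replicates (>= `ceiling(1/alpha) - 1`;
#'   1000 by default).
#' @param alpha Nominal per-item type-I error level (default 0.01).
#' @param seed Seed for the simulation stream.
#' @param ref Reference group label for the OLR fits.
#' @param theta_source `"observed"` (default) conditions each null
#'   replicate on the respondents' EAP traits, preserving the groups'
#'   trait-distribution differences; `"normal"` draws fresh standard
#'   normal traits per replicate instead.
#' @param retry_budget Fit failures are logged and the replicate redrawn,
#'   up to this many extra draws (default 20).
#' @param ... Passed to [fit_grm()] (e.g. `min_category_count`).
#' @return A `threshold_table` data frame: `item_id`, `p_uniform`,
#'   `p_nonuniform`, `dr2_uniform`, `dr2_nonuniform`, `dbeta1`, with
#'   attributes `nrep`, `alpha`, `seed`, `order_stat`, `null_draws`
#'   (list of per-replicate statistic tables) and `n_retries`.
#' @export
empirical_thresholds <- function(m, subscale = NULL, nrep = 1000L,
                                 alpha = 0.01, seed = 1L, ref = NULL,
                                 theta_source = c("observed", "normal"),
                                 retry_budget = 20L, ...) {
  theta_source <- match.arg(theta_source)
  stopifnot(inherits(m, "response_matrix"), alpha > 0, alpha < 1)
  k <- floor(alpha * (nrep + 1L))
  if (k < 1L)
    stop("nrep too small for alpha = ", alpha,
         " (need nrep >= ceiling(1/alpha) - 1)", call. = FALSE)
  spec <- attr(m, "instrument")
  items <- if (is.null(subscale)) spec$items$item_id
           else subscale_items(spec, subscale)
  glev <- sort(unique(m$group))
  stopifnot(length(glev) == 2L)
  if (is.null(ref)) ref <- glev[1]

  calib <- fit_grm(m, items, dif_items = character(), ...)
  if (!is.null(seed)) set.seed(seed)

  draws <- vector("list", nrep)
  failures <- 0L
  r <- 1L
  while (r <= nrep) {
    th0 <- if (theta_source == "normal") rnorm(nrow(m)) else NULL
    sim <- simulate_null_dataset(calib, m, theta = th0)
    res <- tryCatch({
      ft <- fit_grm(sim, items, dif_items = character(),
                    start = calib, ...)
      dif_screen(ft$theta$theta, ft$resp_collapsed, items, sim$group,
                 alpha, ref)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > retry_budget)
        stop("Monte Carlo simulation exceeded the retry budget (",
             retry_budget, " failures); last error: ",
             conditionMessage(res), call. = FALSE)
      next
    }
    draws[[r]] <- res
    r <- r + 1L
  }

  kth_small <- function(x) sort(x)[k]
  kth_large <- function(x) sort(x, decreasing = TRUE)[k]
  pull <- function(col) vapply(draws, function(d) d[[col]], numeric(length(items)))
  # pull() gives items x nrep (or a vector when one item)
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  pu <- as_mat(pull("p_uniform")); pn <- as_mat(pull("p_nonuniform"))
  du <- as_mat(pull("dr2_uniform")); dn <- as_mat(pull("dr2_nonuniform"))
  db <- as_mat(pull("dbeta1"))
  out <- data.frame(
    item_id = items,
    p_uniform = apply(pu, 1L, kth_small),
    p_nonuniform = apply(pn, 1L, kth_small),
    dr2_uniform = apply(du, 1L, kth_large),
    dr2_nonuniform = apply(dn, 1L, kth_large),
    dbeta1 = apply(db, 1L, kth_large),
    stringsAsFactors = FALSE)
  structure(out, nrep = nrep, alpha = alpha, seed = seed,
            order_stat = k, null_draws = draws, n_retries = failures,
            class = c("threshold_table", "data.frame"))
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table> nrep = ", attr(x, "nrep"), ", alpha = ",
      attr(x, "alpha"), " (order statistic ", attr(x, "order_stat"),
      ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
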