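#' Default graded-response item parameters for simulation
#'
#' Discriminations evenly spaced over 1.2-2.0 (informative items typical
#' of patient-reported-outcome scales) and, per item, `K - 1` thresholds
#' equally spaced around an item-specific centre so that all thresholds
#' lie within \[-2.5, 2.5\].
#'
#' @param item_ids Character vector of item ids.
#' @param n_categories Number of response categories.
#' @return Named list of per-item parameter lists (`item_id`, `a`, `b`).
#' @export
default_item_params <- function(item_ids, n_categories = 5L) {
  J <- length(item_ids)
  a <- if (J == 1L) 1.6 else seq(1.2, 2.0, length.out = J)
  centers <- if (J == 1L) 0 else seq(-0.7, 0.7, length.out = J)
  base <- seq(-1.8, 1.8, length.out = n_categories - 1L)
  out <- lapply(seq_len(J), function(j) {
    b <- base + centers[j]
    list(item_id = item_ids[j], a = a[j],
         b = pmin(pmax(b, -2.5), 2.5))
  })
  names(out) <- item_ids
  out
}

#' Specify a synthetic dyadic-response simulation
#'
#' Dyad members' latent traits are bivariate normal with correlation
#' `rho`; the second member's mean is shifted by `group_trait_shift`.
#' Responses come from the graded response model with the member's item
#' parameters; DIF is injected for the second group only, as a common
#' threshold shift `delta` (uniform/location DIF, mapping onto the group
#' main effect) and/or a discrimination ratio `gamma` (non-uniform DIF,
#' mapping onto the trait-by-group interaction).  `delta = 0` and
#' `gamma = 1` mean no DIF for an item.
#'
#' @param n_dyads Number of dyads (each contributes two respondents).
#' @param instrument An [instrument_spec()].
#' @param rho Trait correlation between dyad members, in \[-1, 1\].
#' @param group_trait_shift Mean trait of the second member minus the
#'   first (default -0.25: children rate their own problems slightly
#'   lower than parent proxies do).
#' @param item_params Per-item GRM parameters (default
#'   [default_item_params()]).
#' @param dif Optional data frame `item_id`, `delta`, `gamma`.
#' @param groups Length-2 character: first and second member labels.
#' @param missing_rate MCAR probability that a cell is missing.
#' @param seed Default seed used by [generate_dyads()].
#' @return A `dyad_sim_spec` list.
#' @export
dyad_sim_spec <- function(n_dyads, instrument, rho = 0.5,
                          group_trait_shift = -0.25, item_params = NULL,
                          dif = NULL, groups = c("parent", "child"),
                          missing_rate = 0, seed = 1L) {
  stopifnot(inherits(instrument, "instrument_spec"),
            n_dyads >= 1, abs(rho) <= 1, length(groups) == 2L,
            groups[1] != groups[2], missing_rate >= 0, missing_rate < 1)
  ids <- instrument$items$item_id
  if (is.null(item_params))
    item_params <- default_item_params(ids, instrument$n_categories)
  stopifnot(setequal(names(item_params), ids))
  difdf <- data.frame(item_id = ids, delta = 0, gamma = 1,
                      stringsAsFactors = FALSE)
  if (!is.null(dif)) {
    dif <- as.data.frame(dif)
    bad <- setdiff(dif$item_id, ids)
    if (length(bad))
      stop("dif references unknown item(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    i <- match(dif$item_id, difdf$item_id)
    if (!is.null(dif$delta)) difdf$delta[i] <- dif$delta
    if (!is.null(dif$gamma)) difdf$gamma[i] <- dif$gamma
  }
  structure(list(n_dyads = as.integer(n_dyads), instrument = instrument,
                 rho = rho, group_trait_shift = group_trait_shift,
                 item_params = item_params[ids], dif = difdf,
                 groups = groups, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "dyad_sim_spec")
}

#' Generate a synthetic dyadic response matrix
#'
#' @param spec A [dyad_sim_spec()].
#' @param seed Seed (defaults to `spec$seed`); the same seed always
#'   reproduces the same matrix.
#' @return A [response_matrix()] with `2 * n_dyads` rows; member traits
#'   are attached as attribute `"theta"` (data frame `respondent_id`,
#'   `group`, `theta`).
#' @export
generate_dyads <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dyad_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_dyads
  th1 <- rnorm(n)
  th2 <- spec$group_trait_shift + spec$rho * th1 +
    sqrt(1 - spec$rho^2) * rnorm(n)

  params2 <- lapply(seq_along(spec$item_params), function(j) {
    p <- spec$item_params[[j]]
    list(item_id = p$item_id,
         a = p$a * spec$dif$gamma[j],
         b = p$b + spec$dif$delta[j])
  })
  y1 <- simulate_grm_responses(th1, spec$item_params)
  y2 <- simulate_grm_responses(th2, params2)

  if (spec$missing_rate > 0) {
    y1[matrix(runif(length(y1)) < spec$missing_rate, nrow(y1))] <- NA
    y2[matrix(runif(length(y2)) < spec$missing_rate, nrow(y2))] <- NA
  }

  ids <- spec$instrument$items$item_id
  dyad <- sprintf("d%04d", seq_len(n))
  df1 <- data.frame(respondent_id = paste0(dyad, "_", spec$groups[1]),
                    dyad_id = dyad, group = spec$groups[1],
                    stringsAsFactors = FALSE)
  df2 <- data.frame(respondent_id = paste0(dyad, "_", spec$groups[2]),
                    dyad_id = dyad, group = spec$groups[2],
                    stringsAsFactors = FALSE)
  df1[ids] <- as.data.frame(y1)
  df2[ids] <- as.data.frame(y2)
  out <- response_matrix(rbind(df1, df2), spec$instrument)
  attr(out, "theta") <- data.frame(
    respondent_id = c(df1$respondent_id, df2$respondent_id),
    group = c(df1$group, df2$group), theta = c(th1, th2),
    stringsAsFactors = FALSE)
  out
}

#' Shipped simulation scenarios
#'
#' Named [dyad_sim_spec()]s used throughout the test and calibration
#' suites:
#' \describe{
#'   \item{null}{5 items, one subscale, 500 dyads, no DIF.}
#'   \item{one_uniform}{as `null` with a 0.6 threshold shift on item 3.}
#'   \item{opposite_pair}{uniform shifts +0.6 on item 2 and -0.6 on
#'     item 4 (domain-level cancellation).}
#'   \item{one_nonuniform}{discrimination ratio 2 on item 3.}
#'   \item{pedsql_like}{23 PedsQL items, 4 subscales, 573 dyads, no DIF
#'     (a typical field-study sample size).}
#' }
#'
#' @param n_dyads Dyad count for the five-item scenarios (default 500).
#' @return Named list of `dyad_sim_spec`s.
#' @export
preset_scenarios <- function(n_dyads = 500L) {
  five <- instrument_spec(
    "five-item scale",
    data.frame(item_id = paste0("it", 1:5), subscale_id = "scale1"))
  list(
    null = dyad_sim_spec(n_dyads, five),
    one_uniform = dyad_sim_spec(
      n_dyads, five, dif = data.frame(item_id = "it3", delta = 0.6)),
    opposite_pair = dyad_sim_spec(
      n_dyads, five,
      dif = data.frame(item_id = c("it2", "it4"), delta = c(0.6, -0.6))),
    one_nonuniform = dyad_sim_spec(
      n_dyads, five, dif = data.frame(item_id = "it3", gamma = 2)),
    pedsql_like = dyad_sim_spec(573L, pedsql_spec()))
}
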