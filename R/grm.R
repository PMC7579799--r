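#' Cumulative probability of the graded response model
#'
#' `P(Y >= k | theta) = plogis(a * (theta - b_k))` with `P(Y >= 0) = 1`
#' and `P(Y >= K) = 0`.
#'
#' @param theta Latent trait value(s).
#' @param a Discrimination (> 0).
#' @param b Ordered threshold vector `b_1 < ... < b_{K-1}`.
#' @param k Category index `1 .. K-1`.
#' @return Probability vector the same length as `theta`.
#' @export
grm_cumulative_prob <- function(theta, a, b, k) {
  stopifnot(a > 0, k >= 1, k <= length(b))
  plogis(a * (theta - b[k]))
}

#' Category probabilities of the graded response model
#'
#' @inheritParams grm_cumulative_prob
#' @return Matrix `length(theta) x K` of `P(Y = k | theta)`,
#'   `k = 0 .. K-1`; rows sum to 1.
#' @export
grm_category_prob <- function(theta, a, b) {
  K <- length(b) + 1L
  mid <- vapply(seq_len(K - 1L),
                function(k) grm_cumulative_prob(theta, a, b, k),
                numeric(length(theta)))
  if (is.null(dim(mid))) mid <- matrix(mid, nrow = length(theta))
  cum <- cbind(1, mid, 0)
  out <- cum[, -(K + 1L), drop = FALSE] - cum[, -1L, drop = FALSE]
  colnames(out) <- as.character(0:(K - 1L))
  out
}

# normal quadrature on an equally spaced grid
grm_quadrature <- function(n_points = 49L, range = 4) {
  grid <- seq(-range, range, length.out = n_points)
  w <- dnorm(grid)
  list(grid = grid, weights = w / sum(w))
}

# Collapse observed categories with fewer than min_count responses in
# either group with their neighbour; unobserved categories are dropped.
# Returns the recoded vector, the new category count and the mapping
# (named integer vector: original value -> recoded value).
collapse_item <- function(y, group, min_count = 5L) {
  obs <- sort(unique(y[!is.na(y)]))
  if (length(obs) < 2L)
    stop("item has fewer than 2 observed categories", call. = FALSE)
  glev <- unique(group)
  cnt <- vapply(obs, function(v)
    min(vapply(glev, function(g) sum(y == v & group == g, na.rm = TRUE),
               0L)), 0L)
  groups <- as.list(seq_along(obs))   # indices into obs per merged block
  repeat {
    sizes <- vapply(groups, function(ix) sum(cnt[ix]), 0)
    if (length(groups) <= 2L || all(sizes >= min_count)) break
    i <- which.min(sizes)
    j <- if (i == 1L) 2L
         else if (i == length(groups)) i - 1L
         else if (sizes[i - 1L] <= sizes[i + 1L]) i - 1L else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    groups[[lo]] <- c(groups[[lo]], groups[[hi]])
    groups[[hi]] <- NULL
  }
  map <- integer(length(obs))
  for (g in seq_along(groups)) map[groups[[g]]] <- g - 1L
  names(map) <- as.character(obs)
  ynew <- map[as.character(y)]
  ynew[is.na(y)] <- NA_integer_
  list(y = unname(ynew), K = length(groups), map = map)
}

# starting thresholds from observed cumulative category frequencies
start_thresholds <- function(y, K) {
  p <- vapply(seq_len(K - 1L), function(k) mean(y >= k, na.rm = TRUE),
              0)
  p <- pmin(pmax(p, 0.005), 0.995)
  b <- -qlogis(p)
  # enforce strict increase in degenerate cases
  for (k in seq_along(b)[-1])
    if (b[k] <= b[k - 1L]) b[k] <- b[k - 1L] + 0.05
  b
}

# one M-step update of a single item from its expected count table r (Q x K)
mstep_item <- function(r, grid, a0, b0) {
  Q <- nrow(r); K <- ncol(r)
  y <- rep(0:(K - 1L), each = Q)
  X <- matrix(rep(grid, K), ncol = 1L)
  w <- as.vector(r)
  start <- c(-a0 * b0, a0)
  fit <- .polr_newton_cpp(as.integer(y), X, w, as.integer(K), start,
                          max_iter = 30L, tol = 1e-10)
  a <- fit$beta[1]
  if (!is.finite(a) || a < 1e-3) a <- 1e-3
  list(a = a, b = sort(-fit$alpha / a))
}

#' Calibrate a graded response model by marginal maximum likelihood
#'
#' Fits Samejima's graded response model to pooled two-group data with an
#' EM algorithm over a fixed normal quadrature (49 equally spaced nodes on
#' \[-4, 4\] by default; the latent trait is identified by its standard
#' normal prior).  Items named in `dif_items` are calibrated separately
#' per group (internally they are expanded into per-group pseudo-items
#' that are missing for the other group); all other items share one
#' parameter set.  Observed categories with fewer than
#' `min_category_count` responses in either group are collapsed with
#' their neighbour before fitting, and the mapping is retained.
#' Expected-a-posteriori trait estimates under the fitted parameters are
#' returned for every respondent.
#'
#' @param m A [response_matrix()] with exactly two group labels.
#' @param items Item ids to calibrate (default: all instrument items).
#' @param dif_items Items receiving group-specific parameters.
#' @param min_category_count Collapsing threshold (default 5).
#' @param n_quad,quad_range Quadrature size and half-range.
#' @param tol EM stops when the largest absolute parameter change drops
#'   below `tol` (default 1e-4).
#' @param max_iter Maximum EM iterations (default 500).
#' @param start Optional warm start: a `grm_fit` on the same items whose
#'   parameters seed the EM.
#' @param impute Missing-response handling for fitting: `"none"` leaves
#'   them out of the likelihood (the default), `"mean"` replaces them by
#'   the rounded within-group item mean before fitting.
#' @return A `grm_fit` object: `params` (list per pseudo-item:
#'   `item_id`, `group` (`NA` when shared), `a`, `b`), `theta` (data frame
#'   of EAP estimates `respondent_id`, `group`, `theta`, `se`), `loglik`
#'   (per-iteration marginal log-likelihood, non-decreasing), `converged`,
#'   `n_iter`, `collapse` (per-item category maps), `quad`.
#' @export
fit_grm <- function(m, items = NULL, dif_items = character(),
                    min_category_count = 5L, n_quad = 49L, quad_range = 4,
                    tol = 1e-4, max_iter = 500L, start = NULL,
                    impute = c("none", "mean")) {
  stopifnot(inherits(m, "response_matrix"))
  impute <- match.arg(impute)
  spec <- attr(m, "instrument")
  if (is.null(items)) items <- spec$items$item_id
  if (length(items) < 2L) stop("need at least 2 items", call. = FALSE)
  group <- m$group
  glev <- sort(unique(group))
  x <- resp_matrix_of(m, items)
  if (impute == "mean") x <- impute_item_means(x, group)

  # collapse sparse categories per item
  collapse <- vector("list", length(items))
  names(collapse) <- items
  Kj <- integer(length(items))
  for (j in seq_along(items)) {
    cc <- collapse_item(x[, j], group, min_category_count)
    x[, j] <- cc$y
    Kj[j] <- cc$K
    collapse[[j]] <- cc$map
  }

  # expand DIF items into per-group pseudo-items
  dif_items <- intersect(items, dif_items)
  pseudo <- data.frame(item_id = character(), group = character(),
                       stringsAsFactors = FALSE)
  cols <- list()
  for (j in seq_along(items)) {
    if (items[j] %in% dif_items && length(glev) > 1L) {
      for (g in glev) {
        v <- x[, j]
        v[group != g] <- NA_integer_
        cols[[length(cols) + 1L]] <- v
        pseudo <- rbind(pseudo, data.frame(item_id = items[j], group = g,
                                           stringsAsFactors = FALSE))
      }
    } else {
      cols[[length(cols) + 1L]] <- x[, j]
      pseudo <- rbind(pseudo, data.frame(item_id = items[j],
                                         group = NA_character_,
                                         stringsAsFactors = FALSE))
    }
  }
  xp <- do.call(cbind, cols)
  xp[is.na(xp)] <- -1L
  storage.mode(xp) <- "integer"
  Kp <- Kj[match(pseudo$item_id, items)]

  quad <- grm_quadrature(n_quad, quad_range)

  # starting values: a = 1, thresholds from cumulative frequencies,
  # or a warm start from a previous fit on the same items
  a <- rep(1, nrow(pseudo))
  b <- lapply(seq_len(nrow(pseudo)), function(p) {
    y <- xp[, p]
    start_thresholds(y[y >= 0L], Kp[p])
  })
  if (!is.null(start)) {
    for (p in seq_len(nrow(pseudo))) {
      hit <- which(vapply(start$params, function(pp)
        identical(pp$item_id, pseudo$item_id[p]) &&
          length(pp$b) == Kp[p] - 1L, TRUE))
      if (length(hit)) {
        a[p] <- start$params[[hit[1]]]$a
        b[[p]] <- start$params[[hit[1]]]$b
      }
    }
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- .grm_estep_cpp(xp, a, b, quad$grid, quad$weights, FALSE)
    ll_trace <- c(ll_trace, es$loglik)
    if (it > 1L && es$loglik < ll_trace[it - 1L] -
        1e-6 * abs(ll_trace[it - 1L]))
      stop("EM log-likelihood decreased at iteration ", it, call. = FALSE)
    delta <- 0
    for (p in seq_len(nrow(pseudo))) {
      up <- mstep_item(es$r[[p]], quad$grid, a[p], b[[p]])
      delta <- max(delta, abs(up$a - a[p]), abs(up$b - b[[p]]))
      a[p] <- up$a
      b[[p]] <- up$b
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GRM EM did not converge in ", max_iter, " iterations",
            call. = FALSE)

  final <- .grm_estep_cpp(xp, a, b, quad$grid, quad$weights, TRUE)
  params <- lapply(seq_len(nrow(pseudo)), function(p)
    list(item_id = pseudo$item_id[p], group = pseudo$group[p],
         a = a[p], b = b[[p]]))
  structure(list(
    params = params,
    items = items, dif_items = dif_items, groups = glev,
    theta = data.frame(respondent_id = m$respondent_id, group = group,
                       theta = final$theta, se = final$se,
                       stringsAsFactors = FALSE),
    loglik = c(ll_trace, final$loglik),
    converged = converged, n_iter = length(ll_trace),
    collapse = collapse, quad = quad,
    resp_collapsed = {
      colnames(x) <- items
      x
    }),
    class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("<grm_fit> ", length(x$items), " items (",
      length(x$dif_items), " group-specific), ",
      x$n_iter, " EM iterations, loglik ",
      sprintf("%.2f", x$loglik[length(x$loglik)]),
      if (x$converged) "" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Parameter table of a GRM fit
#'
#' @param fit A `grm_fit`.
#' @return Data frame `item_id`, `group`, `a`, `b_1 .. b_{Kmax-1}` (NA
#'   padded for items with collapsed categories), suitable for TSV export.
#' @export
grm_params_table <- function(fit) {
  stopifnot(inherits(fit, "grm_fit"))
  kmax <- max(vapply(fit$params, function(p) length(p$b), 0L))
  rows <- lapply(fit$params, function(p) {
    b <- c(p$b, rep(NA_real_, kmax - length(p$b)))
    cbind(data.frame(item_id = p$item_id, group = p$group, a = p$a,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            b, paste0("b_", seq_len(kmax))))))
  })
  do.call(rbind, rows)
}

#' Expected-a-posteriori trait scores
#'
#' Posterior mean and SD of the latent trait under a standard normal
#' prior, evaluated on the same quadrature grid used for fitting.
#' Missing responses contribute nothing to the likelihood.  The posterior
#' SD is below 1 whenever at least one item is answered (shrinkage).
#'
#' @param responses Integer matrix (respondents x items, `NA` = missing)
#'   or a single pattern vector, already on the (possibly collapsed)
#'   category scale of `params`.
#' @param params List of per-item parameter lists (`a`, `b`), e.g.
#'   `fit$params` of a [fit_grm()] on the same items.
#' @param n_quad,quad_range Quadrature settings (match the fit).
#' @return Data frame with columns `theta` and `se`.
#' @export
eap_score <- function(responses, params, n_quad = 49L, quad_range = 4) {
  if (is.null(dim(responses)))
    responses <- matrix(responses, nrow = 1L)
  x <- responses
  x[is.na(x)] <- -1L
  storage.mode(x) <- "integer"
  a <- vapply(params, function(p) p$a, 0)
  b <- lapply(params, function(p) p$b)
  stopifnot(ncol(x) == length(a))
  quad <- grm_quadrature(n_quad, quad_range)
  es <- .grm_estep_cpp(x, a, b, quad$grid, quad$weights, TRUE)
  data.frame(theta = es$theta, se = es$se)
}

# round within-group item means into missing cells
impute_item_means <- function(x, group) {
  for (g in unique(group)) {
    rows <- group == g
    for (j in seq_len(ncol(x))) {
      miss <- rows & is.na(x[, j])
      if (any(miss))
        x[miss, j] <- as.integer(round(mean(x[rows, j], na.rm = TRUE)))
    }
  }
  x
}

#' Simulate graded-response-model item responses
#'
#' Draws one response per respondent and item from the GRM category
#' distribution at that respondent's trait value.
#'
#' @param theta Numeric vector of trait values.
#' @param params List of per-item parameter lists (`a`, `b`).
#' @return Integer matrix `length(theta) x length(params)`.
#' @export
simulate_grm_responses <- function(theta, params) {
  n <- length(theta)
  out <- matrix(0L, n, length(params))
  for (j in seq_along(params)) {
    b <- params[[j]]$b
    a <- params[[j]]$a
    u <- runif(n)
    cum <- vapply(seq_along(b), function(k) plogis(a * (theta - b[k])),
                  numeric(n))
    if (n == 1L) cum <- matrix(cum, nrow = 1L)
    out[, j] <- as.integer(rowSums(u <= cum))
  }
  out
}
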