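# subset rows of a response_matrix, preserving class and instrument
subset_responses <- function(m, rows) {
  spec <- attr(m, "instrument")
  out <- as.data.frame(m)[rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, instrument = spec,
            class = c("response_matrix", "data.frame"))
}

restrict_instrument <- function(spec, items) {
  keep <- spec$items[spec$items$item_id %in% items, , drop = FALSE]
  instrument_spec(spec$name, keep, spec$n_categories)
}

# resolve per-item thresholds for classification
item_thresholds <- function(thresholds, item_id) {
  if (is.numeric(thresholds) && length(thresholds) == 1L)
    return(list(p_uniform = thresholds, p_nonuniform = thresholds,
                dr2_uniform = NA_real_, dr2_nonuniform = NA_real_,
                dbeta1 = NA_real_))
  stopifnot(inherits(thresholds, "threshold_table"))
  i <- match(item_id, thresholds$item_id)
  if (is.na(i))
    stop("no thresholds for item ", item_id, call. = FALSE)
  as.list(thresholds[i, c("p_uniform", "p_nonuniform", "dr2_uniform",
                          "dr2_nonuniform", "dbeta1")])
}

# one non-iterative DIF screen over `items`, conditioning on `theta`;
# `y` holds the (collapsed) responses for all screened items
dif_screen <- function(theta, y, items, group, thresholds, ref,
                       gate_dbeta1 = FALSE) {
  rows <- vector("list", length(items))
  for (j in seq_along(items)) {
    st <- item_dif_stats(y[, items[j]], theta, group, ref)
    thr <- item_thresholds(thresholds, items[j])
    cls <- classify_item(st$p_uniform, st$p_nonuniform, st$dr2_uniform,
                         st$dr2_nonuniform, st$dbeta1, thr,
                         gate_dbeta1 = gate_dbeta1)
    rows[[j]] <- cbind(
      data.frame(item_id = items[j], stringsAsFactors = FALSE), st,
      data.frame(thr_p_uniform = thr$p_uniform,
                 thr_p_nonuniform = thr$p_nonuniform,
                 thr_dr2_uniform = thr$dr2_uniform,
                 thr_dr2_nonuniform = thr$dr2_nonuniform,
                 thr_dbeta1 = thr$dbeta1,
                 flag = cls$flag,
                 practically_important = cls$practically_important,
                 stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Iterative hybrid OLR/IRT DIF analysis of one subscale
#'
#' Alternates graded-response-model trait estimation and per-item
#' proportional-odds DIF testing until the flagged item set stabilises.
#' Iteration 1 calibrates all items jointly (pooled); iteration `t`
#' recalibrates with group-specific parameters for the items flagged at
#' `t - 1` (trait purification), re-scores all respondents by EAP, and
#' re-tests every item conditioning on the purified trait.  The
#' procedure stops when two successive iterations flag the same items.
#' When nothing is flagged at iteration 1 the recalibration model is
#' unchanged, so the confirming second iteration is recorded without
#' refitting.  If the flagged set oscillates between two states until
#' `max_iter`, the union is reported with status `"unstable"`.
#'
#' @param m A [response_matrix()] with exactly two group labels.
#' @param subscale Subscale id to analyse (each subscale has its own
#'   matching trait).
#' @param thresholds Either a single nominal alpha (both LRT p-values are
#'   compared against it; no practical-importance gating) or a
#'   `threshold_table` from [empirical_thresholds()].
#' @param max_iter Maximum purification iterations (default 10).
#' @param ref Reference group label (coded 0); default: first
#'   alphabetically.
#' @param purify `"recalibrate"` (default) gives flagged items
#'   group-specific parameters during trait estimation; `"drop"` removes
#'   them from trait estimation entirely (falling back to recalibration
#'   when fewer than 2 items would remain).
#' @param gate_dbeta1 If `TRUE`, a uniform flag additionally requires the
#'   CvBL beta1 change to exceed its threshold (default `FALSE`: the
#'   CvBL criterion is reported descriptively).
#' @param impute Missing-response handling passed to [fit_grm()].
#' @param min_category_count Sparse-category collapsing threshold.
#' @param seed Optional seed (the procedure itself is deterministic given
#'   the data; the seed is set for reproducibility of any downstream use).
#' @return A `hybrid_dif` object: `flagged` (final flagged item ids),
#'   `table` (final per-item statistics/threshold/flag data frame),
#'   `status` (`"converged"`, `"unstable"` or `"nonconverged"`),
#'   `n_iter`, `trace` (list per iteration: `iteration`, `flagged`,
#'   `table`, `theta`), `fit` (final `grm_fit`), `subscale`, `groups`,
#'   `ref`.
#' @export
run_hybrid_dif <- function(m, subscale, thresholds = 0.01, max_iter = 10L,
                           ref = NULL, purify = c("recalibrate", "drop"),
                           gate_dbeta1 = FALSE,
                           impute = c("none", "mean"),
                           min_category_count = 5L, seed = NULL) {
  stopifnot(inherits(m, "response_matrix"))
  impute <- match.arg(impute)
  purify <- match.arg(purify)
  if (!is.null(seed)) set.seed(seed)
  spec <- attr(m, "instrument")
  items <- subscale_items(spec, subscale)
  if (length(items) < 2L)
    stop("subscale ", subscale, " has fewer than 2 items", call. = FALSE)
  glev <- sort(unique(m$group))
  if (length(glev) != 2L)
    stop("need exactly 2 group labels, got: ",
         paste(glev, collapse = ", "), call. = FALSE)
  if (is.null(ref)) ref <- glev[1]

  trace <- list()
  flags_prev <- NULL
  flags <- character(0)
  status <- "nonconverged"
  fit <- NULL
  y_all <- NULL
  for (it in seq_len(max_iter)) {
    drop_mode <- purify == "drop" && length(flags) > 0L &&
      length(setdiff(items, flags)) >= 2L
    fit <- fit_grm(m,
                   items = if (drop_mode) setdiff(items, flags) else items,
                   dif_items = if (drop_mode) character() else flags,
                   min_category_count = min_category_count,
                   impute = impute, start = fit)
    if (it == 1L) y_all <- fit$resp_collapsed  # collapse is data-determined
    tab <- dif_screen(fit$theta$theta, y_all, items, m$group, thresholds,
                      ref, gate_dbeta1)
    flags_prev <- flags
    flags <- tab$item_id[tab$flag != "none"]
    trace[[it]] <- list(iteration = it, flagged = flags, table = tab,
                        theta = fit$theta)
    if (it == 1L && length(flags) == 0L) {
      # empty set: the purification model is unchanged, so iteration 2
      # would reproduce iteration 1 exactly; record the confirmation
      trace[[2L]] <- trace[[1L]]
      trace[[2L]]$iteration <- 2L
      status <- "converged"
      break
    }
    if (it > 1L && setequal(flags, flags_prev)) {
      status <- "converged"
      break
    }
  }
  if (status != "converged") {
    nt <- length(trace)
    if (nt >= 3L &&
        setequal(trace[[nt]]$flagged, trace[[nt - 2L]]$flagged)) {
      status <- "unstable"
      flags <- union(trace[[nt]]$flagged, trace[[nt - 1L]]$flagged)
    }
  }
  structure(list(flagged = flags,
                 table = trace[[length(trace)]]$table,
                 status = status, n_iter = length(trace), trace = trace,
                 fit = fit, subscale = subscale, groups = glev,
                 ref = ref, thresholds = thresholds),
            class = "hybrid_dif")
}

#' @export
print.hybrid_dif <- function(x, ...) {
  cat("<hybrid_dif> subscale ", x$subscale, " (", x$groups[1], " vs ",
      x$groups[2], "), ", x$n_iter, " iterations, status ", x$status,
      "\n", sep = "")
  if (length(x$flagged)) {
    f <- x$table[x$table$flag != "none", c("item_id", "flag")]
    cat("flagged:", paste(sprintf("%s (%s)", f$item_id, f$flag),
                          collapse = ", "), "\n")
  } else cat("no items flagged\n")
  invisible(x)
}

#' Hybrid DIF analysis for several informant pairs
#'
#' Runs [run_hybrid_dif()] independently for every group pair and
#' subscale (e.g. mother-daughter, father-daughter, mother-son,
#' father-son) and summarises the flag patterns across pairs.
#'
#' @param m A [response_matrix()] whose `group` column contains all
#'   labels named by `pairs`.
#' @param pairs List of length-2 character vectors of group labels.
#' @param subscales Subscale ids (default: all).
#' @param thresholds `"analytic"` (nominal `alpha`) or `"montecarlo"`
#'   (per-item empirical thresholds from [empirical_thresholds()],
#'   computed per pair and subscale from the pooled calibration).
#' @param alpha Nominal type-I error level (default 0.01).
#' @param nrep Monte Carlo replicates when `thresholds = "montecarlo"`.
#' @param seed Seed for the Monte Carlo draws.
#' @param theta_source Null-trait conditioning mode for
#'   [empirical_thresholds()].
#' @param ... Passed on to [run_hybrid_dif()].
#' @return A `dyad_dif_results` list: `runs` (nested
#'   `[[pair]][[subscale]]` of `hybrid_dif`), `summary` (data frame
#'   `pair`, `subscale`, `n_items`, `n_flagged`, `n_uniform`,
#'   `n_nonuniform`, `status`) and `thresholds` (nested threshold
#'   tables, when Monte Carlo ones were computed).
#' @export
run_all_dyads <- function(m, pairs, subscales = NULL,
                          thresholds = c("analytic", "montecarlo"),
                          alpha = 0.01, nrep = 1000L, seed = 1L,
                          theta_source = c("observed", "normal"), ...) {
  theta_source <- match.arg(theta_source)
  stopifnot(inherits(m, "response_matrix"))
  thresholds <- match.arg(thresholds)
  spec <- attr(m, "instrument")
  if (is.null(subscales)) subscales <- spec$subscales
  runs <- list()
  thr_out <- list()
  summ <- list()
  for (pr in pairs) {
    stopifnot(length(pr) == 2L)
    bad <- setdiff(pr, unique(m$group))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    key <- paste(pr, collapse = "_vs_")
    sub <- subset_responses(m, m$group %in% pr)
    if (min(table(sub$group)) < 2L) {
      warning("pair ", key, " has a group with < 2 respondents; skipped",
              call. = FALSE)
      next
    }
    runs[[key]] <- list()
    thr_out[[key]] <- list()
    for (s in subscales) {
      thr <- if (thresholds == "analytic") alpha
      else empirical_thresholds(sub, subscale = s, nrep = nrep,
                                alpha = alpha, seed = seed,
                                theta_source = theta_source)
      if (inherits(thr, "threshold_table")) thr_out[[key]][[s]] <- thr
      run <- run_hybrid_dif(sub, s, thresholds = thr, ...)
      runs[[key]][[s]] <- run
      tab <- run$table
      summ[[length(summ) + 1L]] <- data.frame(
        pair = key, subscale = s, n_items = nrow(tab),
        n_flagged = sum(tab$flag != "none"),
        n_uniform = sum(tab$flag == "uniform"),
        n_nonuniform = sum(tab$flag == "nonuniform"),
        status = run$status, stringsAsFactors = FALSE)
    }
  }
  structure(list(runs = runs, summary = do.call(rbind, summ),
                 thresholds = thr_out),
            class = "dyad_dif_results")
}

#' @export
print.dyad_dif_results <- function(x, ...) {
  cat("<dyad_dif_results>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
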