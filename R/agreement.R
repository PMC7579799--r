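#' Pooled-SD (Cohen) effect size
#'
#' Absolute mean difference standardised by the pooled standard
#' deviation of the two paired score sets,
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` (group sizes are equal
#' by pairing, so the pooled SD is the root mean of the two variances).
#'
#' @param mean1,sd1 Mean and SD of the first informant's scores.
#' @param mean2,sd2 Mean and SD of the second informant's scores.
#' @return Non-negative scalar; symmetric in the two informants.
#' @examples
#' cohen_effect_size(76.67, 13.90, 78.58, 13.52)  # 0.14
#' @export
cohen_effect_size <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) return(NA_real_)
  abs(mean1 - mean2) / pooled
}

#' Cohen label for an effect-size magnitude
#'
#' Half-open intervals closed at the conventional cutoffs:
#' `[0, 0.2)` negligible, `[0.2, 0.5)` small, `[0.5, 0.8)` medium,
#' `>= 0.8` large.
#'
#' @param es Non-negative effect size(s).
#' @return Character vector of labels.
#' @export
es_label <- function(es) {
  cut(abs(es), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |>
    as.character()
}

#' Agreement label for an intraclass correlation
#'
#' Printed cutoffs poor (< 0.40), moderate (0.41-0.60), good
#' (0.61-0.80), excellent (> 0.81) leave gaps; the label function closes
#' each gap at the lower edge so it is total: `< 0.40` poor,
#' `[0.40, 0.60]` moderate, `(0.60, 0.80]` good, `> 0.80` excellent.
#'
#' @param icc ICC value(s).
#' @return Character vector of labels.
#' @export
icc_label <- function(icc) {
  out <- character(length(icc))
  out[icc < 0.40] <- "poor"
  out[icc >= 0.40 & icc <= 0.60] <- "moderate"
  out[icc > 0.60 & icc <= 0.80] <- "good"
  out[icc > 0.80] <- "excellent"
  out[is.na(icc)] <- NA_character_
  out
}

#' Paired t-test with a degenerate-difference convention
#'
#' Classical two-sided paired t-test on `x - y`.  When every difference
#' is identical (zero SD) the t statistic is undefined; by convention the
#' test then reports `p = 1` when the common difference is 0 and `p = 0`
#' otherwise (a constant non-zero difference is a sure discrepancy).
#'
#' @param x,y Paired score vectors; pairs with a missing member are
#'   dropped.
#' @return List with `t`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0)
    return(list(t = NA_real_, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), n = n))
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), n = n)
}

#' Agreement intraclass correlation for paired raters
#'
#' Two-way model, single measurement, absolute agreement (the
#' ICC(A,1) of McGraw and Wong), computed from the mean squares of the
#' subjects-by-raters ANOVA:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))` with `k = 2`
#' raters.  The consistency form `(MSR - MSE) / (MSR + (k-1) MSE)`,
#' which ignores a systematic rater offset, is available as a variant.
#'
#' @param x,y Paired scores of the two raters; incomplete pairs dropped.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC in `[-1, 1]`; `NA` when the total variance is zero.
#' @export
icc_agreement <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  if (all(dat == grand)) return(NA_real_)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Partition uniform-DIF items into cancelled pairs and uncancelled items
#'
#' At the scale level, two uniform-DIF items whose group effects point in
#' opposite directions offset each other, so neither needs removing from
#' the scale score; an uncancelled uniform item transfers its bias to the
#' scale and is removed from the DIF-corrected score.  Items are paired
#' greedily by opposite `beta2` sign, largest absolute effect first.
#' Non-uniform items are never removed by this rule.
#'
#' @param dif_table Per-item DIF results (the `table` element of a
#'   [run_hybrid_dif()] result): needs `item_id`, `flag`, `beta2`.
#' @return List with `cancelled_pairs` (list of item-id pairs),
#'   `uncancelled` (item ids to remove) and `removed` (identical to
#'   `uncancelled`; the items excluded from the corrected score).
#' @export
cancellation_partition <- function(dif_table) {
  u <- dif_table[dif_table$flag == "uniform", c("item_id", "beta2")]
  u <- u[order(-abs(u$beta2)), , drop = FALSE]
  pos <- u$item_id[u$beta2 > 0]
  neg <- u$item_id[u$beta2 < 0]
  npair <- min(length(pos), length(neg))
  pairs <- if (npair)
    lapply(seq_len(npair), function(i) c(pos[i], neg[i])) else list()
  rest <- function(v) if (npair > 0L) v[-seq_len(npair)] else v
  uncancelled <- c(rest(pos), rest(neg), u$item_id[u$beta2 == 0])
  list(cancelled_pairs = pairs, uncancelled = uncancelled,
       removed = uncancelled)
}

# one raw-or-corrected agreement block for a pair of informants
agreement_row <- function(s1, s2, subscale, pair, corrected,
                          icc_type = "agreement", note = NA_character_) {
  keep <- is.finite(s1) & is.finite(s2)
  if (sum(keep) < 3L || all(is.na(s1)) || all(is.na(s2)))
    return(data.frame(
      subscale = subscale, pair = pair, corrected = corrected,
      n = sum(keep), mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_,
      sd2 = NA_real_, effect_size = NA_real_, es_label = NA_character_,
      icc = NA_real_, icc_label = NA_character_, t = NA_real_,
      t_p = NA_real_, mean_diff = NA_real_,
      note = if (is.na(note)) "no corrected score exists" else note,
      stringsAsFactors = FALSE))
  s1 <- s1[keep]; s2 <- s2[keep]
  es <- cohen_effect_size(mean(s1), sd(s1), mean(s2), sd(s2))
  icc <- icc_agreement(s1, s2, icc_type)
  tt <- paired_t(s1, s2)
  data.frame(
    subscale = subscale, pair = pair, corrected = corrected,
    n = length(s1), mean1 = mean(s1), sd1 = sd(s1), mean2 = mean(s2),
    sd2 = sd(s2), effect_size = es, es_label = es_label(es),
    icc = icc, icc_label = icc_label(icc), t = tt$t, t_p = tt$p,
    mean_diff = tt$mean_diff, note = note, stringsAsFactors = FALSE)
}

# align the two informants' score tables by dyad
paired_scores <- function(scores, pair) {
  a <- scores[scores$group == pair[1], , drop = FALSE]
  b <- scores[scores$group == pair[2], , drop = FALSE]
  common <- intersect(a$dyad_id, b$dyad_id)
  list(a = a[match(common, a$dyad_id), , drop = FALSE],
       b = b[match(common, b$dyad_id), , drop = FALSE])
}

#' Raw cross-informant agreement table
#'
#' Per subscale and for the total score: each informant's mean and SD,
#' the pooled-SD effect size with its Cohen label, the agreement ICC
#' with its cut-point label, and the paired t-test.
#'
#' @param m A [response_matrix()].
#' @param pair Length-2 character vector of group labels (informant 1,
#'   informant 2).
#' @param icc_type Passed to [icc_agreement()].
#' @return Data frame with one row per subscale plus `"total"`.
#' @export
agreement_table <- function(m, pair, icc_type = "agreement") {
  stopifnot(inherits(m, "response_matrix"), length(pair) == 2L)
  spec <- attr(m, "instrument")
  sc <- scale_scores(m)
  ps <- paired_scores(sc, pair)
  key <- paste(pair, collapse = "_vs_")
  rows <- lapply(c(spec$subscales, "total"), function(s)
    agreement_row(ps$a[[s]], ps$b[[s]], s, key, FALSE, icc_type))
  do.call(rbind, rows)
}

#' Raw and DIF-corrected agreement tables
#'
#' Recomputes the agreement statistics on subscale scores restricted to
#' the items retained after removing uncancelled uniform-DIF items (or
#' all uniform-DIF items with `remove = "all_uniform"`).  When every
#' item of a subscale is removed no corrected score exists and the row
#' says so.  The corrected total is the mean over all retained items.
#'
#' @param m A [response_matrix()].
#' @param flags Named list of per-subscale DIF results for this pair:
#'   each element a [run_hybrid_dif()] result (or its `table`).
#' @param pair Length-2 character vector of group labels.
#' @param remove `"uncancelled"` (default) or `"all_uniform"`.
#' @param icc_type Passed to [icc_agreement()].
#' @return Data frame of raw rows (`corrected = FALSE`) followed by
#'   corrected rows (`corrected = TRUE`), with a `note` column
#'   (removed items, or why no corrected score exists).
#' @export
corrected_agreement_table <- function(m, flags, pair,
                                      remove = c("uncancelled",
                                                 "all_uniform"),
                                      icc_type = "agreement") {
  stopifnot(inherits(m, "response_matrix"), length(pair) == 2L)
  remove <- match.arg(remove)
  spec <- attr(m, "instrument")
  raw <- agreement_table(m, pair, icc_type)
  key <- paste(pair, collapse = "_vs_")

  kept <- list()
  notes <- list()
  for (s in spec$subscales) {
    items <- subscale_items(spec, s)
    fl <- flags[[s]]
    tab <- if (inherits(fl, "hybrid_dif")) fl$table else fl
    if (is.null(tab)) {
      kept[[s]] <- items
      notes[[s]] <- NA_character_
      next
    }
    drop_ids <- if (remove == "uncancelled")
      cancellation_partition(tab)$removed
    else tab$item_id[tab$flag == "uniform"]
    kept[[s]] <- setdiff(items, drop_ids)
    notes[[s]] <- if (length(drop_ids))
      paste("removed:", paste(drop_ids, collapse = ", "))
    else "no items removed"
  }

  sub <- subset_responses(m, m$group %in% pair)
  meta <- data.frame(respondent_id = sub$respondent_id,
                     dyad_id = sub$dyad_id, group = sub$group,
                     stringsAsFactors = FALSE)
  corr_scores <- meta
  for (s in spec$subscales)
    corr_scores[[s]] <- if (length(kept[[s]]))
      subscale_score(sub, s, item_subset = kept[[s]])
    else rep(NA_real_, nrow(sub))
  all_kept <- unlist(kept, use.names = FALSE)
  corr_scores$total <- if (length(all_kept)) {
    x <- as.matrix(as.data.frame(sub)[, all_kept, drop = FALSE])
    tx <- transform_item(x, spec$n_categories)
    dim(tx) <- dim(x)
    rowMeans(tx, na.rm = TRUE)
  } else rep(NA_real_, nrow(sub))

  ps <- paired_scores(corr_scores, pair)
  corr <- do.call(rbind, lapply(c(spec$subscales, "total"), function(s) {
    note <- if (s == "total") {
      rem <- setdiff(spec$items$item_id, all_kept)
      if (length(rem)) paste("removed:", paste(rem, collapse = ", "))
      else "no items removed"
    } else notes[[s]]
    if (s != "total" && length(kept[[s]]) == 0L)
      note <- "all items showed uniform DIF; no corrected score exists"
    agreement_row(ps$a[[s]], ps$b[[s]], s, key, TRUE, icc_type, note)
  }))
  rbind(raw, corr)
}
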