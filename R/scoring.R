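#' Reverse-transform a raw Likert response onto the 0-100 PedsQL metric
#'
#' Raw responses run 0 (never a problem) to 4 (almost always a problem);
#' the reporting metric reverses and rescales them so that higher scores
#' indicate better health-related quality of life:
#' 0 -> 100, 1 -> 75, 2 -> 50, 3 -> 25, 4 -> 0.
#'
#' @param raw Integer vector with values in `0..4` (or
#'   `0..n_categories-1`); `NA` passes through.
#' @param n_categories Number of response categories (default 5).
#' @return Numeric vector on the 0-100 scale.
#' @examples
#' transform_item(c(0, 2, 4))  # 100 50 0
#' @export
transform_item <- function(raw, n_categories = 5L) {
  top <- n_categories - 1L
  bad <- !is.na(raw) & (raw < 0 | raw > top | raw != floor(raw))
  if (any(bad))
    stop("raw response out of range 0..", top, ": ", raw[which(bad)[1]],
         call. = FALSE)
  (top - raw) * (100 / top)
}

#' Subscale score on the 0-100 metric
#'
#' Mean of the transformed available items of one subscale, optionally
#' restricted to a subset of its items (used for DIF-corrected scores).
#' The score is undefined (`NA`) when the item subset is empty or fewer
#' than `min_answered_frac` of its items were answered.
#'
#' @param m A [response_matrix()].
#' @param subscale Subscale id.
#' @param item_subset Optional character vector of item ids (must lie
#'   inside the subscale); `NULL` uses all subscale items.
#' @param min_answered_frac Minimum fraction of the (possibly restricted)
#'   item set that must be answered for a defined score (default 0.5).
#' @return Numeric vector, one score per respondent (`NA` if undefined).
#' @export
subscale_score <- function(m, subscale, item_subset = NULL,
                           min_answered_frac = 0.5) {
  spec <- attr(m, "instrument")
  items <- subscale_items(spec, subscale)
  if (!is.null(item_subset)) {
    extra <- setdiff(item_subset, items)
    if (length(extra))
      stop("items not in subscale ", subscale, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    items <- item_subset
  }
  if (length(items) == 0L) return(rep(NA_real_, nrow(m)))
  x <- as.matrix(as.data.frame(m)[, items, drop = FALSE])
  tx <- transform_item(x, spec$n_categories)
  dim(tx) <- dim(x)
  score <- rowMeans(tx, na.rm = TRUE)
  answered <- rowMeans(!is.na(x))
  score[answered < min_answered_frac | answered == 0] <- NA_real_
  score
}

#' Total score on the 0-100 metric
#'
#' Mean of all transformed answered items across the whole instrument
#' (not the mean of subscale means, so longer subscales weigh
#' proportionally, as in standard PedsQL scoring).
#'
#' @inheritParams subscale_score
#' @return Numeric vector, one total score per respondent.
#' @export
total_score <- function(m, min_answered_frac = 0.5) {
  spec <- attr(m, "instrument")
  items <- spec$items$item_id
  x <- as.matrix(as.data.frame(m)[, items, drop = FALSE])
  tx <- transform_item(x, spec$n_categories)
  dim(tx) <- dim(x)
  score <- rowMeans(tx, na.rm = TRUE)
  answered <- rowMeans(!is.na(x))
  score[answered < min_answered_frac | answered == 0] <- NA_real_
  score
}

#' All subscale scores plus the total
#'
#' @inheritParams subscale_score
#' @return Data frame: `respondent_id`, `dyad_id`, `group`, one column per
#'   subscale, and `total`.
#' @export
scale_scores <- function(m, min_answered_frac = 0.5) {
  spec <- attr(m, "instrument")
  out <- data.frame(respondent_id = m$respondent_id,
                    dyad_id = m$dyad_id, group = m$group,
                    stringsAsFactors = FALSE)
  for (s in spec$subscales)
    out[[s]] <- subscale_score(m, s, min_answered_frac = min_answered_frac)
  out$total <- total_score(m, min_answered_frac)
  out
}
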