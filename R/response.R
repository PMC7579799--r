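#' Construct a response matrix
#'
#' A response matrix is a data frame with one row per respondent and
#' columns `respondent_id`, `dyad_id`, `group` followed by one integer
#' column per item of the instrument.  Responses are coded
#' `0 .. n_categories - 1`; `NA` marks a missing response.
#'
#' @param df Data frame with the columns above.
#' @param spec The [instrument_spec()] the item columns belong to.
#' @return A `response_matrix` (data frame subclass) carrying `spec` as the
#'   `"instrument"` attribute.
#' @export
response_matrix <- function(df, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("respondent_id", "dyad_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  items <- spec$items$item_id
  miss <- setdiff(items, names(df))
  if (length(miss))
    stop("missing item column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (id in need) df[[id]] <- as.character(df[[id]])
  K <- spec$n_categories
  for (it in items) {
    v <- df[[it]]
    if (is.logical(v) && all(is.na(v))) v <- as.integer(v)  # all-empty column
    if (!is.numeric(v) && !is.integer(v))
      stop("item column ", it, " is not numeric", call. = FALSE)
    vi <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(vi) | vi != v))
    if (length(bad))
      stop("non-integer response in column ", it, ", row ", bad[1],
           call. = FALSE)
    out <- which(!is.na(vi) & (vi < 0L | vi >= K))
    if (length(out))
      stop("out-of-range response ", vi[out[1]], " in column ", it,
           ", row ", out[1], " (allowed 0..", K - 1L, ")", call. = FALSE)
    df[[it]] <- vi
  }
  if (anyDuplicated(df$respondent_id))
    stop("duplicated respondent_id", call. = FALSE)
  dup <- duplicated(df[, c("dyad_id", "group")])
  if (any(dup))
    stop("dyad ", df$dyad_id[which(dup)[1]],
         " has more than one respondent in group ",
         df$group[which(dup)[1]], call. = FALSE)
  df <- df[, c(need, items)]
  structure(df, instrument = spec,
            class = c("response_matrix", "data.frame"))
}

#' @export
print.response_matrix <- function(x, ...) {
  spec <- attr(x, "instrument")
  cat("<response_matrix> ", nrow(x), " respondents x ",
      nrow(spec$items), " items (", spec$name, ")\n", sep = "")
  print(table(group = x$group))
  nmiss <- sum(is.na(as.matrix(x[, spec$items$item_id])))
  cat("missing cells:", nmiss, "\n")
  invisible(x)
}

#' Read wide-format item responses from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing
#' `respondent_id`, `dyad_id`, `group` and one column per item id of
#' `spec`.  Empty cells and `"NA"` are treated as missing.  Out-of-range
#' or non-integer values raise an error naming the offending cell rather
#' than being silently clamped.
#'
#' @param path CSV file path.
#' @param spec An [instrument_spec()].
#' @return A [response_matrix()].
#' @seealso [write_responses()], [apply_eligibility_filter()]
#' @export
read_responses <- function(path, spec) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  items <- spec$items$item_id
  miss <- setdiff(items, names(df))
  if (length(miss))
    stop("input file ", path, " lacks item column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (it in items) {
    v <- df[[it]]
    if (is.character(v)) {
      vi <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vi))
      if (length(bad))
        stop("cannot parse value '", v[bad[1]], "' in column ", it,
             ", row ", bad[1], call. = FALSE)
      df[[it]] <- vi
    }
  }
  response_matrix(df, spec)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: missing responses are written as empty
#' cells, all other cells round-trip exactly.
#'
#' @param m A [response_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(m, path) {
  stopifnot(inherits(m, "response_matrix"))
  write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Eligibility filter on missing item responses
#'
#' Respondents with more than `max_missing_frac` of items missing are
#' excluded (default 5%, i.e. at most 1 of 23 items may be missing).
#' Because the DIF analysis pairs both members of a dyad, the partner(s)
#' of an excluded respondent are dropped as well, keeping every analysed
#' pair complete.  Applying the filter twice equals applying it once.
#'
#' @param m A [response_matrix()].
#' @param max_missing_frac Maximum tolerated fraction of missing items.
#' @param drop_partners Drop all dyad members of an excluded respondent
#'   (default `TRUE`).
#' @return List with elements `data` (filtered `response_matrix`),
#'   `excluded_ids` (respondents over the threshold) and
#'   `excluded_partner_ids` (respondents dropped only because a dyad
#'   partner was excluded).
#' @export
apply_eligibility_filter <- function(m, max_missing_frac = 0.05,
                                     drop_partners = TRUE) {
  stopifnot(inherits(m, "response_matrix"))
  spec <- attr(m, "instrument")
  items <- spec$items$item_id
  frac <- rowMeans(is.na(as.matrix(m[, items, drop = FALSE])))
  over <- frac > max_missing_frac
  partner <- rep(FALSE, nrow(m))
  if (drop_partners && any(over))
    partner <- !over & m$dyad_id %in% m$dyad_id[over]
  out <- m[!(over | partner), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(
    data = structure(out, instrument = spec,
                     class = c("response_matrix", "data.frame")),
    excluded_ids = m$respondent_id[over],
    excluded_partner_ids = m$respondent_id[partner]),
    class = "eligibility_result")
}

# item response columns as an integer matrix (rows = respondents)
resp_matrix_of <- function(m, items) {
  x <- as.matrix(as.data.frame(m)[, items, drop = FALSE])
  storage.mode(x) <- "integer"
  rownames(x) <- m$respondent_id
  x
}
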