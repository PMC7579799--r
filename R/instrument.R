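#' Define a Likert instrument
#'
#' An instrument specification records the item/subscale layout and the
#' number of ordered response categories of a polytomous questionnaire.
#' All analysis functions take their item layout from such an object.
#'
#' @param name Instrument name.
#' @param items Data frame with columns `item_id`, `subscale_id` and
#'   optionally `prompt` (defaults to the item id).
#' @param n_categories Number of ordered response categories (>= 2).
#'   Raw responses are coded `0 .. n_categories - 1`.
#' @return An object of class `instrument_spec` with elements `name`,
#'   `items` (data frame), `subscales` (character vector in first-appearance
#'   order) and `n_categories`.
#' @examples
#' spec <- instrument_spec(
#'   "toy",
#'   data.frame(item_id = c("a1", "a2", "b1"),
#'              subscale_id = c("A", "A", "B")))
#' spec$subscales
#' @export
instrument_spec <- function(name, items, n_categories = 5L) {
  stopifnot(is.character(name), length(name) == 1L)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (!all(c("item_id", "subscale_id") %in% names(items)))
    stop("`items` needs columns item_id and subscale_id", call. = FALSE)
  if (is.null(items$prompt)) items$prompt <- items$item_id
  items$item_id <- as.character(items$item_id)
  items$subscale_id <- as.character(items$subscale_id)
  if (anyDuplicated(items$item_id))
    stop("duplicated item_id in instrument", call. = FALSE)
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L)
    stop("n_categories must be >= 2", call. = FALSE)
  structure(
    list(name = name,
         items = items[, c("item_id", "subscale_id", "prompt")],
         subscales = unique(items$subscale_id),
         n_categories = n_categories),
    class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("<instrument_spec> ", x$name, ": ", nrow(x$items), " items, ",
      length(x$subscales), " subscales, ", x$n_categories,
      " categories\n", sep = "")
  tab <- table(factor(x$items$subscale_id, levels = x$subscales))
  for (s in x$subscales) cat("  ", s, ": ", tab[[s]], " items\n", sep = "")
  invisible(x)
}

#' Item ids of one subscale
#'
#' @param spec An [instrument_spec()].
#' @param subscale Subscale id; `NULL` returns all items.
#' @return Character vector of item ids.
#' @export
subscale_items <- function(spec, subscale = NULL) {
  stopifnot(inherits(spec, "instrument_spec"))
  if (is.null(subscale)) return(spec$items$item_id)
  if (!subscale %in% spec$subscales)
    stop("unknown subscale: ", subscale, call. = FALSE)
  spec$items$item_id[spec$items$subscale_id == subscale]
}

#' The PedsQL 4.0 Generic Core Scales layout (teen self/proxy form)
#'
#' 23 five-category items in four subscales: physical (8), emotional (5),
#' social (5) and school functioning (5).  Raw responses are 0 = never a
#' problem up to 4 = almost always a problem, so higher raw scores mean
#' worse health-related quality of life; [transform_item()] reverses this
#' onto the 0-100 reporting metric.
#'
#' @return An `instrument_spec` with 23 items.
#' @examples
#' pedsql_spec()
#' @export
pedsql_spec <- function() {
  prompts <- list(
    physical = c("Hard to walk more than one block",
                 "Hard to run",
                 "Hard to do sports or exercise",
                 "Hard to lift something heavy",
                 "Hard to take a bath or shower",
                 "Hard to do chores around the house",
                 "Having hurts or aches",
                 "Low energy"),
    emotional = c("Feel afraid or scared",
                  "Feel sad or blue",
                  "Feel angry",
                  "Trouble sleeping",
                  "Worry about what will happen"),
    social = c("Trouble getting along with peers",
               "Other kids do not want to be friends",
               "Teased",
               "Doing things other peers do",
               "Hard to keep up when play with others"),
    school = c("Hard to concentrate",
               "Forget things",
               "Trouble keeping up with schoolwork",
               "Miss school - not well",
               "Miss school - doctor appointment"))
  items <- do.call(rbind, lapply(names(prompts), function(s) {
    data.frame(item_id = sprintf("%s%d", substr(s, 1, 3),
                                 seq_along(prompts[[s]])),
               subscale_id = s, prompt = prompts[[s]],
               stringsAsFactors = FALSE)
  }))
  instrument_spec("PedsQL 4.0 Generic Core Scales", items, 5L)
}
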