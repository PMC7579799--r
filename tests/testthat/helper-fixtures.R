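# small fixtures shared across test files

toy_instrument <- function(n_items = 4L, n_categories = 5L,
                           subscale = "s1") {
  instrument_spec(
    "toy",
    data.frame(item_id = paste0("q", seq_len(n_items)),
               subscale_id = subscale),
    n_categories)
}

# two-subscale instrument for scoring / pipeline tests
two_scale_instrument <- function() {
  instrument_spec(
    "two-scale",
    data.frame(item_id = paste0("q", 1:8),
               subscale_id = rep(c("A", "B"), each = 4)))
}

# deterministic tiny response matrix (values recycled by row)
toy_responses <- function(values, spec = toy_instrument(),
                          groups = NULL) {
  n <- nrow(values)
  df <- data.frame(respondent_id = paste0("r", seq_len(n)),
                   dyad_id = paste0("d", seq_len(n)),
                   group = if (is.null(groups)) "g1" else groups,
                   stringsAsFactors = FALSE)
  df[spec$items$item_id] <- as.data.frame(values)
  response_matrix(df, spec)
}

# paired two-group matrix from explicit item matrices (one row per dyad)
dyad_responses <- function(y1, y2, spec,
                           groups = c("parent", "child")) {
  n <- nrow(y1)
  dy <- sprintf("d%03d", seq_len(n))
  df1 <- data.frame(respondent_id = paste0(dy, "_1"), dyad_id = dy,
                    group = groups[1], stringsAsFactors = FALSE)
  df2 <- data.frame(respondent_id = paste0(dy, "_2"), dyad_id = dy,
                    group = groups[2], stringsAsFactors = FALSE)
  df1[spec$items$item_id] <- as.data.frame(y1)
  df2[spec$items$item_id] <- as.data.frame(y2)
  response_matrix(rbind(df1, df2), spec)
}
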