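# Five healthy-ageing indices: polarity recode -> min-max scale per item ->
# sum within dimension -> zero-mean centering over the full analysis sample.

#' Min-max scale a value to [0, 1]
#'
#' `(x - min_v) / (max_v - min_v)`, the scaling applied to every recoded item
#' before summation.
#'
#' @param x Numeric vector with `min_v <= x <= max_v`.
#' @param min_v,max_v Scaling bounds, `max_v > min_v`.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_scale(3, 1, 5)  # 0.5
minmax_scale <- function(x, min_v, max_v) {
  if (max_v == min_v) {
    abort("degenerate variable: max equals min; drop it or treat as constant 0",
          class = "agetree_degenerate_error")
  }
  if (max_v < min_v) abort("max_v must exceed min_v")
  if (any(x < min_v | x > max_v, na.rm = TRUE)) {
    abort("values outside the scaling bounds")
  }
  (x - min_v) / (max_v - min_v)
}

#' Index definitions for the five dimensions
#'
#' One row per indicator item: its dimension, whether the raw coding is
#' reversed (so that after recoding higher always means healthier) and the
#' min-max scaling bounds. With `bounds = "theoretical"` (the default) the
#' bounds are the full code range `0 .. n_codes - 1` from the codebook, so
#' indices do not depend on which sample they are computed in;
#' `bounds = "empirical"` instead uses the observed min/max of each recoded
#' item in `data` (which must then be supplied).
#'
#' @param codebook A codebook tibble.
#' @param bounds `"theoretical"` or `"empirical"`.
#' @param data Survey tibble, required for empirical bounds.
#' @return A tibble with columns `dimension`, `item`, `reverse`, `min_v`,
#'   `max_v`.
#' @export
index_definitions <- function(codebook = default_codebook(),
                              bounds = c("theoretical", "empirical"),
                              data = NULL) {
  bounds <- match.arg(bounds)
  items <- codebook[codebook$role == "indicator", ]
  defs <- tibble::tibble(
    dimension = items$dimension,
    item = items$name,
    reverse = items$polarity == "higher_is_worse",
    n_codes = items$n_codes,
    min_v = 0,
    max_v = as.numeric(items$n_codes - 1L)
  )
  if (bounds == "empirical") {
    if (is.null(data)) abort("empirical bounds need the data")
    for (i in seq_len(nrow(defs))) {
      x <- recode_item(data[[defs$item[i]]], defs$reverse[i], defs$n_codes[i])
      defs$min_v[i] <- min(x, na.rm = TRUE)
      defs$max_v[i] <- max(x, na.rm = TRUE)
    }
  }
  defs
}

# recode so higher = healthier: reversed items map code c -> (K-1) - c
recode_item <- function(code, reverse, n_codes) {
  if (reverse) (n_codes - 1L) - code else code
}

#' Raw composite index for one dimension
#'
#' For each respondent, the sum over the dimension's items of the min-max
#' scaled, polarity-recoded item value. The table must already be filtered:
#' missing cells among the dimension's items are an error.
#'
#' @param table Filtered survey tibble.
#' @param defn Rows of [index_definitions()] for a single dimension.
#' @return Numeric vector of raw index values, one per respondent, in
#'   `[0, number of items]` under theoretical bounds.
#' @export
build_index <- function(table, defn) {
  stopifnot(nrow(defn) >= 1, length(unique(defn$dimension)) == 1)
  missing_items <- setdiff(defn$item, names(table))
  if (length(missing_items)) {
    abort(paste0("items absent from the table: ",
                 paste(missing_items, collapse = ", ")),
          class = "agetree_codebook_error")
  }
  total <- numeric(nrow(table))
  for (i in seq_len(nrow(defn))) {
    x <- recode_item(table[[defn$item[i]]], defn$reverse[i], defn$n_codes[i])
    if (anyNA(x)) abort(paste0("missing values in item ", defn$item[i],
                               "; filter the table first"))
    if (defn$max_v[i] == defn$min_v[i]) {
      warn(paste0("item ", defn$item[i],
                  " is constant under empirical bounds; contributes 0"))
      next
    }
    total <- total + minmax_scale(as.numeric(x), defn$min_v[i], defn$max_v[i])
  }
  total
}

#' Center a vector to zero mean
#'
#' @param raw Numeric vector with at least one element.
#' @return `raw - mean(raw)`; the result has mean 0 to within 1e-10.
#' @export
#' @examples
#' normalize_zero_mean(c(1, 2, 3))  # -1 0 1
normalize_zero_mean <- function(raw) {
  if (length(raw) == 0) abort("cannot center an empty vector")
  raw - mean(raw)
}

#' All five healthy-ageing indices
#'
#' Composes [build_index()] and [normalize_zero_mean()] for each dimension in
#' canonical order. Centering is over the full filtered analysis sample,
#' before any age-group stratification, so stratum means remain comparable
#' signed quantities.
#'
#' @param table Filtered survey tibble (no missing analysis cells).
#' @param codebook Codebook tibble; defaults to the one attached to `table`.
#' @param bounds Passed to [index_definitions()].
#' @return A tibble with `id` plus the five index columns in canonical order
#'   (physical, functional, mental, cognition, social), each centered to
#'   mean zero.
#' @export
#' @examples
#' coh <- apply_filters(generate_survey(synth_config(n = 200, seed = 3)))
#' idx <- build_all_indices(coh$data)
#' colMeans(idx[index_dimensions()])
build_all_indices <- function(table, codebook = NULL,
                              bounds = c("theoretical", "empirical")) {
  bounds <- match.arg(bounds)
  codebook <- codebook %||% attr(table, "codebook") %||% default_codebook()
  defs <- index_definitions(codebook, bounds = bounds, data = table)
  out <- tibble::tibble(id = table$id)
  for (dim_i in index_dimensions()) {
    d <- defs[defs$dimension == dim_i, ]
    out[[dim_i]] <- normalize_zero_mean(build_index(table, d))
  }
  out
}
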