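# Descriptive summaries and tree rendering.

#' Mean index scores by age group
#'
#' Arithmetic means of the (globally centred) index scores within each age
#' stratum. Because centering is over the full analysis sample, stratum
#' means are signed: a younger stratum typically sits above zero and older
#' strata below.
#'
#' @param scores Tibble holding the five index columns plus an age column
#'   (join the index table to the filtered survey first if needed).
#' @param age_col Name of the age column.
#' @param strata Named list of `(lower, upper)` age bounds; the default drops
#'   the `"all"` stratum, keeping the three disjoint groups.
#' @return A tibble of class `age_group_summary`, long format: `stratum`,
#'   `dimension` (canonical order), `n`, `mean`.
#' @export
#' @examples
#' coh <- apply_filters(generate_survey(synth_config(n = 400, seed = 5)))
#' scores <- dplyr::left_join(build_all_indices(coh$data),
#'                            coh$data[c("id", "age")], by = "id")
#' age_group_means(scores)
age_group_means <- function(scores, age_col = "age",
                            strata = default_age_strata()[c("45-59", "60-74", "75+")]) {
  dims <- intersect(index_dimensions(), names(scores))
  if (length(dims) == 0) abort("scores has no index columns")
  if (!age_col %in% names(scores)) abort("scores has no age column")
  rows <- purrr::imap(strata, function(bounds, label) {
    sub <- scores[scores[[age_col]] >= bounds[1] & scores[[age_col]] < bounds[2], ]
    if (nrow(sub) == 0) {
      warn(paste0("empty age stratum omitted: ", label))
      return(NULL)
    }
    tibble::tibble(stratum = label,
                   dimension = factor(dims, levels = index_dimensions()),
                   n = nrow(sub),
                   mean = purrr::map_dbl(dims, ~ mean(sub[[.x]])))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- c("age_group_summary", class(out))
  out
}

# grayscale fill by rank of squared_error within the tree: darkest = lowest
node_shades <- function(squared_error) {
  r <- rank(squared_error, ties.method = "min")
  if (max(r) == min(r)) {
    lev <- rep(0.55, length(r))
  } else {
    lev <- 0.35 + 0.6 * (r - min(r)) / (max(r) - min(r))
  }
  grDevices::gray(lev)
}

format_value <- function(v) {
  paste0("[", paste(sprintf("%.3f", v), collapse = ", "), "]")
}

#' Render a fitted tree as Graphviz DOT or indented text
#'
#' Each node displays its split rule (`feature <= threshold`), sample count,
#' summed squared error and the five-entry `value` vector in canonical order
#' at 3 decimals. In DOT output nodes are filled on a grayscale ramp over the
#' rank of `squared_error`, darkest for the lowest squared error.
#'
#' @param tree An `mrt`.
#' @param format `"dot"` or `"text"`.
#' @return A character vector of document lines.
#' @export
render_tree <- function(tree, format = c("dot", "text")) {
  format <- match.arg(format)
  nodes <- tree$nodes
  if (format == "dot") {
    fill <- node_shades(nodes$squared_error)
    font <- ifelse(colMeans(grDevices::col2rgb(fill)) < 128, "white", "black")
    lines <- c("digraph mrt {",
               "  node [shape=box, style=filled, fontname=\"Helvetica\"];")
    for (i in seq_len(nrow(nodes))) {
      rule <- if (nodes$is_leaf[i]) "leaf" else
        sprintf("%s <= %g", nodes$feature[i], nodes$threshold[i])
      label <- sprintf("%s\\nn = %d\\nsquared_error = %.3f\\nvalue = %s",
                       rule, nodes$n[i], nodes$squared_error[i],
                       format_value(nodes$value[[i]]))
      lines <- c(lines, sprintf(
        "  n%d [label=\"%s\", fillcolor=\"%s\", fontcolor=\"%s\"];",
        nodes$id[i], label, fill[i], font[i]))
    }
    for (i in which(!nodes$is_leaf)) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nodes$id[i], nodes$left[i]),
                 sprintf("  n%d -> n%d [label=\"no\"];", nodes$id[i], nodes$right[i]))
    }
    c(lines, "}")
  } else {
    render_text_node <- function(id, indent) {
      i <- which(nodes$id == id)
      rule <- if (nodes$is_leaf[i]) "leaf" else
        sprintf("%s <= %g", nodes$feature[i], nodes$threshold[i])
      line <- sprintf("%s%s | n = %d | squared_error = %.3f | value = %s",
                      strrep("  ", indent), rule, nodes$n[i],
                      nodes$squared_error[i], format_value(nodes$value[[i]]))
      if (nodes$is_leaf[i]) return(line)
      c(line,
        render_text_node(nodes$left[i], indent + 1),
        render_text_node(nodes$right[i], indent + 1))
    }
    render_text_node(1L, 0)
  }
}

#' Serialize a fitted tree to JSON and back
#'
#' The JSON carries, per node: `id`, `depth`, `n`, `value` (canonical
#' order), `squared_error`, `feature`, `threshold` and `children`
#' `[left, right]`, plus the target and feature names. The round trip is
#' lossless: a deserialized tree renders and predicts identically.
#'
#' @param tree An `mrt`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `tree_to_json()`: the path (invisibly) or a JSON string;
#'   `tree_from_json()`: an `mrt`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- purrr::pmap(tree$nodes, function(id, depth, n, squared_error,
                                            feature, threshold, left, right,
                                            is_leaf, value) {
    nd <- list(id = id, depth = depth, n = n,
               value = as.numeric(value), squared_error = squared_error)
    if (!is_leaf) {
      nd$feature <- feature
      nd$threshold <- threshold
      nd$children <- c(left, right)
    }
    nd
  })
  obj <- list(targets = tree$targets, features = tree$features,
              control = tree$control, nodes = nodes)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname tree_to_json
#' @param json A path to a JSON file or a JSON string.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- purrr::map_dfr(obj$nodes, function(nd) {
    leaf <- is.null(nd$children)
    tibble::tibble(
      id = as.integer(nd$id), depth = as.integer(nd$depth),
      n = as.integer(nd$n), squared_error = nd$squared_error,
      feature = if (leaf) NA_character_ else nd$feature,
      threshold = if (leaf) NA_real_ else nd$threshold,
      left = if (leaf) NA_integer_ else as.integer(nd$children[[1]]),
      right = if (leaf) NA_integer_ else as.integer(nd$children[[2]]),
      is_leaf = leaf,
      value = list(setNames(as.numeric(unlist(nd$value)),
                            unlist(obj$targets)))
    )
  })
  structure(list(nodes = nodes,
                 targets = unlist(obj$targets),
                 features = unlist(obj$features),
                 control = obj$control),
            class = "mrt")
}
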