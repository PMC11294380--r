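# Multivariate regression tree: greedy binary recursive partitioning of
# respondents on ordinal integer predictors, minimising mean squared error
# summed over the five index targets. Written from scratch; no tree library
# stands behind it.

as_target_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("targets must not contain missing values")
  m
}

#' Node impurity: mean squared error summed over targets
#'
#' For an n-by-J block of target values,
#' `MSE = (1/N) * sum_i sum_j (y_ij - ybar_j)^2`, with the per-target means
#' `ybar_j` computed within the block. Means and deviations use a two-pass
#' accumulation for reproducible split choices.
#'
#' @param targets Numeric matrix or data frame, one row per observation, one
#'   column per target.
#' @return A single non-negative number.
#' @export
#' @examples
#' node_mse(rbind(c(0, 0, 0, 0, 0), c(2, 0, 0, 0, 0)))  # 1
node_mse <- function(targets) {
  m <- as_target_matrix(targets)
  if (nrow(m) == 0) abort("node_mse needs at least one observation")
  ctr <- colMeans(m)
  sum(sweep(m, 2, ctr)^2) / nrow(m)
}

# per-target MSE vector of a block (two-pass)
node_mse_by_target <- function(m) {
  ctr <- colMeans(m)
  colSums(sweep(m, 2, ctr)^2) / nrow(m)
}

#' Split objective: child impurities weighted by child fractions
#'
#' `sum_j (N_left/N_total * MSE_left,j + N_right/N_total * MSE_right,j)`,
#' summed over the targets. `criterion = "as_printed"` reproduces a variant
#' that weights both children by `N_left/N_total` (kept for auditability; its
#' weights do not sum to one, so the default corrected form is used
#' everywhere else).
#'
#' @param left,right Target blocks (matrix or data frame) for the two
#'   children; both must be non-empty.
#' @param criterion `"corrected"` (default) or `"as_printed"`.
#' @return A single non-negative number.
#' @export
weighted_split_mse <- function(left, right,
                               criterion = c("corrected", "as_printed")) {
  criterion <- match.arg(criterion)
  l <- as_target_matrix(left)
  r <- as_target_matrix(right)
  if (nrow(l) == 0 || nrow(r) == 0) abort("both children must be non-empty")
  n_total <- nrow(l) + nrow(r)
  w_l <- nrow(l) / n_total
  w_r <- if (criterion == "corrected") nrow(r) / n_total else w_l
  sum(w_l * node_mse_by_target(l) + w_r * node_mse_by_target(r))
}

#' Best split of a node by exhaustive midpoint search
#'
#' Evaluates every candidate feature and every midpoint between consecutive
#' distinct observed codes, rejecting splits that would leave a child below
#' `min_samples_leaf`, and returns the rule minimising
#' [weighted_split_mse()]. Returns `NULL` when no admissible split reduces
#' the parent [node_mse()] by more than `tol`. Ties within `tol` resolve to
#' the feature listed earliest in `features`, then the smallest threshold.
#' Rows with feature code `<= threshold` go left.
#'
#' @param data Tibble holding the feature columns (integer codes).
#' @param targets Numeric matrix or data frame of target values, row-aligned
#'   with `data`.
#' @param features Character vector of candidate feature names, in codebook
#'   order.
#' @param min_samples_leaf Minimum rows in each child.
#' @param tol Minimum impurity reduction for a split to be accepted.
#' @param criterion Passed to [weighted_split_mse()].
#' @return `list(feature, threshold, objective)` or `NULL`.
#' @export
#' @examples
#' d <- tibble::tibble(wealth_quintile = rep(0:4, each = 4))
#' y <- matrix(rep(ifelse(d$wealth_quintile <= 2, 0, 1), 5), ncol = 5)
#' best_split(d, y, "wealth_quintile")$threshold  # 2.5
best_split <- function(data, targets, features, min_samples_leaf = 1,
                       tol = 1e-12, criterion = c("corrected", "as_printed")) {
  criterion <- match.arg(criterion)
  m <- as_target_matrix(targets)
  if (nrow(m) != nrow(data)) abort("data and targets are misaligned")
  parent <- node_mse(m)
  best <- NULL
  best_obj <- Inf
  for (f in features) {
    v <- data[[f]]
    if (is.null(v)) abort(paste0("feature not in data: ", f))
    codes <- sort(unique(v))
    if (length(codes) < 2) next
    mids <- (head(codes, -1) + codes[-1]) / 2
    for (thr in mids) {
      go_left <- v <= thr
      n_l <- sum(go_left)
      if (n_l < min_samples_leaf || nrow(m) - n_l < min_samples_leaf) next
      obj <- weighted_split_mse(m[go_left, , drop = FALSE],
                                m[!go_left, , drop = FALSE],
                                criterion = criterion)
      if (obj < best_obj - tol) {
        best_obj <- obj
        best <- list(feature = f, threshold = thr, objective = obj)
      }
    }
  }
  if (is.null(best) || parent - best_obj <= tol) return(NULL)
  best
}

#' Fit a multivariate regression tree
#'
#' Greedy recursive binary partitioning, depth-first with the left child
#' grown first. Growth stops at `max_depth`, below `min_samples_split`, or
#' when [best_split()] finds no impurity-reducing split. Every node carries
#' its sample count, the per-target mean vector (`value`, canonical order)
#' and its summed-MSE impurity (`squared_error`).
#'
#' @param data Tibble containing both the feature columns and the target
#'   columns.
#' @param targets Names of the target columns; defaults to the five index
#'   dimensions in canonical order.
#' @param features Names of the predictor columns, in codebook order;
#'   defaults to the codebook predictors present in `data`.
#' @param max_depth Maximum tree depth (root is depth 0).
#' @param min_samples_split Smallest node that may be split.
#' @param min_samples_leaf Smallest admissible child.
#' @param tol Minimum impurity reduction for a split.
#' @param criterion Split objective variant, see [weighted_split_mse()].
#' @return An object of class `mrt`: list with `nodes` (tibble: `id`,
#'   `depth`, `n`, `squared_error`, `feature`, `threshold`, `left`, `right`,
#'   `is_leaf`, list-column `value`), `targets`, `features` and the resolved
#'   control settings.
#' @export
#' @examples
#' bench <- synth_tree_benchmark(n = 400, seed = 1)
#' fit <- fit_mrt(bench, max_depth = 2,
#'                features = c("education", "safe", "wealth_quintile", "hh_act"),
#'                min_samples_split = 2, min_samples_leaf = 1)
#' fit
fit_mrt <- function(data, targets = index_dimensions(), features = NULL,
                    max_depth = 3, min_samples_split = 20,
                    min_samples_leaf = 10, tol = 1e-12,
                    criterion = c("corrected", "as_printed")) {
  criterion <- match.arg(criterion)
  features <- features %||% intersect(predictor_names(), names(data))
  if (length(features) == 0) abort("no candidate features in data")
  missing_cols <- setdiff(c(features, targets), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns absent from data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("cannot fit a tree on an empty table")
  feats <- data[features]
  if (anyNA(feats)) abort("features contain missing values; filter first")
  y <- as_target_matrix(data[targets])

  nodes <- list()
  next_id <- 0L
  grow <- function(idx, depth) {
    next_id <<- next_id + 1L
    id <- next_id
    block <- y[idx, , drop = FALSE]
    value <- colMeans(block)
    se <- node_mse(block)
    node <- list(id = id, depth = depth, n = length(idx),
                 squared_error = se, feature = NA_character_,
                 threshold = NA_real_, left = NA_integer_,
                 right = NA_integer_, is_leaf = TRUE, value = value)
    nodes[[id]] <<- node  # placeholder; children filled in below
    if (depth < max_depth && length(idx) >= min_samples_split) {
      s <- best_split(feats[idx, , drop = FALSE], block, features,
                      min_samples_leaf = min_samples_leaf, tol = tol,
                      criterion = criterion)
      if (!is.null(s)) {
        go_left <- feats[[s$feature]][idx] <= s$threshold
        left_id <- grow(idx[go_left], depth + 1L)
        right_id <- grow(idx[!go_left], depth + 1L)
        node$feature <- s$feature
        node$threshold <- s$threshold
        node$left <- left_id
        node$right <- right_id
        node$is_leaf <- FALSE
        nodes[[id]] <<- node
      }
    }
    id
  }
  grow(seq_len(nrow(data)), 0L)

  node_tbl <- tibble::tibble(
    id = purrr::map_int(nodes, "id"),
    depth = purrr::map_int(nodes, "depth"),
    n = purrr::map_int(nodes, "n"),
    squared_error = purrr::map_dbl(nodes, "squared_error"),
    feature = purrr::map_chr(nodes, "feature"),
    threshold = purrr::map_dbl(nodes, "threshold"),
    left = purrr::map_int(nodes, "left"),
    right = purrr::map_int(nodes, "right"),
    is_leaf = purrr::map_lgl(nodes, "is_leaf"),
    value = purrr::map(nodes, "value")
  )
  structure(list(nodes = node_tbl, targets = targets, features = features,
                 control = list(max_depth = max_depth,
                                min_samples_split = min_samples_split,
                                min_samples_leaf = min_samples_leaf,
                                tol = tol, criterion = criterion)),
            class = "mrt")
}

#' @export
print.mrt <- function(x, ...) {
  cat("Multivariate regression tree:", sum(x$nodes$is_leaf), "leaves,",
      "depth", max(x$nodes$depth), "| n =", x$nodes$n[1], "\n")
  cat(render_tree(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Number of leaves / depth of a fitted tree
#' @param tree An `mrt` object.
#' @return An integer.
#' @export
n_leaves <- function(tree) sum(tree$nodes$is_leaf)

#' @rdname n_leaves
#' @export
tree_depth <- function(tree) max(tree$nodes$depth)

#' Predict leaf mean vectors for new rows
#'
#' Routes each row down the tree (code `<=` threshold goes left) and returns
#' the reached leaf's per-target mean vector. `max_depth` truncates routing
#' at that depth, yielding the predictions of the identically grown shallower
#' tree (greedy growth does not depend on the depth cap).
#'
#' @param object An `mrt`.
#' @param newdata Tibble with all features the tree references.
#' @param max_depth Optional truncation depth.
#' @param ... Unused.
#' @return A tibble with one column per target, one row per input row.
#' @export
predict.mrt <- function(object, newdata, max_depth = Inf, ...) {
  nodes <- object$nodes
  used <- unique(nodes$feature[!nodes$is_leaf])
  miss <- setdiff(used, names(newdata))
  if (length(miss)) abort(paste0("newdata lacks features: ",
                                 paste(miss, collapse = ", ")))
  for (f in used) {
    if (anyNA(newdata[[f]])) {
      abort(paste0("cannot route rows with missing ", f),
            class = "agetree_routing_error")
    }
  }
  cur <- rep(1L, nrow(newdata))
  repeat {
    at_internal <- !nodes$is_leaf[cur] & nodes$depth[cur] < max_depth
    if (!any(at_internal)) break
    idx <- which(at_internal)
    for (nd in unique(cur[idx])) {
      sel <- idx[cur[idx] == nd]
      go_left <- newdata[[nodes$feature[nd]]][sel] <= nodes$threshold[nd]
      cur[sel] <- ifelse(go_left, nodes$left[nd], nodes$right[nd])
    }
  }
  vals <- do.call(rbind, nodes$value[cur])
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- object$targets
  out
}

#' @method tidy mrt
#' @export
tidy.mrt <- function(x, ...) {
  vals <- do.call(rbind, x$nodes$value)
  colnames(vals) <- x$targets
  dplyr::bind_cols(
    x$nodes[c("id", "depth", "n", "is_leaf", "feature", "threshold",
              "squared_error")],
    tibble::as_tibble(as.data.frame(vals))
  )
}

#' @method glance mrt
#' @export
glance.mrt <- function(x, ...) {
  leaves <- x$nodes[x$nodes$is_leaf, ]
  tibble::tibble(
    n = x$nodes$n[1],
    n_leaves = nrow(leaves),
    depth = max(x$nodes$depth),
    root_squared_error = x$nodes$squared_error[1],
    train_weighted_mse = sum(leaves$n / x$nodes$n[1] * leaves$squared_error)
  )
}
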