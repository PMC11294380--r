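# Depth selection by plain (unstratified) k-fold cross-validation, and
# age-stratified fitting.

#' Select tree depth by k-fold cross-validation
#'
#' Rows are shuffled once with the given seed and dealt into `cv_folds`
#' folds of as-equal-as-possible size. For each fold, one tree is grown on
#' the remaining folds at the largest candidate depth; predictions truncated
#' at each candidate depth (equivalent to growing at that depth, since
#' greedy growth does not depend on the depth cap) are scored on the held-out
#' fold by mean squared error summed over the targets. The chosen depth
#' minimises the mean held-out error; ties resolve to the smaller depth.
#'
#' @inheritParams fit_mrt
#' @param depth_grid Candidate depths (non-negative integers).
#' @param cv_folds Number of folds, `2 <= k <= n`.
#' @param seed Integer seed for the fold shuffle.
#' @return An object of class `mrt_cv`: list with `curve` (tibble `depth`,
#'   `mean_mse`), `folds` (tibble `depth`, `fold`, `mse`), `chosen_depth`,
#'   `cv_folds`, `seed`.
#' @export
#' @examples
#' bench <- synth_tree_benchmark(n = 600, seed = 2)
#' cv <- select_depth_cv(bench, depth_grid = 0:3, cv_folds = 3, seed = 2,
#'                       features = c("education", "safe", "wealth_quintile", "hh_act"))
#' cv$chosen_depth
select_depth_cv <- function(data, targets = index_dimensions(),
                            features = NULL, depth_grid = 1:6,
                            cv_folds = 5, seed = 1L,
                            min_samples_split = 20, min_samples_leaf = 10,
                            tol = 1e-12,
                            criterion = c("corrected", "as_printed")) {
  criterion <- match.arg(criterion)
  if (length(depth_grid) == 0) abort("depth_grid must be non-empty")
  n <- nrow(data)
  if (cv_folds < 2 || cv_folds > n) abort("need 2 <= cv_folds <= n")
  if (floor(n / cv_folds) < 1 || n - ceiling(n / cv_folds) < min_samples_leaf) {
    abort("folds too small for the leaf-size constraints")
  }
  depth_grid <- sort(unique(as.integer(depth_grid)))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold_of <- sample(rep(seq_len(cv_folds), length.out = n))

  res <- purrr::map_dfr(seq_len(cv_folds), function(k) {
    train <- data[fold_of != k, , drop = FALSE]
    test <- data[fold_of == k, , drop = FALSE]
    fit <- fit_mrt(train, targets = targets, features = features,
                   max_depth = max(depth_grid),
                   min_samples_split = min_samples_split,
                   min_samples_leaf = min_samples_leaf,
                   tol = tol, criterion = criterion)
    y <- as_target_matrix(test[targets])
    purrr::map_dfr(depth_grid, function(d) {
      pred <- as.matrix(predict(fit, test, max_depth = d))
      tibble::tibble(depth = d, fold = k, mse = sum((y - pred)^2) / nrow(y))
    })
  })
  curve <- res |>
    dplyr::group_by(.data$depth) |>
    dplyr::summarise(mean_mse = mean(.data$mse), .groups = "drop") |>
    dplyr::arrange(.data$depth)
  chosen <- curve$depth[which.min(curve$mean_mse)]
  structure(list(curve = curve, folds = res, chosen_depth = chosen,
                 cv_folds = cv_folds, seed = seed),
            class = "mrt_cv")
}

#' @export
print.mrt_cv <- function(x, ...) {
  cat("Cross-validated depth selection (k =", x$cv_folds, "): chosen depth",
      x$chosen_depth, "\n")
  print(x$curve)
  invisible(x)
}

#' @method tidy mrt_cv
#' @export
tidy.mrt_cv <- function(x, ...) {
  x$folds |>
    dplyr::group_by(.data$depth) |>
    dplyr::summarise(mean_mse = mean(.data$mse), sd_mse = stats::sd(.data$mse),
                     .groups = "drop")
}

#' @method glance mrt_cv
#' @export
glance.mrt_cv <- function(x, ...) {
  tibble::tibble(chosen_depth = x$chosen_depth,
                 min_mean_mse = min(x$curve$mean_mse),
                 cv_folds = x$cv_folds)
}

#' Default age strata
#'
#' Left-closed intervals `[45, 60)`, `[60, 75)`, `[75, Inf)` plus an `"all"`
#' stratum covering the full filtered sample.
#' @return Named list of `(lower, upper)` pairs.
#' @export
default_age_strata <- function() {
  list(`45-59` = c(45, 60), `60-74` = c(60, 75), `75+` = c(75, Inf),
       all = c(-Inf, Inf))
}

#' Fit one multivariate regression tree per age stratum
#'
#' Each stratum is fitted independently on its rows (the `"all"` stratum on
#' the whole table). With `cv = TRUE` the depth is first chosen per stratum
#' by [select_depth_cv()]; otherwise `max_depth` is used as a fixed depth.
#' Empty strata are skipped with a warning.
#'
#' @inheritParams fit_mrt
#' @inheritParams select_depth_cv
#' @param age_col Name of the age column in `data`.
#' @param strata Named list of `(lower, upper)` age bounds, lower inclusive,
#'   upper exclusive.
#' @param cv Whether to choose the depth by cross-validation.
#' @return A tibble of class `mrt_strata` with columns `stratum`, `n`,
#'   list-columns `tree` (`mrt`) and `cv` (`mrt_cv` or `NULL`).
#' @export
fit_age_stratified <- function(data, targets = index_dimensions(),
                               features = NULL, age_col = "age",
                               strata = default_age_strata(),
                               cv = FALSE, max_depth = 3,
                               depth_grid = 1:6, cv_folds = 5, seed = 1L,
                               min_samples_split = 20, min_samples_leaf = 10,
                               tol = 1e-12,
                               criterion = c("corrected", "as_printed")) {
  criterion <- match.arg(criterion)
  if (!age_col %in% names(data)) abort("data has no age column")
  rows <- purrr::imap(strata, function(bounds, label) {
    sub <- data[data[[age_col]] >= bounds[1] & data[[age_col]] < bounds[2], ,
                drop = FALSE]
    if (nrow(sub) == 0) {
      warn(paste0("empty age stratum skipped: ", label))
      return(NULL)
    }
    cv_fit <- NULL
    depth <- max_depth
    if (cv) {
      cv_fit <- select_depth_cv(sub, targets = targets, features = features,
                                depth_grid = depth_grid, cv_folds = cv_folds,
                                seed = seed,
                                min_samples_split = min_samples_split,
                                min_samples_leaf = min_samples_leaf,
                                tol = tol, criterion = criterion)
      depth <- cv_fit$chosen_depth
    }
    tree <- fit_mrt(sub, targets = targets, features = features,
                    max_depth = depth,
                    min_samples_split = min_samples_split,
                    min_samples_leaf = min_samples_leaf,
                    tol = tol, criterion = criterion)
    tibble::tibble(stratum = label, n = nrow(sub), tree = list(tree),
                   cv = list(cv_fit))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- c("mrt_strata", class(out))
  out
}

#' Split a table into training and testing parts
#'
#' A seeded uniform split used before model fitting; cross-validated depth
#' selection is then applied to the training part only.
#'
#' @param data A tibble.
#' @param prop Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, prop = 0.8, seed = 1L) {
  if (prop <= 0 || prop >= 1) abort("prop must lie strictly in (0, 1)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- nrow(data)
  take <- sample(n, round(prop * n))
  list(train = data[take, , drop = FALSE],
       test = data[-take, , drop = FALSE])
}
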