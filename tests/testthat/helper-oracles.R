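# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas. They deliberately share no code with the package
# internals they check.

# (1/N) sum_i sum_j (y_ij - ybar_j)^2, as an explicit double loop
brute_node_mse <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y)
  ybar <- numeric(p)
  for (j in seq_len(p)) ybar[j] <- sum(y[, j]) / n
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(p)) acc <- acc + (y[i, j] - ybar[j])^2
  }
  acc / n
}

# sum_j (NL/NT * MSE_L,j + NR/NT * MSE_R,j), explicit loops; per-target MSE
# recomputed from its own definition
brute_weighted_mse <- function(l, r, right_weight = c("corrected", "as_printed")) {
  right_weight <- match.arg(right_weight)
  l <- as.matrix(l); r <- as.matrix(r)
  nl <- nrow(l); nr <- nrow(r); nt <- nl + nr
  per_target <- function(block, j) {
    m <- sum(block[, j]) / nrow(block)
    sum((block[, j] - m)^2) / nrow(block)
  }
  wr <- if (right_weight == "corrected") nr / nt else nl / nt
  acc <- 0
  for (j in seq_len(ncol(l))) {
    acc <- acc + (nl / nt) * per_target(l, j) + wr * per_target(r, j)
  }
  acc
}

# exhaustive search over every feature and every midpoint between
# consecutive distinct observed codes
brute_best_split <- function(feats, y, features, min_samples_leaf = 1) {
  y <- as.matrix(y)
  best <- NULL
  for (f in features) {
    v <- feats[[f]]
    codes <- sort(unique(v))
    if (length(codes) < 2) next
    for (k in seq_len(length(codes) - 1)) {
      thr <- (codes[k] + codes[k + 1]) / 2
      left <- v <= thr
      if (sum(left) < min_samples_leaf || sum(!left) < min_samples_leaf) next
      obj <- brute_weighted_mse(y[left, , drop = FALSE], y[!left, , drop = FALSE])
      if (is.null(best) || obj < best$objective - 1e-12) {
        best <- list(feature = f, threshold = thr, objective = obj)
      }
    }
  }
  if (!is.null(best) && brute_node_mse(y) - best$objective <= 1e-12) return(NULL)
  best
}

# random ordinal-feature / continuous-target instance
random_instance <- function(n, n_features, n_codes = 4, seed = 1) {
  withr::with_seed(seed, {
    feats <- tibble::tibble(.rows = n)
    for (j in seq_len(n_features)) {
      feats[[paste0("f", j)]] <- sample(0:(n_codes - 1), n, replace = TRUE)
    }
    y <- matrix(stats::rnorm(n * 5), ncol = 5,
                dimnames = list(NULL, index_dimensions()))
    list(feats = feats, y = y)
  })
}

# small clean survey table (no missingness, everyone eligible)
clean_survey <- function(n, seed = 1) {
  generate_survey(synth_config(n = n, seed = seed, under45_rate = 0,
                               biomarker_missing_rate = 0,
                               missing_rate_items = 0))
}
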