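test_that("node impurity matches the defining double sum", {
  y <- rbind(c(0, 0, 0, 0, 0), c(2, 0, 0, 0, 0))
  expect_equal(node_mse(y), 1)
  expect_equal(node_mse(matrix(3, nrow = 4, ncol = 5)), 0)
  withr::with_seed(10, {
    y <- matrix(rnorm(50), ncol = 5)
    expect_equal(node_mse(y), brute_node_mse(y), tolerance = 1e-12)
  })
  expect_error(node_mse(matrix(numeric(0), ncol = 5)), "at least one")
})

test_that("split objective matches the weighted child-impurity formula", {
  const <- matrix(1, nrow = 3, ncol = 5)
  expect_equal(weighted_split_mse(const, const), 0)
  # pure children: each child constant, parent mixed
  l <- matrix(0, nrow = 4, ncol = 5); r <- matrix(1, nrow = 2, ncol = 5)
  expect_equal(weighted_split_mse(l, r), 0)
  withr::with_seed(20, {
    y <- matrix(rnorm(60), ncol = 5)
    for (cut in c(2, 5, 9)) {
      l <- y[1:cut, , drop = FALSE]
      r <- y[(cut + 1):12, , drop = FALSE]
      expect_equal(weighted_split_mse(l, r), brute_weighted_mse(l, r),
                   tolerance = 1e-12)
      expect_equal(weighted_split_mse(l, r, criterion = "as_printed"),
                   brute_weighted_mse(l, r, "as_printed"), tolerance = 1e-12)
    }
  })
  expect_error(weighted_split_mse(matrix(numeric(0), ncol = 5), const),
               "non-empty")
})

test_that("constant targets admit no split", {
  d <- tibble::tibble(f1 = rep(0:3, 5))
  y <- matrix(2, nrow = 20, ncol = 5)
  expect_null(best_split(d, y, "f1"))
})

test_that("wealth-quintile targets split at 2.5 and route the three poorest groups left", {
  d <- tibble::tibble(wealth_quintile = rep(0:4, each = 6))
  y <- matrix(rep(ifelse(d$wealth_quintile <= 2, -0.3, 0.4), 5), ncol = 5)
  s <- best_split(d, y, "wealth_quintile")
  expect_equal(s$feature, "wealth_quintile")
  expect_equal(s$threshold, 2.5)
  expect_setequal(d$wealth_quintile[d$wealth_quintile <= s$threshold], 0:2)
  expect_setequal(d$wealth_quintile[d$wealth_quintile > s$threshold], 3:4)
})

test_that("best_split equals exhaustive search on random fixtures", {
  for (seed in 1:10) {
    inst <- random_instance(n = 30, n_features = 3, n_codes = 5, seed = seed)
    got <- best_split(inst$feats, inst$y, names(inst$feats))
    want <- brute_best_split(inst$feats, inst$y, names(inst$feats))
    expect_equal(got$feature, want$feature)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$objective, want$objective, tolerance = 1e-12)
  }
})

test_that("a depth-0 tree is a single leaf holding the global means", {
  bench <- synth_tree_benchmark(n = 200, seed = 2)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 0)
  expect_equal(n_leaves(fit), 1L)
  expect_equal(fit$nodes$value[[1]],
               colMeans(as.matrix(bench[index_dimensions()])))
  pred <- predict(fit, bench)
  expect_true(all(apply(pred, 2, function(c) length(unique(c)) == 1)))
})

test_that("the planted two-group driver is recovered at the root", {
  bench <- synth_tree_benchmark(n = 800, seed = 4)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 1,
                 min_samples_split = 2, min_samples_leaf = 1)
  plant <- attr(bench, "plant")
  expect_equal(fit$nodes$feature[1], plant$feature)
  expect_equal(fit$nodes$threshold[1], plant$threshold)
  # and the root choice agrees with exhaustive search
  want <- brute_best_split(bench[feats], bench[index_dimensions()], feats)
  expect_equal(fit$nodes$feature[1], want$feature)
  expect_equal(fit$nodes$threshold[1], want$threshold)
})

test_that("node counts and value vectors are conserved down the tree", {
  bench <- synth_tree_benchmark(n = 500, seed = 6)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 4,
                 min_samples_split = 10, min_samples_leaf = 5)
  nodes <- fit$nodes
  for (i in which(!nodes$is_leaf)) {
    l <- which(nodes$id == nodes$left[i]); r <- which(nodes$id == nodes$right[i])
    expect_equal(nodes$n[i], nodes$n[l] + nodes$n[r])
    # value is the n-weighted mean of the children's values
    expect_equal(nodes$value[[i]],
                 (nodes$n[l] * nodes$value[[l]] + nodes$n[r] * nodes$value[[r]]) / nodes$n[i],
                 tolerance = 1e-10)
    # accepted splits strictly reduce the parent impurity
    child_obj <- (nodes$n[l] * nodes$squared_error[l] +
                    nodes$n[r] * nodes$squared_error[r]) / nodes$n[i]
    expect_lt(child_obj, nodes$squared_error[i] - 1e-12)
  }
  leaves <- nodes[nodes$is_leaf, ]
  expect_equal(sum(leaves$n), nodes$n[1])
  agg <- Reduce(`+`, purrr::map2(leaves$n, leaves$value, `*`)) / nodes$n[1]
  expect_equal(agg, nodes$value[[1]], tolerance = 1e-10)
})

test_that("every split in a grown tree matches exhaustive search (small instances)", {
  for (seed in 1:12) {
    inst <- random_instance(n = sample(15:40, 1), n_features = sample(2:4, 1),
                            n_codes = 4, seed = seed)
    d <- dplyr::bind_cols(inst$feats, tibble::as_tibble(as.data.frame(inst$y)))
    fit <- fit_mrt(d, features = names(inst$feats), max_depth = 3,
                   min_samples_split = 4, min_samples_leaf = 2)
    nodes <- fit$nodes
    # reconstruct each node's row set by routing and re-derive its best split
    route <- function(id, rows) {
      i <- which(nodes$id == id)
      if (!nodes$is_leaf[i]) {
        want <- brute_best_split(inst$feats[rows, ], inst$y[rows, , drop = FALSE],
                                 names(inst$feats), min_samples_leaf = 2)
        expect_equal(nodes$feature[i], want$feature)
        expect_equal(nodes$threshold[i], want$threshold)
        left <- rows[inst$feats[[nodes$feature[i]]][rows] <= nodes$threshold[i]]
        route(nodes$left[i], left)
        route(nodes$right[i], setdiff(rows, left))
      }
    }
    route(1L, seq_len(nrow(d)))
  }
})

test_that("training predictions are leaf means: grand means and weighted MSE identities hold", {
  bench <- synth_tree_benchmark(n = 400, seed = 8)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 3,
                 min_samples_split = 10, min_samples_leaf = 5)
  pred <- as.matrix(predict(fit, bench))
  y <- as.matrix(bench[index_dimensions()])
  expect_equal(colMeans(pred), colMeans(y), tolerance = 1e-10)
  train_mse <- sum((y - pred)^2) / nrow(y)
  leaves <- fit$nodes[fit$nodes$is_leaf, ]
  expect_equal(train_mse,
               sum(leaves$n / nrow(y) * leaves$squared_error),
               tolerance = 1e-10)
})

test_that("prediction truncated at depth d equals the tree grown with depth cap d", {
  bench <- synth_tree_benchmark(n = 600, seed = 12)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  deep <- fit_mrt(bench, features = feats, max_depth = 5,
                  min_samples_split = 10, min_samples_leaf = 5)
  for (d in 0:3) {
    shallow <- fit_mrt(bench, features = feats, max_depth = d,
                       min_samples_split = 10, min_samples_leaf = 5)
    expect_equal(predict(deep, bench, max_depth = d),
                 predict(shallow, bench))
  }
})

test_that("routing rejects missing feature values", {
  bench <- synth_tree_benchmark(n = 100, seed = 3)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 2,
                 min_samples_split = 2, min_samples_leaf = 1)
  bad <- bench
  bad$education[1] <- NA_integer_
  expect_error(predict(fit, bad), class = "agetree_routing_error")
})

test_that("leaf-size and split-size controls bind", {
  inst <- random_instance(n = 40, n_features = 3, n_codes = 5, seed = 77)
  d <- dplyr::bind_cols(inst$feats, tibble::as_tibble(as.data.frame(inst$y)))
  fit <- fit_mrt(d, features = names(inst$feats), max_depth = 6,
                 min_samples_split = 10, min_samples_leaf = 4)
  leaves <- fit$nodes[fit$nodes$is_leaf, ]
  expect_true(all(leaves$n >= 4))
  internal <- fit$nodes[!fit$nodes$is_leaf, ]
  expect_true(all(internal$n >= 10))
  expect_lte(n_leaves(fit), 2^6)
})

test_that("training predictions agree with an independent multi-output tree", {
  withr::with_seed(314, {
    n <- 120
    d <- tibble::tibble(f1 = sample(0:6, n, TRUE),
                        f2 = sample(0:4, n, TRUE),
                        f3 = sample(0:3, n, TRUE))
    y <- matrix(rnorm(n * 5), ncol = 5, dimnames = list(NULL, index_dimensions()))
  })
  dat <- dplyr::bind_cols(d, tibble::as_tibble(as.data.frame(y)))
  fit <- fit_mrt(dat, features = c("f1", "f2", "f3"), max_depth = 3,
                 min_samples_split = 10, min_samples_leaf = 5)
  pred <- as.matrix(predict(fit, dat))

  td <- withr::local_tempdir()
  readr::write_csv(dat, file.path(td, "train.csv"))
  script <- paste(
    "import sys, pandas as pd",
    "from sklearn.tree import DecisionTreeRegressor",
    "d = pd.read_csv(sys.argv[1])",
    "X = d[['f1','f2','f3']]; Y = d.iloc[:, 3:]",
    "m = DecisionTreeRegressor(criterion='squared_error', max_depth=3,",
    "    min_samples_split=10, min_samples_leaf=5).fit(X, Y)",
    "pd.DataFrame(m.predict(X)).to_csv(sys.argv[2], index=False)",
    sep = "\n")
  sf <- file.path(td, "oracle.py")
  writeLines(script, sf)
  status <- system2("python", c(sf, file.path(td, "train.csv"),
                                file.path(td, "pred.csv")),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ext <- as.matrix(readr::read_csv(file.path(td, "pred.csv"),
                                   show_col_types = FALSE))
  expect_equal(unname(pred), unname(ext), tolerance = 1e-8)
})
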