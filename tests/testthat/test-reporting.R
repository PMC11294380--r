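test_that("a single stratum covering everyone has mean zero in every index", {
  tab <- clean_survey(300, seed = 31)
  idx <- build_all_indices(tab)
  scores <- dplyr::left_join(idx, tab[c("id", "age")], by = "id")
  summ <- age_group_means(scores, strata = list(all = c(-Inf, Inf)))
  expect_true(all(abs(summ$mean) < 1e-10))
  expect_equal(unique(summ$n), nrow(tab))
})

test_that("hand-built +1/-1 strata report means +1 and -1", {
  scores <- tibble::tibble(
    id = 1:10, age = rep(c(50L, 70L), each = 5),
    physical = rep(c(1, -1), each = 5), functional = rep(c(1, -1), each = 5),
    mental = rep(c(1, -1), each = 5), cognition = rep(c(1, -1), each = 5),
    social = rep(c(1, -1), each = 5)
  )
  expect_warning(summ <- age_group_means(scores), "empty age stratum")
  expect_equal(summ$mean[summ$stratum == "45-59"], rep(1, 5))
  expect_equal(summ$mean[summ$stratum == "60-74"], rep(-1, 5))
  expect_equal(levels(summ$dimension), index_dimensions())
})

test_that("planted age decline shows up as strictly decreasing cognition means", {
  tab <- generate_survey(synth_config(n = 6000, seed = 37, under45_rate = 0,
                                      biomarker_missing_rate = 0,
                                      missing_rate_items = 0))
  idx <- build_all_indices(tab)
  scores <- dplyr::left_join(idx, tab[c("id", "age")], by = "id")
  summ <- age_group_means(scores)
  cog <- summ$mean[summ$dimension == "cognition"]
  expect_equal(length(cog), 3L)
  expect_true(all(diff(cog) < 0))
  # stratum counts partition the sample
  expect_equal(sum(unique(summ[c("stratum", "n")])$n), nrow(tab))
})

test_that("tree documents carry the node conventions", {
  bench <- synth_tree_benchmark(n = 300, seed = 7)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")

  leaf <- fit_mrt(bench, features = feats, max_depth = 0)
  dot0 <- render_tree(leaf, "dot")
  expect_equal(sum(grepl("label=", dot0)), 1)
  expect_false(any(grepl("->", dot0)))

  full <- fit_mrt(bench, features = feats, max_depth = 3,
                  min_samples_split = 2, min_samples_leaf = 1)
  expect_equal(n_leaves(full), 8L)
  dot <- render_tree(full, "dot")
  node_lines <- grep("^  n\\d+ \\[label=", dot, value = TRUE)
  expect_length(node_lines, 15)   # 2^4 - 1 nodes
  expect_equal(sum(grepl("->", dot)), 14)
  # five values at three decimals in each node label
  expect_true(all(grepl("value = \\[(-?\\d+\\.\\d{3}(, )?){5}\\]", node_lines)))
  expect_error(render_tree(full, "svg"))
})

test_that("node fill shade decreases monotonically with squared error", {
  shades <- agetree:::node_shades(c(0.5, 0.1, 0.9, 0.3))
  lum <- colMeans(grDevices::col2rgb(shades))
  expect_equal(order(lum), order(c(0.5, 0.1, 0.9, 0.3)))
  expect_lt(lum[2], lum[1])  # lowest squared error is darkest
})

test_that("text rendering round-trips through JSON serialization losslessly", {
  bench <- synth_tree_benchmark(n = 400, seed = 19)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 3,
                 min_samples_split = 10, min_samples_leaf = 5)
  f <- withr::local_tempfile(fileext = ".json")
  tree_to_json(fit, f)
  back <- tree_from_json(f)
  expect_identical(render_tree(fit, "text"), render_tree(back, "text"))
  expect_identical(render_tree(fit, "dot"), render_tree(back, "dot"))
  expect_equal(predict(back, bench), predict(fit, bench))
})

test_that("the pipeline is deterministic at the artifact level", {
  cfg <- list(synth = list(n = 800, seed = 3),
              mrt = list(max_depth = 2, min_samples_split = 10,
                         min_samples_leaf = 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("survey.csv", "codebook.yaml", "ledger.json",
                    "indices.csv", "age_group_means.csv", "tree_all.json",
                    "tree_all.dot", "run_log.txt") %in% files))
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]],
                     label = paste("checksum of", f))
  }
})

test_that("pipeline ledger tracks the configured under-45 rate", {
  cfg <- list(synth = list(n = 10000, seed = 8, under45_rate = 0.1,
                           biomarker_missing_rate = 0,
                           missing_rate_items = 0),
              mrt = list(max_depth = 1))
  d <- withr::local_tempdir()
  out <- run_pipeline(cfg, d)
  removed <- glance(out$cohort)$removed_under_age
  # binomial(10000, 0.1): allow 4 sd
  expect_lt(abs(removed - 1000), 4 * sqrt(10000 * 0.1 * 0.9))
})

test_that("pipeline trees reach eight leaves at depth 3 when stopping rules do not bind", {
  cfg <- list(synth = list(n = 4000, seed = 12),
              mrt = list(max_depth = 3, min_samples_split = 2,
                         min_samples_leaf = 1))
  d <- withr::local_tempdir()
  out <- run_pipeline(cfg, d)
  for (i in seq_len(nrow(out$fits))) {
    expect_equal(n_leaves(out$fits$tree[[i]]), 8L,
                 label = paste("leaves in stratum", out$fits$stratum[i]))
  }
  dot <- readLines(file.path(d, "tree_all.dot"))
  expect_equal(sum(grepl("^  n\\d+ \\[label=\"leaf", dot)), 8)
})

test_that("stage errors propagate with stage context", {
  expect_error(run_pipeline(list(synth = list(n = -1)), withr::local_tempdir()),
               "stage 'synth'")
})

test_that("autoplot methods return ggplot objects", {
  tab <- clean_survey(200, seed = 41)
  idx <- build_all_indices(tab)
  scores <- dplyr::left_join(idx, tab[c("id", "age")], by = "id")
  expect_s3_class(autoplot(age_group_means(scores)), "ggplot")
  bench <- synth_tree_benchmark(n = 300, seed = 5)
  feats <- c("education", "safe", "wealth_quintile", "hh_act")
  fit <- fit_mrt(bench, features = feats, max_depth = 2,
                 min_samples_split = 10, min_samples_leaf = 5)
  expect_s3_class(autoplot(fit), "ggplot")
  cv <- select_depth_cv(bench, features = feats, depth_grid = 0:2,
                        cv_folds = 3, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
})
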