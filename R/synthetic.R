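# Synthetic survey generator: seeded, codebook-driven, with planted effects
# acting on item-generation probabilities (pre-index) so recovery tests
# exercise the full index pipeline.

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the composition of a large ageing-survey wave: the
#' under-45 fraction, biomarker non-response fraction and per-cell item
#' missingness are set so the three exclusion stages remove roughly the
#' proportions seen in a 72,250-person wave (9.26%, 8.84% of the remainder,
#' and about 1.2% of rows respectively). Planted effects shift the
#' item-level probability of a healthy response for one dimension wherever a
#' predictor exceeds a threshold; age effects tilt those probabilities
#' per year of age so index means decline across age groups.
#'
#' @param n Number of respondents.
#' @param seed Integer seed; one root seed governs all draws (draw order:
#'   ages, predictors in codebook order, indicator items in codebook order,
#'   biomarker flag, missingness mask).
#' @param age_range Two integers, minimum and maximum age in years.
#' @param under45_rate Fraction of respondents drawn with age below 45.
#' @param biomarker_missing_rate Fraction with `biomarker_available = 0`.
#' @param missing_rate_items Per-cell probability that a predictor or item
#'   cell is set missing (`NA`).
#' @param planted_effects List of lists with elements `feature`, `threshold`,
#'   `dimension`, `shift`: rows whose `feature` code exceeds `threshold` get
#'   the healthy-response probability of every item in `dimension` shifted by
#'   `shift`.
#' @param age_effects Named numeric, per-dimension change in the
#'   healthy-response probability per year of age (centred at 60).
#' @param base_p Named numeric, baseline healthy-response probability per
#'   dimension at age 60 in the reference stratum.
#' @param marginals Optional named list of category probability vectors
#'   overriding the default marginal distribution of a predictor.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n = 500, seed = 7, missing_rate_items = 0)
synth_config <- function(n = 72250,
                         seed = 1L,
                         age_range = c(30L, 95L),
                         under45_rate = 0.0926,
                         biomarker_missing_rate = 0.0884,
                         missing_rate_items = 0.00017,
                         planted_effects = default_planted_effects(),
                         age_effects = default_age_effects(),
                         base_p = default_base_p(),
                         marginals = list()) {
  rates <- c(under45 = under45_rate, biomarker = biomarker_missing_rate,
             missing = missing_rate_items)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "agetree_config_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("n must be a positive count", class = "agetree_config_error")
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    abort("age_range must be (min, max) with min <= max",
          class = "agetree_config_error")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_range = as.integer(age_range),
                 under45_rate = under45_rate,
                 biomarker_missing_rate = biomarker_missing_rate,
                 missing_rate_items = missing_rate_items,
                 planted_effects = planted_effects,
                 age_effects = age_effects,
                 base_p = base_p,
                 marginals = marginals),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_planted_effects <- function() {
  list(
    list(feature = "education", threshold = 4, dimension = "cognition", shift = 0.10),
    list(feature = "education", threshold = 4, dimension = "mental", shift = 0.05),
    list(feature = "education", threshold = 4, dimension = "social", shift = 0.05),
    list(feature = "education", threshold = 10, dimension = "functional", shift = 0.05),
    list(feature = "safe", threshold = 0, dimension = "mental", shift = 0.06),
    list(feature = "hh_act", threshold = 0, dimension = "functional", shift = 0.04),
    list(feature = "wealth_quintile", threshold = 2, dimension = "physical", shift = -0.04)
  )
}

#' @rdname synth_config
#' @export
default_age_effects <- function() {
  c(physical = -0.0030, functional = -0.0045, mental = -0.0012,
    cognition = -0.0045, social = -0.0022)
}

#' @rdname synth_config
#' @export
default_base_p <- function() {
  c(physical = 0.78, functional = 0.88, mental = 0.62,
    cognition = 0.66, social = 0.40)
}

# default marginal for a predictor: mildly skewed for a few named variables,
# uniform otherwise
default_marginal <- function(name, n_codes) {
  if (name == "education") {
    p <- c(0.35, 0.92^(0:19))  # many with no schooling, geometric tail
  } else if (name == "wealth_quintile") {
    p <- rep(1, 5)
  } else if (name == "gender") {
    p <- c(0.48, 0.52)
  } else if (name %in% c("safe", "hh_act", "spiritual_activity")) {
    p <- c(0.35, 0.65)
  } else if (name %in% c("pension", "health_insurance", "ill_treatment",
                         "food_insecurity")) {
    p <- c(0.75, 0.25)
  } else {
    p <- rep(1, n_codes)
  }
  p / sum(p)
}

#' Generate a synthetic coded survey table
#'
#' Draws a rectangular respondent table following the codebook: integer codes
#' for every predictor, indicator items generated per dimension from a
#' binomial model on the healthy-response probability (then flipped to the
#' raw coding direction for `higher_is_worse` items), an `age` column, a
#' `biomarker_available` flag and injected cell-level missingness (`NA`).
#' Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param codebook A codebook tibble; defaults to [default_codebook()].
#' @return A tibble with columns `id`, `age`, `biomarker_available`, then one
#'   integer column per codebook variable; the codebook is attached as
#'   attribute `"codebook"`.
#' @export
#' @examples
#' tab <- generate_survey(synth_config(n = 100, seed = 1))
#' dim(tab)
generate_survey <- function(config = synth_config(), codebook = default_codebook()) {
  if (!inherits(config, "synth_config")) {
    abort("config must be a synth_config", class = "agetree_config_error")
  }
  validate_codebook(codebook)
  n <- config$n
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # ages: fraction under45_rate below 45, remainder 45..max
  lo <- config$age_range[1]; hi <- config$age_range[2]
  under <- runif(n) < config$under45_rate
  age <- integer(n)
  age[under] <- sample(seq(min(lo, 44L), 44L), sum(under), replace = TRUE)
  age[!under] <- sample(seq(max(45L, lo), max(hi, 45L)), sum(!under), replace = TRUE)

  preds <- codebook[codebook$role != "indicator", ]
  tab <- tibble::tibble(id = seq_len(n), age = age)
  for (i in seq_len(nrow(preds))) {
    nm <- preds$name[i]; k <- preds$n_codes[i]
    p <- config$marginals[[nm]] %||% default_marginal(nm, k)
    if (length(p) != k) abort(paste0("marginal for ", nm, " must have ", k, " entries"),
                              class = "agetree_config_error")
    tab[[nm]] <- sample(0:(k - 1L), n, replace = TRUE, prob = p)
  }

  # indicator items: healthy-score s ~ Binomial(K-1, p_dim(row)), then map to
  # raw code by polarity
  items <- codebook[codebook$role == "indicator", ]
  for (i in seq_len(nrow(items))) {
    nm <- items$name[i]; k <- items$n_codes[i]
    dim_i <- items$dimension[i]
    p <- rep(config$base_p[[dim_i]], n)
    p <- p + config$age_effects[[dim_i]] * (age - 60)
    for (eff in config$planted_effects) {
      if (identical(eff$dimension, dim_i)) {
        p <- p + eff$shift * (tab[[eff$feature]] > eff$threshold)
      }
    }
    p <- pmin(pmax(p, 0.02), 0.98)
    s <- rbinom(n, k - 1L, p)
    tab[[nm]] <- if (items$polarity[i] == "higher_is_worse") (k - 1L) - s else s
  }

  tab$biomarker_available <- as.integer(runif(n) >= config$biomarker_missing_rate)

  if (config$missing_rate_items > 0) {
    cells <- codebook$name
    miss <- matrix(runif(n * length(cells)) < config$missing_rate_items,
                   nrow = n)
    for (j in seq_along(cells)) {
      col <- tab[[cells[j]]]
      col[miss[, j]] <- NA_integer_
      tab[[cells[j]]] <- col
    }
  }

  tab <- dplyr::relocate(tab, "id", "age", "biomarker_available")
  attr(tab, "codebook") <- codebook
  tab
}

#' Synthetic benchmark with a planted depth-2 partition
#'
#' Generates uniformly coded predictors and five continuous targets whose
#' means follow a true depth-2 tree: the root splits `education` at the
#' planted threshold, the left child splits `safe` and the right child splits
#' `wealth_quintile`, giving four cells with distinct five-dimensional mean
#' vectors plus Gaussian noise. Used for depth-recovery studies of the
#' cross-validated tree.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A tibble with predictors `education`, `safe`, `wealth_quintile`,
#'   `hh_act` and the five target columns in canonical order; the true
#'   root rule is attached as attribute `"plant"`
#'   (`list(feature, threshold)`).
#' @export
synth_tree_benchmark <- function(n = 2000, seed = 1L, noise_sd = 0.25) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tab <- tibble::tibble(
    education = sample(0:20, n, replace = TRUE),
    safe = sample(0:1, n, replace = TRUE),
    wealth_quintile = sample(0:4, n, replace = TRUE),
    hh_act = sample(0:1, n, replace = TRUE)
  )
  cell <- ifelse(tab$education <= 4,
                 ifelse(tab$safe <= 0, 1L, 2L),
                 ifelse(tab$wealth_quintile <= 2, 3L, 4L))
  # four well-separated mean vectors, one per cell
  mu <- rbind(
    c(-0.6, -0.5, -0.7, -0.6, -0.4),
    c(-0.2, -0.1, -0.1, -0.3, -0.1),
    c( 0.1,  0.2,  0.2,  0.2,  0.1),
    c( 0.6,  0.5,  0.6,  0.7,  0.5)
  )
  dims <- index_dimensions()
  for (j in seq_along(dims)) {
    tab[[dims[j]]] <- mu[cell, j] + stats::rnorm(n, sd = noise_sd)
  }
  attr(tab, "plant") <- list(feature = "education", threshold = 4.5)
  tab
}

#' Write or read a survey table as delimited text
#'
#' Comma-separated with a header row; missing cells are written as empty
#' fields.
#'
#' @param table A survey tibble.
#' @param path File path.
#' @return `write_survey()` returns `path` invisibly; `read_survey()` returns
#'   a tibble of integer columns.
#' @export
write_survey <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_integer()))
}
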