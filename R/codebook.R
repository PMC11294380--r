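# Codebook: declarative description of every survey variable.
# Codes are always consecutive integers 0..n_codes-1 (the survey's encoding
# convention, e.g. wealth quintile poorest = 0 ... richest = 4).

var_spec <- function(name, role, n_codes, polarity, dimension = "none",
                     labels = NULL) {
  tibble::tibble(
    name = name, role = role, n_codes = as.integer(n_codes),
    polarity = polarity, dimension = dimension,
    labels = list(labels %||% as.character(seq_len(n_codes) - 1L))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default codebook for a LASI-like ageing survey
#'
#' Returns one row per variable: the 19 predictors (demographic,
#' socio-economic and health/behavioural factors) and the 48 indicator items
#' feeding the five healthy-ageing indices: 9 chronic-disease items
#' (physical), 13 ADL/IADL difficulty items (functional), 10 affect and
#' life-satisfaction items on a 4-level frequency scale (mental), 5 cognition
#' components (word recall 0-10, orientation 0-8, arithmetic 0-2, executive
#' function 0-2, object naming 0-2), and 11 social-activity items on a
#' 4-level daily/occasionally/rarely/never frequency scale.
#'
#' Integer codes for variable `v` run `0 .. n_codes - 1`. `polarity` records
#' the health direction of the raw coding (`higher_is_better`,
#' `higher_is_worse`, or `neutral` for predictors); index construction uses it
#' to recode every item so that higher always means healthier. `dimension` is
#' `"none"` for predictors and one of [index_dimensions()] for indicator
#' items.
#'
#' Category labels for predictors whose bands the survey documentation leaves
#' open (BMI bands, caste groups, living arrangement) are documented
#' assumptions; they affect labels only, never the code arithmetic.
#'
#' @return A tibble with columns `name`, `role`, `n_codes`, `polarity`,
#'   `dimension` and list-column `labels`.
#' @export
#' @examples
#' cb <- default_codebook()
#' dplyr::count(cb, role)
#' dplyr::filter(cb, name == "wealth_quintile")$labels[[1]]
default_codebook <- function() {
  yn <- c("no", "yes")
  freq4 <- c("never", "rarely", "occasionally", "daily")
  dplyr::bind_rows(
    # demographic
    var_spec("gender", "demographic", 2, "neutral", labels = c("male", "female")),
    var_spec("place_resi", "demographic", 2, "neutral", labels = c("rural", "urban")),
    var_spec("marital_status", "demographic", 4, "neutral",
             labels = c("currently_married", "widowed", "divorced_separated", "never_married")),
    var_spec("education", "demographic", 21, "neutral",
             labels = paste0(0:20, "_years")),
    var_spec("caste", "demographic", 4, "neutral",
             labels = c("scheduled_caste", "scheduled_tribe", "obc", "other")),
    # socio-economic
    var_spec("living_arrangement", "socioeconomic", 4, "neutral",
             labels = c("alone", "with_spouse", "with_spouse_children", "with_children_others")),
    var_spec("wealth_quintile", "socioeconomic", 5, "neutral",
             labels = c("poorest", "poorer", "middle", "richer", "richest")),
    var_spec("work_st", "socioeconomic", 3, "neutral",
             labels = c("never_worked", "currently_working", "not_working")),
    var_spec("financial_support", "socioeconomic", 2, "neutral", labels = yn),
    var_spec("pension", "socioeconomic", 2, "neutral", labels = yn),
    var_spec("health_insurance", "socioeconomic", 2, "neutral", labels = yn),
    var_spec("safe", "socioeconomic", 2, "neutral", labels = yn),
    var_spec("ill_treatment", "socioeconomic", 2, "neutral", labels = yn),
    # health & behaviour
    var_spec("bmi", "health_behaviour", 4, "neutral",
             labels = c("underweight", "normal", "overweight", "obese")),
    var_spec("alcohol_tobacco", "health_behaviour", 2, "neutral", labels = yn),
    var_spec("food_insecurity", "health_behaviour", 2, "neutral", labels = yn),
    var_spec("physical_activity", "health_behaviour", 4, "neutral", labels = freq4),
    var_spec("spiritual_activity", "health_behaviour", 2, "neutral", labels = yn),
    var_spec("hh_act", "health_behaviour", 2, "neutral", labels = yn),
    # physical: chronic-disease items, 1 = disease present
    purrr::map_dfr(
      paste0("chronic_", c("hypertension", "diabetes", "cancer", "lung",
                           "heart", "stroke", "bone", "cholesterol", "neuro")),
      var_spec, role = "indicator", n_codes = 2, polarity = "higher_is_worse",
      dimension = "physical", labels = yn
    ),
    # functional: ADL/IADL items, 1 = difficulty doing the activity
    purrr::map_dfr(
      c(paste0("adl_", c("dressing", "walking", "bathing", "eating", "bed", "toilet")),
        paste0("iadl_", c("food_prep", "shopping", "telephone", "medicine",
                          "housework", "money", "familiar_places"))),
      var_spec, role = "indicator", n_codes = 2, polarity = "higher_is_worse",
      dimension = "functional", labels = yn
    ),
    # mental: frequency of the feeling, 0..3; negative-affect items are
    # higher_is_worse, positively worded items higher_is_better
    purrr::map_dfr(
      paste0("mh_", c("concentrate", "depressed", "tired", "fear",
                      "lonely", "bothered", "effort")),
      var_spec, role = "indicator", n_codes = 4, polarity = "higher_is_worse",
      dimension = "mental", labels = freq4
    ),
    purrr::map_dfr(
      paste0("mh_", c("satisfied", "hopeful", "happy")),
      var_spec, role = "indicator", n_codes = 4, polarity = "higher_is_better",
      dimension = "mental", labels = freq4
    ),
    # cognition components, each on its own score range
    var_spec("cog_word_recall", "indicator", 11, "higher_is_better", "cognition"),
    var_spec("cog_orientation", "indicator", 9, "higher_is_better", "cognition"),
    var_spec("cog_arithmetic", "indicator", 3, "higher_is_better", "cognition"),
    var_spec("cog_executive", "indicator", 3, "higher_is_better", "cognition"),
    var_spec("cog_naming", "indicator", 3, "higher_is_better", "cognition"),
    # social-activity frequency items
    purrr::map_dfr(
      paste0("soc_", c("eat_out", "park", "indoor_games", "outdoor_games",
                       "visit_relatives", "cultural", "religious",
                       "group_meetings", "read", "tv", "computer")),
      var_spec, role = "indicator", n_codes = 4, polarity = "higher_is_better",
      dimension = "social", labels = freq4
    )
  )
}

#' Predictor and indicator names from a codebook
#'
#' @param codebook A codebook tibble, as from [default_codebook()].
#' @return Character vector of variable names.
#' @export
predictor_names <- function(codebook = default_codebook()) {
  codebook$name[codebook$role != "indicator"]
}

#' @rdname predictor_names
#' @param dimension Optional dimension to restrict to.
#' @export
indicator_names <- function(codebook = default_codebook(), dimension = NULL) {
  cb <- codebook[codebook$role == "indicator", ]
  if (!is.null(dimension)) cb <- cb[cb$dimension %in% dimension, ]
  cb$name
}

validate_codebook <- function(codebook) {
  stopifnot(is.data.frame(codebook),
            all(c("name", "role", "n_codes", "polarity", "dimension") %in% names(codebook)))
  if (anyDuplicated(codebook$name) > 0) {
    abort("codebook variable names must be unique")
  }
  if (any(codebook$n_codes < 2L)) {
    abort("every codebook variable needs at least two codes")
  }
  bad <- codebook$role == "indicator" & codebook$dimension == "none"
  if (any(bad)) {
    abort(paste0("indicator items must carry a dimension: ",
                 paste(codebook$name[bad], collapse = ", ")))
  }
  bad <- codebook$role != "indicator" & codebook$dimension != "none"
  if (any(bad)) {
    abort(paste0("predictors must have dimension 'none': ",
                 paste(codebook$name[bad], collapse = ", ")))
  }
  invisible(codebook)
}

#' Write or read a codebook as a human-editable YAML file
#'
#' One top-level key per variable, holding role, polarity, dimension and the
#' ordered code labels (position = integer code).
#'
#' @param codebook A codebook tibble.
#' @param path File path.
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns a codebook tibble.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  entries <- purrr::pmap(codebook, function(name, role, n_codes, polarity,
                                            dimension, labels) {
    list(role = role, polarity = polarity, dimension = dimension,
         labels = as.list(labels))
  })
  names(entries) <- codebook$name
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  entries <- yaml::read_yaml(path)
  cb <- purrr::imap_dfr(entries, function(e, nm) {
    var_spec(nm, e$role, length(e$labels), e$polarity,
             e$dimension %||% "none", unlist(e$labels))
  })
  validate_codebook(cb)
  cb
}
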