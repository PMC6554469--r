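#' Score bands of the semi-quantitative IHC scheme
#' @export
SCORE_BANDS <- c("negative", "weak-moderate", "strong")

percent_category_levels <- c("Zero", "I", "II", "III")

#' Bin a percent-positive value into its IHC percentage category
#'
#' Exactly 0% of cells positive is `Zero` (negative); under 5% is `I`;
#' 5-10% inclusive is `II`; strictly more than 10% is `III`. The 5% and 10%
#' boundaries fall in `II` because category I is defined as under 5% and
#' category III as over 10%.
#'
#' @param percent_positive Numeric vector of percentages in \[0, 100\].
#' @return Factor with levels `Zero`, `I`, `II`, `III`.
#' @examples
#' percent_category(c(0, 3, 7, 10, 10.5))
#' @export
percent_category <- function(percent_positive) {
  if (!is.numeric(percent_positive) || anyNA(percent_positive)) {
    abort("`percent_positive` must be numeric with no missing values.")
  }
  if (any(percent_positive < 0 | percent_positive > 100)) {
    abort("`percent_positive` must lie in [0, 100].")
  }
  out <- dplyr::case_when(
    percent_positive == 0 ~ "Zero",
    percent_positive < 5 ~ "I",
    percent_positive <= 10 ~ "II",
    TRUE ~ "III"
  )
  factor(out, levels = percent_category_levels)
}

#' Semi-quantitative IHC expression score
#'
#' Multiplies the numeric value of the percentage category (`Zero` = 0,
#' `I` = 1, `II` = 2, `III` = 3) by the staining intensity (1 weak,
#' 2 moderate, 3 strong). Attainable scores are exactly
#' {0, 1, 2, 3, 4, 6, 9}: positive samples score 1-4 (weak-moderate band)
#' or 6-9 (strong band); 5, 7 and 8 cannot arise as products. Negative
#' (`Zero`) samples carry no intensity, score 0.
#'
#' @param percent_category Character or factor vector over
#'   `Zero`/`I`/`II`/`III`.
#' @param intensity Integer vector in {1, 2, 3}; must be `NA` exactly where
#'   the category is `Zero`.
#' @return Integer vector of expression scores.
#' @examples
#' expression_score("III", 3)        # 9, the maximum
#' expression_score("Zero", NA)      # 0
#' @export
expression_score <- function(percent_category, intensity) {
  cat <- as.character(percent_category)
  bad <- setdiff(unique(cat), percent_category_levels)
  if (length(bad) || anyNA(cat)) {
    abort(sprintf("Unknown percentage category: %s",
                  paste(c(bad, if (anyNA(cat)) "NA"), collapse = ", ")))
  }
  if (length(intensity) != length(cat)) {
    intensity <- rep(intensity, length.out = length(cat))
  }
  zero <- cat == "Zero"
  if (any(!is.na(intensity[zero]))) {
    abort("Intensity must be absent (NA) for Zero (negative) samples.")
  }
  if (anyNA(intensity[!zero])) {
    abort("Intensity is required for positive samples.")
  }
  if (any(!intensity[!zero] %in% c(1L, 2L, 3L))) {
    abort("Intensity must be 1 (weak), 2 (moderate) or 3 (strong).")
  }
  mult <- c(Zero = 0L, I = 1L, II = 2L, III = 3L)[cat]
  out <- integer(length(cat))
  out[!zero] <- mult[!zero] * as.integer(intensity[!zero])
  unname(out)
}

#' Band an IHC expression score
#'
#' Score 0 is `negative`; 1-4 is `weak-moderate`; 6 and 9 are `strong`.
#' Scores outside the attainable set {0, 1, 2, 3, 4, 6, 9} are rejected.
#'
#' @param score Integer vector of expression scores.
#' @return Factor with levels `negative`, `weak-moderate`, `strong`.
#' @export
score_band <- function(score) {
  if (anyNA(score) || any(!score %in% c(0L, 1L, 2L, 3L, 4L, 6L, 9L))) {
    abort("Scores must lie in the attainable set {0, 1, 2, 3, 4, 6, 9}.")
  }
  out <- dplyr::case_when(
    score == 0 ~ "negative",
    score <= 4 ~ "weak-moderate",
    TRUE ~ "strong"
  )
  factor(out, levels = SCORE_BANDS)
}

#' Score a table of IHC observations
#'
#' Adds `percent_category` (derived from a `percent_positive` column when
#' the category is not already present), the product expression `score` and
#' its `band` to each observation row.
#'
#' @param observations Data frame of stained-sample records with columns
#'   `sample`, `patient`, `group`, `gene`, `intensity` and either
#'   `percent_category` or `percent_positive`.
#' @return The observations as a tibble with `percent_category`, `score`
#'   and `band` columns appended.
#' @export
score_ihc <- function(observations) {
  obs <- as_tibble(observations)
  needed <- c("sample", "group", "gene", "intensity")
  if (!all(needed %in% colnames(obs))) {
    abort(sprintf("Observations must have columns %s plus percent_category or percent_positive.",
                  paste(needed, collapse = ", ")))
  }
  if (!"percent_category" %in% colnames(obs)) {
    if (!"percent_positive" %in% colnames(obs)) {
      abort("Provide either a percent_category or a percent_positive column.")
    }
    obs$percent_category <- percent_category(obs$percent_positive)
  } else {
    obs$percent_category <- factor(as.character(obs$percent_category),
                                   levels = percent_category_levels)
  }
  obs$score <- expression_score(obs$percent_category, obs$intensity)
  obs$band <- score_band(obs$score)
  obs
}
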