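#' Height-for-age Z-scores
#'
#' Standardises height against a growth reference:
#' `HAZ = (height - median(sex, age)) / sd(sex, age)`.
#' Vectorised over children; every (sex, age) pair must be present in the
#' reference.
#'
#' @param height_cm Numeric vector of heights (cm), all > 0.
#' @param age_months Integer vector of ages in months.
#' @param sex Character vector, `"male"` or `"female"`.
#' @param ref Growth reference tibble (see [load_growth_reference()]).
#' @return Numeric vector of HAZ values (SD units).
#' @export
#' @examples
#' ref <- tibble::tibble(sex = "male", age_months = 12L,
#'                       median_cm = 75, sd_cm = 2.5)
#' compute_haz(70, 12, "male", ref)  # -2
compute_haz <- function(height_cm, age_months, sex, ref) {
  stopifnot(length(height_cm) == length(age_months),
            length(height_cm) == length(sex))
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be finite and > 0", call. = FALSE)
  }
  key <- paste(sex, age_months)
  idx <- match(key, paste(ref$sex, ref$age_months))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("growth reference has no entry for: ",
         paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
  }
  (height_cm - ref$median_cm[idx]) / ref$sd_cm[idx]
}

#' Classify stunting from HAZ
#'
#' A child is stunted when HAZ is *strictly* below -2 SD; HAZ exactly -2 is
#' not stunted. The strict rule is fixed for reproducibility even though
#' boundary ties are vanishingly rare with continuous heights.
#'
#' @param haz Numeric vector of finite HAZ values.
#' @return Logical vector.
#' @export
classify_stunting <- function(haz) {
  if (any(!is.finite(haz))) stop("haz must be finite", call. = FALSE)
  haz < -2
}

#' Classify poverty status from income
#'
#' Children are split into wealth groups at the World Bank international
#' poverty line of $5.50/day (2011 PPP), i.e. 19.4 RMB/day. Income exactly
#' at the line counts as non-poor ("living under the line" is strict).
#'
#' @param income_per_capita Numeric vector, RMB/day, >= 0.
#' @param poverty_line_rmb_day The line, RMB/day.
#' @return Character vector, `"poor"` or `"nonpoor"`.
#' @export
classify_wealth <- function(income_per_capita, poverty_line_rmb_day = 19.4) {
  if (any(!is.finite(income_per_capita)) || any(income_per_capita < 0)) {
    stop("income_per_capita must be finite and >= 0", call. = FALSE)
  }
  ifelse(income_per_capita < poverty_line_rmb_day, "poor", "nonpoor")
}

#' Add HAZ, stunting and wealth columns to child microdata
#'
#' Convenience wrapper for the standardisation step of the pipeline: takes
#' the children table and returns it with `haz`, `stunted` and `wealth`
#' columns appended.
#'
#' @param children Child microdata tibble with at least `height_cm`,
#'   `age_months`, `sex` and `income_per_capita`.
#' @param ref Growth reference tibble.
#' @param poverty_line_rmb_day Poverty line for [classify_wealth()].
#' @return `children` with `haz`, `stunted`, `wealth` columns.
#' @export
add_haz <- function(children, ref = load_growth_reference(),
                    poverty_line_rmb_day = 19.4) {
  dplyr::mutate(
    children,
    haz = compute_haz(.data$height_cm, .data$age_months, .data$sex, ref),
    stunted = classify_stunting(.data$haz),
    wealth = classify_wealth(.data$income_per_capita, poverty_line_rmb_day)
  )
}

#' Stunting prevalence of a group
#'
#' The (optionally weighted) fraction of records that are stunted. An empty
#' group has no defined prevalence and is an error here; group-level
#' reporting propagates such groups as `NA` instead (see
#' [stunting_prevalence()]).
#'
#' @param stunted Logical vector (one element per child).
#' @param weights Optional positive weights, same length.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' prevalence(c(TRUE, FALSE, FALSE, FALSE))            # 0.25
#' prevalence(c(TRUE, FALSE), weights = c(3, 1))       # 0.75
prevalence <- function(stunted, weights = NULL) {
  if (length(stunted) == 0) {
    stop("prevalence is undefined for an empty group", call. = FALSE)
  }
  if (anyNA(stunted)) stop("stunted contains NA", call. = FALSE)
  if (is.null(weights)) {
    return(mean(stunted))
  }
  if (length(weights) != length(stunted) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("weights must be positive, finite, and match length", call. = FALSE)
  }
  sum(weights * stunted) / sum(weights)
}

#' Stunting prevalence by subgroup
#'
#' Groupwise prevalence over a children table that already carries a
#' `stunted` column (see [add_haz()]). Grouping combinations listed in
#' `complete` but absent from the data get `NA` prevalence, mirroring the
#' "NA" cells that appear for provinces with no children in a wealth group.
#'
#' @param children Tibble with a logical `stunted` column and the grouping
#'   columns.
#' @param by Character vector of grouping column names.
#' @param weight_col Optional name of a positive weight column
#'   (e.g. `"survey_weight"`).
#' @param complete Optional tibble of grouping combinations that must all
#'   appear in the output.
#' @return Tibble with the grouping columns, `n`, and `prevalence`.
#' @export
stunting_prevalence <- function(children, by = c("province", "wealth"),
                                weight_col = NULL, complete = NULL) {
  w <- if (is.null(weight_col)) rep(1, nrow(children)) else children[[weight_col]]
  out <- children |>
    dplyr::mutate(.w = w) |>
    dplyr::summarise(
      n = dplyr::n(),
      prevalence = sum(.data$.w * .data$stunted) / sum(.data$.w),
      .by = dplyr::all_of(by)
    )
  if (!is.null(complete)) {
    out <- dplyr::left_join(complete, out, by = by) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}
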