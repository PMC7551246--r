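#' Height effect of the supplementation programme
#'
#' The intervention is modelled as a uniform height gain for supplemented
#' children. The default effect is a 2.46 cm mean height increase with a
#' 95% confidence interval of 0.96-3.97 cm, the pooled estimate across YYB
#' evaluation studies; it is an input parameter here, not re-estimated.
#'
#' @param eff_cm Mean height gain, cm, >= 0.
#' @param ci_lower_cm,ci_upper_cm Confidence bounds, cm.
#' @return A list of class `"effect_params"`.
#' @export
effect_params <- function(eff_cm = 2.46, ci_lower_cm = 0.96,
                          ci_upper_cm = 3.97) {
  if (!is.finite(eff_cm) || eff_cm < 0) {
    stop("eff_cm must be finite and >= 0", call. = FALSE)
  }
  if (!(ci_lower_cm <= eff_cm && eff_cm <= ci_upper_cm)) {
    stop("need ci_lower_cm <= eff_cm <= ci_upper_cm", call. = FALSE)
  }
  structure(list(eff_cm = eff_cm, ci_lower_cm = ci_lower_cm,
                 ci_upper_cm = ci_upper_cm), class = "effect_params")
}

#' Apply the height-shift intervention model
#'
#' In `"expected_shift"` mode (the default, and the model behind the
#' published tables) every child's post-intervention height is the expected
#' height `height + eff * coverage`. In `"bernoulli"` mode each child is
#' covered with probability `coverage` (seeded) and covered children gain
#' the full `eff`; the two modes differ in distribution even though the
#' mean height shift is identical. Post-intervention HAZ and stunting are
#' recomputed against the same growth reference.
#'
#' @param children Child table that already has `haz`/`stunted` columns
#'   (see [add_haz()]); bare tables are standardised on the fly.
#' @param ref Growth reference.
#' @param effect An [effect_params()].
#' @param coverage Coverage probability in `[0, 1]`.
#' @param mode `"expected_shift"` or `"bernoulli"`.
#' @param seed Seed for `"bernoulli"` mode.
#' @return `children` with added columns `height_post_cm`, `haz_post`,
#'   `stunted_post` (and `covered` in bernoulli mode).
#' @export
#' @examples
#' ref <- tibble::tibble(sex = "male", age_months = 12L,
#'                       median_cm = 75, sd_cm = 2.5)
#' child <- tibble::tibble(child_id = "c1", province = "P01",
#'                         age_months = 12L, sex = "male",
#'                         height_cm = 75 - 2.05 * 2.5,
#'                         income_per_capita = 10, survey_weight = 1)
#' out <- apply_effect(child, ref, coverage = 1)
#' out$haz_post  # -2.05 + 2.46 / 2.5 = -1.066; no longer stunted
apply_effect <- function(children, ref = load_growth_reference(),
                         effect = effect_params(), coverage,
                         mode = c("expected_shift", "bernoulli"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(children) == 0) stop("children must be nonempty", call. = FALSE)
  if (!is.finite(coverage) || coverage < 0 || coverage > 1) {
    stop("coverage must be in [0, 1]", call. = FALSE)
  }
  if (!"haz" %in% names(children)) children <- add_haz(children, ref)
  if (mode == "expected_shift") {
    children <- dplyr::mutate(
      children,
      height_post_cm = .data$height_cm + effect$eff_cm * coverage
    )
  } else {
    covered <- withr::with_seed(
      seed, stats::runif(nrow(children)) < coverage)
    children <- dplyr::mutate(
      children,
      covered = covered,
      height_post_cm = .data$height_cm + effect$eff_cm * .data$covered
    )
  }
  dplyr::mutate(
    children,
    haz_post = compute_haz(.data$height_post_cm, .data$age_months,
                           .data$sex, ref),
    stunted_post = classify_stunting(.data$haz_post)
  )
}

#' Stunting cases averted in one subgroup
#'
#' Population-scaled expectation
#' `averted = pop * (s_pre - s_post)`
#' where `s_pre`/`s_post` are the pre- and post-intervention stunting
#' prevalences of the subgroup. `pre` and `post` must describe the same
#' children (matched on `child_id`). Averted counts are carried as reals;
#' rounding happens only at presentation.
#'
#' @param pre,post Tibbles with `child_id` and a logical `stunted` column.
#' @param pop Subgroup population size (>= 0).
#' @param weights Optional positive survey weights aligned with `pre`.
#' @return One-row tibble with `s_pre`, `s_post`, `pop`, `averted`.
#' @export
#' @examples
#' pre <- tibble::tibble(child_id = 1:10, stunted = rep(c(TRUE, FALSE), 5))
#' post <- tibble::tibble(child_id = 1:10, stunted = rep(FALSE, 10))
#' averted_cases(pre, post, pop = 1e6)  # s 0.5 -> 0, averts 500,000
averted_cases <- function(pre, post, pop, weights = NULL) {
  if (!is.finite(pop) || pop < 0) stop("pop must be >= 0", call. = FALSE)
  if (nrow(pre) != nrow(post) ||
      !identical(sort(as.character(pre$child_id)),
                 sort(as.character(post$child_id)))) {
    stop("pre and post must cover the same child_ids", call. = FALSE)
  }
  post <- post[match(pre$child_id, post$child_id), ]
  s_pre <- prevalence(pre$stunted, weights)
  s_post <- prevalence(post$stunted, weights)
  tibble::tibble(s_pre = s_pre, s_post = s_post, pop = pop,
                 averted = pop * (s_pre - s_post))
}

#' Subgroup outcomes of an intervention run
#'
#' Summarises an [apply_effect()] result into one row per province and
#' wealth group: survey-weighted pre/post stunting prevalence, the
#' subgroup population taken from the province table, and cases averted.
#' Province x wealth cells with no surveyed children get `NA` prevalences
#' and `NA` averted.
#'
#' @param shifted Output of [apply_effect()] (has `stunted`,
#'   `stunted_post`, `wealth`).
#' @param provinces Province table with `pop_6_36m_poor` /
#'   `pop_6_36m_nonpoor`.
#' @param weight_col Name of the survey-weight column, or `NULL` for
#'   unweighted.
#' @return Tibble with `province`, `wealth`, `n`, `pop`, `s_pre`, `s_post`,
#'   `averted`.
#' @export
group_outcomes <- function(shifted, provinces, weight_col = "survey_weight") {
  pops <- provinces |>
    dplyr::select("province", poor = "pop_6_36m_poor",
                  nonpoor = "pop_6_36m_nonpoor") |>
    tidyr::pivot_longer(c("poor", "nonpoor"), names_to = "wealth",
                        values_to = "pop")
  w <- if (is.null(weight_col)) rep(1, nrow(shifted)) else shifted[[weight_col]]
  obs <- shifted |>
    dplyr::mutate(.w = w) |>
    dplyr::summarise(
      n = dplyr::n(),
      s_pre = sum(.data$.w * .data$stunted) / sum(.data$.w),
      s_post = sum(.data$.w * .data$stunted_post) / sum(.data$.w),
      .by = c("province", "wealth")
    )
  pops |>
    dplyr::left_join(obs, by = c("province", "wealth")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      averted = .data$pop * (.data$s_pre - .data$s_post)
    ) |>
    dplyr::arrange(.data$province, .data$wealth)
}
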