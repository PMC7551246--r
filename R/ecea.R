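#' Define an analysis scenario
#'
#' A scenario fixes the programme coverage, the delivery type, the effect
#' modification (either a multiplier on the default effect or an absolute
#' override in cm — never both), a transport-cost multiplier, the
#' intervention mode, and the seed for any scenario-level randomness.
#'
#' @param coverage Coverage in `[0, 1]` (the study's scenarios use 0.25 and
#'   0.75).
#' @param delivery_type 1 (village health posts) or 2 (township hospitals).
#' @param effect_multiplier Scale on the default effect size (>= 0).
#' @param effect_override_cm Absolute effect size in cm; when given,
#'   `effect_multiplier` must stay 1.
#' @param transport_multiplier Positive scale on the transport cost term.
#' @param mode `"expected_shift"` or `"bernoulli"` (see [apply_effect()]).
#' @param seed Integer seed for bernoulli coverage draws.
#' @param label Optional scenario label used in outputs.
#' @return A list of class `"yyb_scenario"`.
#' @export
scenario <- function(coverage, delivery_type = 1L, effect_multiplier = 1.0,
                     effect_override_cm = NULL, transport_multiplier = 1.0,
                     mode = c("expected_shift", "bernoulli"), seed = 1L,
                     label = NULL) {
  mode <- match.arg(mode)
  problems <- character()
  if (!is.finite(coverage) || coverage < 0 || coverage > 1) {
    problems <- c(problems, "coverage must be in [0, 1]")
  }
  if (!delivery_type %in% c(1, 2)) {
    problems <- c(problems, "delivery_type must be 1 or 2")
  }
  if (!is.finite(effect_multiplier) || effect_multiplier < 0) {
    problems <- c(problems, "effect_multiplier must be >= 0")
  }
  if (!is.null(effect_override_cm)) {
    if (!is.finite(effect_override_cm) || effect_override_cm < 0) {
      problems <- c(problems, "effect_override_cm must be >= 0")
    }
    if (effect_multiplier != 1.0) {
      problems <- c(problems,
                    "give either effect_multiplier or effect_override_cm, not both")
    }
  }
  if (!is.finite(transport_multiplier) || transport_multiplier <= 0) {
    problems <- c(problems, "transport_multiplier must be > 0")
  }
  if (length(problems) > 0) {
    stop("invalid scenario:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(
    list(coverage = coverage, delivery_type = as.integer(delivery_type),
         effect_multiplier = effect_multiplier,
         effect_override_cm = effect_override_cm,
         transport_multiplier = transport_multiplier, mode = mode,
         seed = as.integer(seed), label = label),
    class = "yyb_scenario"
  )
}

# effective height gain (cm) implied by a scenario
scenario_effect_cm <- function(effect, scen) {
  if (!is.null(scen$effect_override_cm)) scen$effect_override_cm
  else effect$eff_cm * scen$effect_multiplier
}

#' Run one full ECEA scenario
#'
#' The complete pipeline for one scenario: HAZ standardisation and wealth
#' classification, height-shift intervention, per-group pre/post stunting
#' prevalence and cases averted, per-pack and total costs, and the cost per
#' stunting case averted (ICER) for every province x wealth group. Groups
#' that avert zero cases get an `NA` ICER (never infinity), matching the
#' "NA" convention for provinces with no stunted children.
#'
#' @param children Child microdata (see [simulate_children()] or
#'   [read_children()]).
#' @param provinces Province table with populations, road density and GDP.
#' @param ref Growth reference.
#' @param effect An [effect_params()].
#' @param costs A [cost_params()].
#' @param scen A [scenario()].
#' @param weight_col Survey-weight column name, or `NULL`.
#' @return An object of class `"yyb_ecea"`: use [tidy()][generics::tidy]
#'   for the per-group table, [glance()][generics::glance] for national
#'   totals, and `autoplot()` for an ICER plot.
#' @export
#' @examples
#' cfg <- sim_config(n_provinces = 3, children_per_province = 200)
#' prov <- simulate_provinces(cfg, seed = 7)
#' kids <- simulate_children(cfg, prov, seed = 7)
#' res <- run_scenario(kids, prov, scen = scenario(coverage = 0.75))
#' tidy(res)
#' glance(res)
run_scenario <- function(children, provinces, ref = load_growth_reference(),
                         effect = effect_params(), costs = cost_params(),
                         scen, weight_col = "survey_weight") {
  stopifnot(inherits(scen, "yyb_scenario"))
  missing_prov <- setdiff(unique(children$province), provinces$province)
  if (length(missing_prov) > 0) {
    stop("children reference provinces without a profile: ",
         paste(missing_prov, collapse = ", "), call. = FALSE)
  }
  scen_costs <- costs
  scen_costs$transport_multiplier <-
    costs$transport_multiplier * scen$transport_multiplier
  eff_cm <- scenario_effect_cm(effect, scen)
  scen_effect <- effect_params(eff_cm, min(effect$ci_lower_cm, eff_cm),
                               max(effect$ci_upper_cm, eff_cm))

  std <- add_haz(children, ref)
  shifted <- apply_effect(std, ref, scen_effect, scen$coverage,
                          mode = scen$mode, seed = scen$seed)
  outcomes <- group_outcomes(shifted, provinces, weight_col)
  packs <- pack_costs(provinces, summarise_travel(std, weight_col),
                      scen_costs) |>
    dplyr::filter(.data$delivery_type == scen$delivery_type)

  groups <- outcomes |>
    dplyr::left_join(
      dplyr::select(packs, "province", "wealth", "delivery_type",
                    "t_total", "pp"),
      by = c("province", "wealth")
    ) |>
    dplyr::mutate(
      coverage = scen$coverage,
      total_cost_rmb = dplyr::if_else(
        is.na(.data$pp), NA_real_,
        total_cost(.data$pp, .data$pop, scen$coverage, scen_costs)),
      total_cost_intl = rmb_to_intl(.data$total_cost_rmb, scen_costs),
      icer_rmb_per_case = dplyr::if_else(
        !is.na(.data$averted) & .data$averted > 0,
        .data$total_cost_rmb / .data$averted, NA_real_),
      icer_intl_per_case = rmb_to_intl(.data$icer_rmb_per_case, scen_costs)
    ) |>
    dplyr::relocate("delivery_type", "coverage", .after = "wealth")

  national <- groups |>
    dplyr::summarise(
      pop = sum(.data$pop),
      averted = sum(.data$averted, na.rm = TRUE),
      total_cost_rmb = sum(.data$total_cost_rmb, na.rm = TRUE),
      .by = "wealth"
    ) |>
    dplyr::mutate(total_cost_intl = rmb_to_intl(.data$total_cost_rmb, scen_costs)) |>
    dplyr::arrange(.data$wealth)

  structure(
    list(groups = groups, national = national, scenario = scen,
         effect_cm = eff_cm, costs = scen_costs),
    class = "yyb_ecea"
  )
}

#' @export
print.yyb_ecea <- function(x, ...) {
  scen <- x$scenario
  cat("<yyb_ecea> coverage ", scen$coverage * 100, "%, Delivery Type ",
      scen$delivery_type, ", effect ", round(x$effect_cm, 2), " cm, mode ",
      scen$mode, "\n", sep = "")
  tot <- sum(x$national$averted)
  cost <- sum(x$national$total_cost_rmb)
  cat("  cases averted: ", format(round(tot), big.mark = ","),
      "; total cost: ", format(round(cost), big.mark = ","), " RMB (",
      format(round(rmb_to_intl(cost, x$costs)), big.mark = ","), " intl $)\n",
      sep = "")
  cat("  groups: ", nrow(x$groups), " (province x wealth); use tidy() for the table\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-group results of an ECEA scenario
#'
#' One row per province x wealth group: pre/post stunting prevalence,
#' population, cases averted, per-pack and total costs, and the cost per
#' stunting case averted in RMB and international dollars.
#'
#' @param x A `yyb_ecea` object from [run_scenario()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy yyb_ecea
#' @export
tidy.yyb_ecea <- function(x, ...) {
  x$groups
}

#' National summary of an ECEA scenario
#'
#' @param x A `yyb_ecea` object.
#' @param ... Unused.
#' @return A one-row tibble with scenario settings, total and poor-group
#'   cases averted, total costs (RMB and intl $), and the national average
#'   cost per case averted.
#' @method glance yyb_ecea
#' @export
glance.yyb_ecea <- function(x, ...) {
  tot_averted <- sum(x$national$averted)
  tot_cost <- sum(x$national$total_cost_rmb)
  poor <- x$national[x$national$wealth == "poor", ]
  tibble::tibble(
    coverage = x$scenario$coverage,
    delivery_type = x$scenario$delivery_type,
    effect_cm = x$effect_cm,
    mode = x$scenario$mode,
    averted_total = tot_averted,
    averted_poor = if (nrow(poor) == 1) poor$averted else NA_real_,
    total_cost_rmb = tot_cost,
    total_cost_intl = rmb_to_intl(tot_cost, x$costs),
    icer_rmb_per_case = if (tot_averted > 0) tot_cost / tot_averted else NA_real_
  )
}

#' Rank subgroups by cost per case averted
#'
#' Sorts the per-group table ascending by ICER; groups with an undefined
#' (`NA`) ICER come last. Ties are broken stably by province then wealth
#' label.
#'
#' @param result A `yyb_ecea` object or a tidy per-group tibble with an
#'   `icer_rmb_per_case` column.
#' @return The per-group tibble, ranked, with a `rank` column (`NA` for
#'   undefined ICERs).
#' @export
rank_groups <- function(result) {
  groups <- if (inherits(result, "yyb_ecea")) result$groups else result
  ranked <- groups |>
    dplyr::arrange(is.na(.data$icer_rmb_per_case),
                   .data$icer_rmb_per_case, .data$province, .data$wealth)
  ranked$rank <- ifelse(is.na(ranked$icer_rmb_per_case), NA_integer_,
                        seq_len(nrow(ranked)))
  ranked
}

#' Sensitivity-analysis scenario grid
#'
#' Runs the labelled sensitivity suite over the full scenario grid:
#' effect variations \{base, effect halved, effect at the lower 95% CI
#' bound of 0.96 cm\} and transport-cost variations \{halved, doubled\},
#' each crossed with coverage \{0.25, 0.75\} and Delivery Types \{1, 2\}.
#'
#' @param children,provinces,ref,effect,costs As in [run_scenario()].
#' @param coverages Coverage levels to sweep.
#' @param delivery_types Delivery types to sweep.
#' @param mode,seed,weight_col Passed to each scenario.
#' @return A tibble of class `"yyb_sensitivity"`: one row per label x
#'   coverage x delivery type with the fitted `yyb_ecea` in a list column
#'   `result` and its [glance()] columns unnested alongside.
#' @export
sensitivity_suite <- function(children, provinces,
                              ref = load_growth_reference(),
                              effect = effect_params(),
                              costs = cost_params(),
                              coverages = c(0.25, 0.75),
                              delivery_types = c(1L, 2L),
                              mode = "expected_shift", seed = 1L,
                              weight_col = "survey_weight") {
  specs <- tibble::tibble(
    label = c("base", "eff_halved", "eff_ci_lower", "transport_halved",
              "transport_doubled"),
    effect_multiplier = c(1, 0.5, 1, 1, 1),
    effect_override_cm = list(NULL, NULL, effect$ci_lower_cm, NULL, NULL),
    transport_multiplier = c(1, 1, 1, 0.5, 2)
  )
  grid <- tidyr::crossing(specs, coverage = coverages,
                          delivery_type = as.integer(delivery_types))
  grid$result <- purrr::pmap(
    grid,
    function(label, effect_multiplier, effect_override_cm,
             transport_multiplier, coverage, delivery_type) {
      run_scenario(
        children, provinces, ref, effect, costs,
        scenario(coverage = coverage, delivery_type = delivery_type,
                 effect_multiplier = effect_multiplier,
                 effect_override_cm = effect_override_cm,
                 transport_multiplier = transport_multiplier,
                 mode = mode, seed = seed, label = label),
        weight_col = weight_col
      )
    }
  )
  out <- dplyr::bind_cols(
    dplyr::select(grid, "label", "coverage", "delivery_type", "result"),
    purrr::list_rbind(purrr::map(grid$result, function(r) {
      dplyr::select(glance(r), "effect_cm", "averted_total", "averted_poor",
                    "total_cost_rmb", "total_cost_intl", "icer_rmb_per_case")
    }))
  )
  class(out) <- c("yyb_sensitivity", class(out))
  out
}

#' Per-group table of a sensitivity suite
#'
#' @param x A `yyb_sensitivity` tibble from [sensitivity_suite()].
#' @param ... Unused.
#' @return A long tibble: every province x wealth row of every scenario,
#'   tagged with `label`, `coverage`, `delivery_type`.
#' @method tidy yyb_sensitivity
#' @export
tidy.yyb_sensitivity <- function(x, ...) {
  purrr::pmap(
    list(x$label, x$result),
    function(label, result) {
      dplyr::mutate(tidy(result), label = label, .before = 1)
    }
  ) |>
    purrr::list_rbind()
}

#' Plot cost per stunting case averted by province and wealth group
#'
#' Dot plot of the per-group ICER (log scale), provinces ordered by their
#' cheapest group; undefined (zero-averted) groups are dropped from the
#' plot.
#'
#' @param object A `yyb_ecea` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yyb_ecea
#' @export
autoplot.yyb_ecea <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$icer_rmb_per_case))
  ord <- df |>
    dplyr::summarise(best = min(.data$icer_rmb_per_case), .by = "province") |>
    dplyr::arrange(dplyr::desc(.data$best))
  df$province <- factor(df$province, levels = ord$province)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$icer_rmb_per_case, y = .data$province,
    colour = .data$wealth)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10(labels = function(b) format(b, big.mark = ",")) +
    ggplot2::labs(
      x = "Cost per stunting case averted (RMB, log scale)", y = NULL,
      colour = "Wealth group",
      title = sprintf("Delivery Type %d, %.0f%% coverage",
                      object$scenario$delivery_type,
                      object$scenario$coverage * 100)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot total cases averted across sensitivity scenarios
#'
#' @param object A `yyb_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yyb_sensitivity
#' @export
autoplot.yyb_sensitivity <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    setting = sprintf("cov %.0f%% / type %d", .data$coverage * 100,
                      .data$delivery_type))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$averted_total, fill = .data$setting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Stunting cases averted",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
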