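#' Cost-model parameters
#'
#' Per-pack cost components in RMB cents: procurement and manufacturing
#' `m_cents` (35.0), implementation `f_cents` (17.9), advertisement
#' `a_cents` (16.7), village-doctor collection `tv_cents` (0.9, Delivery
#' Type 1 only), and the manufacturer-to-township transport anchors
#' `tm_max_cents`/`tm_min_cents` (13.5 at road density `r_min` = 31 km per
#' 100 km^2, 0.9 at `r_max` = 208). Caregiver time is valued at
#' `gdp_per_capita / hours_per_workyear` per hour over `trips_per_year`
#' monthly round trips, amortised over `packs_per_year` daily packs; the
#' paper-level description of this time cost fixes no unit basis, so the
#' three knobs make the assumption explicit and tunable. `ppp_rmb_per_intl`
#' converts RMB to 2011 international dollars via the 19.4 RMB/day = $5.50/day
#' poverty-line equivalence. `transport_multiplier` scales the entire
#' transport term (the sensitivity-analysis hook).
#'
#' @param m_cents,f_cents,a_cents,tv_cents Fixed components, RMB cents/pack.
#' @param tm_max_cents,tm_min_cents Transport cost at `r_min` / `r_max`.
#' @param r_min,r_max Road-density anchors, km per 100 km^2.
#' @param packs_per_year Packs per child-year (one pack/day).
#' @param trips_per_year Collection round trips per year.
#' @param hours_per_workyear Hours dividing annual GDP into an hourly value.
#' @param ppp_rmb_per_intl RMB per international dollar.
#' @param transport_multiplier Positive scale on the transport term.
#' @return A validated list of class `"cost_params"`.
#' @export
cost_params <- function(m_cents = 35.0, f_cents = 17.9, a_cents = 16.7,
                        tv_cents = 0.9, tm_max_cents = 13.5,
                        tm_min_cents = 0.9, r_min = 31, r_max = 208,
                        packs_per_year = 365, trips_per_year = 12,
                        hours_per_workyear = 2000,
                        ppp_rmb_per_intl = 19.4 / 5.5,
                        transport_multiplier = 1.0) {
  p <- list(m_cents = m_cents, f_cents = f_cents, a_cents = a_cents,
            tv_cents = tv_cents, tm_max_cents = tm_max_cents,
            tm_min_cents = tm_min_cents, r_min = r_min, r_max = r_max,
            packs_per_year = packs_per_year, trips_per_year = trips_per_year,
            hours_per_workyear = hours_per_workyear,
            ppp_rmb_per_intl = ppp_rmb_per_intl,
            transport_multiplier = transport_multiplier)
  problems <- character()
  nonneg <- c("m_cents", "f_cents", "a_cents", "tv_cents", "tm_max_cents",
              "tm_min_cents")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      problems <- c(problems, paste0(nm, " must be >= 0"))
    }
  }
  if (!(p$r_min < p$r_max)) problems <- c(problems, "need r_min < r_max")
  if (!(p$tm_min_cents <= p$tm_max_cents)) {
    problems <- c(problems, "need tm_min_cents <= tm_max_cents")
  }
  if (!(p$ppp_rmb_per_intl > 0)) problems <- c(problems, "ppp factor must be > 0")
  if (!(p$transport_multiplier > 0)) {
    problems <- c(problems, "transport_multiplier must be > 0")
  }
  for (nm in c("packs_per_year", "trips_per_year", "hours_per_workyear")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      problems <- c(problems, paste0(nm, " must be > 0"))
    }
  }
  if (length(problems) > 0) {
    stop("invalid cost_params:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(p, class = "cost_params")
}

#' Manufacturer-to-township transport cost from road density
#'
#' Linear interpolation between the anchor provinces:
#' `TM = 13.5 - (13.5 - 0.9) / (208 - 31) * (R - 31)` RMB cents/pack, so
#' the best-connected province (road density 208) pays 0.9 cents and the
#' least-connected (31) pays 13.5. Densities outside the anchor range are
#' clamped to the anchor costs rather than extrapolated (extrapolation
#' could go negative; the linear form is only supported on the observed
#' range).
#'
#' @param road_density Road density, km per 100 km^2, > 0. Vectorised.
#' @param params A [cost_params()].
#' @return Transport cost, RMB cents/pack.
#' @export
#' @examples
#' tm_from_density(c(31, 119.5, 208))  # 13.5, 7.2, 0.9
tm_from_density <- function(road_density, params = cost_params()) {
  if (any(!is.finite(road_density)) || any(road_density <= 0)) {
    stop("road_density must be finite and > 0", call. = FALSE)
  }
  r <- pmin(pmax(road_density, params$r_min), params$r_max)
  params$tm_max_cents -
    (params$tm_max_cents - params$tm_min_cents) /
    (params$r_max - params$r_min) * (r - params$r_min)
}

#' Caregiver time cost per pack
#'
#' Values caregiver travel time at the provincial hourly GDP per capita
#' (`gdp / hours_per_workyear`), over `trips_per_year` round trips (factor
#' 2 for the return leg), amortised across `packs_per_year` packs:
#' `cents = 100 * trips * 2 * time * (gdp / hours) / packs`.
#'
#' @param travel_time_hours One-way travel time, hours, >= 0. Vectorised.
#' @param gdp_per_capita_yr Provincial GDP per capita, RMB/year, >= 0.
#' @param params A [cost_params()].
#' @return Time cost, RMB cents/pack.
#' @export
#' @examples
#' time_cost_per_pack(0.1, 50000)  # 16.44 cents
time_cost_per_pack <- function(travel_time_hours, gdp_per_capita_yr,
                               params = cost_params()) {
  if (any(!is.finite(travel_time_hours)) || any(travel_time_hours < 0) ||
      any(!is.finite(gdp_per_capita_yr)) || any(gdp_per_capita_yr < 0)) {
    stop("travel time and GDP must be finite and >= 0", call. = FALSE)
  }
  yuan_per_year <- params$trips_per_year * 2 * travel_time_hours *
    gdp_per_capita_yr / params$hours_per_workyear
  100 * yuan_per_year / params$packs_per_year
}

#' Group mean travel times
#'
#' Survey-weighted mean one-way travel times to the village health post and
#' to the nearest town, per province and wealth group. Feeds the per-group
#' caregiver time costs TH (Type 1) and TO (Type 2).
#'
#' @param children Child table with a `wealth` column (see [add_haz()]).
#' @param weight_col Survey-weight column name, or `NULL` for unweighted.
#' @return Tibble `province`, `wealth`, `mean_time_health_post`,
#'   `mean_time_town`.
#' @export
summarise_travel <- function(children, weight_col = "survey_weight") {
  w <- if (is.null(weight_col)) rep(1, nrow(children)) else children[[weight_col]]
  children |>
    dplyr::mutate(.w = w) |>
    dplyr::summarise(
      mean_time_health_post =
        sum(.data$.w * .data$travel_time_health_post) / sum(.data$.w),
      mean_time_town = sum(.data$.w * .data$travel_time_town) / sum(.data$.w),
      .by = c("province", "wealth")
    ) |>
    dplyr::arrange(.data$province, .data$wealth)
}

#' Per-pack cost table by province, wealth group and delivery type
#'
#' Assembles the full per-pack cost `PP = M + F + A + T` for every
#' province x wealth x delivery-type combination, where the transport term
#' is `T = TM + TV + TH` under Delivery Type 1 (village doctors collect
#' from township hospitals, caregivers collect from village health posts)
#' and `T = TM + TO` under Delivery Type 2 (caregivers travel to township
#' hospitals themselves). TH and TO are computed from the group-mean travel
#' times and applied uniformly within the group. `transport_multiplier`
#' scales the whole transport term and leaves M, F, A unchanged.
#'
#' @param provinces Province table with `road_density` and
#'   `gdp_per_capita`.
#' @param travel Group travel-time table from [summarise_travel()].
#' @param params A [cost_params()].
#' @return Tibble with one row per `province` x `wealth` x `delivery_type`,
#'   columns `tm`, `tv`, `th`, `to`, `t_total`, `pp` (all RMB cents/pack,
#'   `pp_intl` in international cents).
#' @export
pack_costs <- function(provinces, travel, params = cost_params()) {
  base <- provinces |>
    dplyr::select("province", "road_density", "gdp_per_capita") |>
    dplyr::inner_join(travel, by = "province") |>
    dplyr::mutate(
      tm = tm_from_density(.data$road_density, params),
      tv = params$tv_cents,
      th = time_cost_per_pack(.data$mean_time_health_post,
                              .data$gdp_per_capita, params),
      to = time_cost_per_pack(.data$mean_time_town,
                              .data$gdp_per_capita, params)
    )
  tidyr::crossing(base, delivery_type = c(1L, 2L)) |>
    dplyr::mutate(
      t_total = params$transport_multiplier * dplyr::if_else(
        .data$delivery_type == 1L,
        .data$tm + .data$tv + .data$th,
        .data$tm + .data$to
      ),
      pp = params$m_cents + params$f_cents + params$a_cents + .data$t_total,
      pp_intl = rmb_to_intl(.data$pp, params)
    ) |>
    dplyr::select("province", "wealth", "delivery_type", "tm", "tv", "th",
                  "to", "t_total", "pp", "pp_intl") |>
    dplyr::arrange(.data$province, .data$wealth, .data$delivery_type)
}

#' Per-pack cost for a single subgroup
#'
#' Scalar counterpart of [pack_costs()] for one province, wealth group and
#' delivery type, given the group-mean one-way travel times.
#'
#' @param road_density Province road density.
#' @param gdp_per_capita Province GDP per capita, RMB/year.
#' @param delivery_type 1 or 2.
#' @param mean_time_health_post,mean_time_town Group-mean one-way travel
#'   times, hours.
#' @param params A [cost_params()].
#' @return One-row tibble as in [pack_costs()] without identifiers.
#' @export
pack_cost <- function(road_density, gdp_per_capita, delivery_type,
                      mean_time_health_post, mean_time_town,
                      params = cost_params()) {
  if (!delivery_type %in% c(1, 2)) {
    stop("delivery_type must be 1 or 2", call. = FALSE)
  }
  tm <- tm_from_density(road_density, params)
  th <- time_cost_per_pack(mean_time_health_post, gdp_per_capita, params)
  to <- time_cost_per_pack(mean_time_town, gdp_per_capita, params)
  t_total <- params$transport_multiplier *
    if (delivery_type == 1) tm + params$tv_cents + th else tm + to
  pp <- params$m_cents + params$f_cents + params$a_cents + t_total
  tibble::tibble(delivery_type = as.integer(delivery_type), tm = tm,
                 tv = params$tv_cents, th = th, to = to, t_total = t_total,
                 pp = pp, pp_intl = rmb_to_intl(pp, params))
}

#' Total programme cost for a subgroup
#'
#' `pp` cents/pack x population x coverage x packs per year, returned in
#' RMB (yuan): a 12-month programme at one pack per day.
#'
#' @param pp_cents Per-pack cost, RMB cents.
#' @param pop Subgroup population.
#' @param coverage Coverage in `[0, 1]`.
#' @param params A [cost_params()].
#' @return Total cost in RMB.
#' @export
#' @examples
#' total_cost(69.6, 1e5, 0.75)  # 19,053,900 RMB
total_cost <- function(pp_cents, pop, coverage, params = cost_params()) {
  if (any(pop < 0)) stop("pop must be >= 0", call. = FALSE)
  if (any(coverage < 0 | coverage > 1)) {
    stop("coverage must be in [0, 1]", call. = FALSE)
  }
  pp_cents / 100 * pop * coverage * params$packs_per_year
}

#' Convert RMB amounts to 2011 international dollars
#'
#' Uses the poverty-line equivalence 19.4 RMB/day = $5.50/day (2011 PPP),
#' i.e. divides by `ppp_rmb_per_intl`. Presentation rounding (1 decimal for
#' cents) is left to the caller.
#'
#' @param amount_rmb Amount in RMB (any unit; cents in, cents out).
#' @param params A [cost_params()].
#' @return Amount in international dollars (same unit).
#' @export
#' @examples
#' round(rmb_to_intl(35.0), 1)  # 9.9
#' rmb_to_intl(19.4)            # 5.5
rmb_to_intl <- function(amount_rmb, params = cost_params()) {
  amount_rmb / params$ppp_rmb_per_intl
}

#' Convert international dollars back to RMB
#'
#' Inverse of [rmb_to_intl()].
#'
#' @param amount_intl Amount in international dollars.
#' @param params A [cost_params()].
#' @return Amount in RMB.
#' @export
intl_to_rmb <- function(amount_intl, params = cost_params()) {
  amount_intl * params$ppp_rmb_per_intl
}
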