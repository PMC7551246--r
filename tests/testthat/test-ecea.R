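ref <- toy_ref()

# two-province fixture: poor children concentrated just below -2
fixture_children <- function() {
  dplyr::bind_rows(
    make_children(c(-2.4, -2.2, -2.1, -1.5, -0.5), income = 5, province = "P01"),
    make_children(c(-1.9, -1.2, -0.3, 0.2, 1.0), income = 40, province = "P01"),
    make_children(c(-2.3, -2.1, -1.8, -1.0, 0.0), income = 5, province = "P02"),
    make_children(c(-2.5, -0.8, -0.2, 0.5, 1.2), income = 40, province = "P02")
  )
}
fixture_provinces <- function() make_provinces(c("P01", "P02"))

test_that("a zero-effect scenario averts nothing and yields NA ICERs", {
  res <- run_scenario(fixture_children(), fixture_provinces(), ref,
                      scen = scenario(coverage = 0.75, effect_multiplier = 0))
  g <- tidy(res)
  expect_equal(g$averted, rep(0, 4))
  expect_true(all(is.na(g$icer_rmb_per_case)))
  expect_true(all(g$total_cost_rmb > 0))  # costs accrue even with no benefit
})

test_that("ICER is total cost over cases averted, group by group", {
  res <- run_scenario(fixture_children(), fixture_provinces(), ref,
                      scen = scenario(coverage = 0.75, delivery_type = 1))
  g <- tidy(res)
  defined <- !is.na(g$icer_rmb_per_case)
  expect_true(any(defined))
  expect_equal(g$icer_rmb_per_case[defined] * g$averted[defined],
               g$total_cost_rmb[defined])
  # the worked ratio: cost 4e7 over 4e4 averted is 1000 RMB/case
  expect_equal(4e7 / 4e4, 1000)
  expect_equal(g$icer_intl_per_case, rmb_to_intl(g$icer_rmb_per_case))
})

test_that("national totals add up over subgroups", {
  res <- run_scenario(fixture_children(), fixture_provinces(), ref,
                      scen = scenario(coverage = 0.25, delivery_type = 2))
  g <- tidy(res)
  nat <- res$national
  for (wg in c("poor", "nonpoor")) {
    expect_equal(nat$averted[nat$wealth == wg],
                 sum(g$averted[g$wealth == wg], na.rm = TRUE))
    expect_equal(nat$total_cost_rmb[nat$wealth == wg],
                 sum(g$total_cost_rmb[g$wealth == wg], na.rm = TRUE))
  }
  expect_equal(glance(res)$averted_total, sum(g$averted, na.rm = TRUE))
})

test_that("raising transport costs strictly raises every defined ICER", {
  base <- run_scenario(fixture_children(), fixture_provinces(), ref,
                       scen = scenario(coverage = 0.75))
  dbl <- run_scenario(fixture_children(), fixture_provinces(), ref,
                      scen = scenario(coverage = 0.75,
                                      transport_multiplier = 2))
  b <- tidy(base)$icer_rmb_per_case
  d <- tidy(dbl)$icer_rmb_per_case
  ok <- !is.na(b)
  expect_true(all(d[ok] > b[ok]))
})

test_that("children without a province profile are rejected", {
  orphan <- make_children(-1, province = "P99")
  expect_error(
    run_scenario(orphan, fixture_provinces(), ref,
                 scen = scenario(coverage = 0.25)),
    "P99")
})

test_that("scenario validation enforces the effect override exclusivity", {
  expect_error(scenario(coverage = 0.25, effect_multiplier = 0.5,
                        effect_override_cm = 0.96), "not both")
  expect_error(scenario(coverage = 1.5), "coverage")
  expect_error(scenario(coverage = 0.5, delivery_type = 3), "delivery_type")
})

test_that("the sensitivity suite runs the labelled grid with correct settings", {
  suite <- sensitivity_suite(fixture_children(), fixture_provinces(), ref,
                             coverages = c(0.25, 0.75),
                             delivery_types = c(1L, 2L))
  expect_equal(nrow(suite), 5 * 2 * 2)
  expect_setequal(unique(suite$label),
                  c("base", "eff_halved", "eff_ci_lower", "transport_halved",
                    "transport_doubled"))
  expect_equal(unique(suite$effect_cm[suite$label == "eff_ci_lower"]), 0.96)
  expect_equal(unique(suite$effect_cm[suite$label == "eff_halved"]), 1.23)

  for (cov in c(0.25, 0.75)) {
    for (dt in 1:2) {
      pick <- function(lbl) {
        suite$result[[which(suite$label == lbl & suite$coverage == cov &
                              suite$delivery_type == dt)]]
      }
      b <- tidy(pick("base"))
      # halved effect cannot decrease any defined ICER (costs unchanged)
      h <- tidy(pick("eff_halved"))
      ok <- !is.na(b$icer_rmb_per_case) & !is.na(h$icer_rmb_per_case)
      expect_true(all(h$icer_rmb_per_case[ok] >= b$icer_rmb_per_case[ok]))
      # transport scaling strictly orders total costs while transport > 0
      lo <- tidy(pick("transport_halved"))
      hi <- tidy(pick("transport_doubled"))
      expect_true(all(lo$total_cost_rmb < b$total_cost_rmb))
      expect_true(all(b$total_cost_rmb < hi$total_cost_rmb))
      # benefits are untouched by transport scaling
      expect_equal(lo$averted, b$averted)
    }
  }
})

test_that("groups are ranked ascending by ICER with NA last and stable ties", {
  g <- tibble::tibble(
    province = c("P02", "P01", "P03", "P01"),
    wealth = c("poor", "poor", "poor", "nonpoor"),
    icer_rmb_per_case = c(23300, 800, NA, 800)
  )
  r <- rank_groups(g)
  expect_equal(r$icer_rmb_per_case[1], 800)
  # tie at 800 broken by province then wealth label
  expect_equal(r$province[1:2], c("P01", "P01"))
  expect_equal(r$wealth[1:2], c("nonpoor", "poor"))
  expect_true(is.na(r$icer_rmb_per_case[4]))
  expect_equal(r$rank, c(1L, 2L, 3L, NA))
  all_na <- dplyr::mutate(g, icer_rmb_per_case = NA_real_)
  expect_true(all(is.na(rank_groups(all_na)$rank)))
})

test_that("pro-poor cost-effectiveness emerges on the calibrated generator", {
  cfg <- sim_config()  # defaults: poor mean HAZ below non-poor
  prov <- simulate_provinces(cfg, seed = 8)
  kids <- simulate_children(cfg, prov, seed = 8)
  res <- run_scenario(kids, prov,
                      scen = scenario(coverage = 0.25, delivery_type = 1))
  wide <- tidy(res) |>
    dplyr::select("province", "wealth", "icer_rmb_per_case") |>
    tidyr::pivot_wider(names_from = "wealth", values_from = "icer_rmb_per_case")
  both <- !is.na(wide$poor) & !is.na(wide$nonpoor)
  expect_gt(sum(wide$poor[both] < wide$nonpoor[both]), sum(both) / 2)
})

test_that("bernoulli-mode scenarios are reproducible from the scenario seed", {
  scen <- scenario(coverage = 0.5, mode = "bernoulli", seed = 42)
  a <- run_scenario(fixture_children(), fixture_provinces(), ref, scen = scen)
  b <- run_scenario(fixture_children(), fixture_provinces(), ref, scen = scen)
  expect_identical(tidy(a), tidy(b))
})

test_that("autoplot returns ggplot objects for results and suites", {
  res <- run_scenario(fixture_children(), fixture_provinces(), ref,
                      scen = scenario(coverage = 0.75))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  suite <- sensitivity_suite(fixture_children(), fixture_provinces(), ref,
                             coverages = 0.25, delivery_types = 1L)
  expect_s3_class(ggplot2::autoplot(suite), "ggplot")
  expect_equal(nrow(tidy(suite)), 5 * 4)
})
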