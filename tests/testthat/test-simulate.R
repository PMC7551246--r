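test_that("province generation is deterministic and respects ranges", {
  cfg <- sim_config(n_provinces = 25, road_density_range = c(31, 208))
  a <- simulate_provinces(cfg, seed = 1)
  b <- simulate_provinces(cfg, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 25)
  expect_true(all(a$road_density >= 31 & a$road_density <= 208))
  expect_true(all(a$gdp_per_capita >= 28000 & a$gdp_per_capita <= 95000))
  # two provinces from the same draw differ
  two <- simulate_provinces(sim_config(n_provinces = 2), seed = 1)
  expect_false(two$road_density[1] == two$road_density[2])
  # different seeds give different tables
  expect_false(identical(a, simulate_provinces(cfg, seed = 2)))
})

test_that("invalid generator configurations are rejected with field names", {
  expect_error(sim_config(road_density_range = c(208, 31)), "road_density_range")
  expect_error(sim_config(poverty_fraction = 1.5), "poverty_fraction")
  expect_error(sim_config(n_provinces = 0), "n_provinces")
  expect_error(sim_config(haz_sd = -1), "haz_sd")
})

test_that("children generation is seed-deterministic and structurally valid", {
  cfg <- small_sim()
  prov <- simulate_provinces(cfg, seed = 5)
  a <- simulate_children(cfg, prov, seed = 5)
  expect_identical(a, simulate_children(cfg, prov, seed = 5))
  expect_false(identical(a, simulate_children(cfg, prov, seed = 6)))
  expect_equal(nrow(a), 4 * 250)
  expect_true(all(a$age_months >= 6 & a$age_months <= 36))
  expect_true(all(a$height_cm > 40 & a$height_cm < 120))
  expect_true(all(a$income_per_capita >= 0))
})

test_that("degenerate HAZ variance puts every child exactly at the mean", {
  cfg <- sim_config(n_provinces = 1, children_per_province = 50,
                    haz_sd = 0, haz_mean_poor = -2, haz_mean_nonpoor = -2,
                    haz_mean_province_sd = 0)
  prov <- simulate_provinces(cfg, seed = 1)
  # reference with exactly representable medians/SDs so the height -> HAZ
  # round trip is exact at the threshold
  ref <- toy_ref(median_cm = 75, sd_cm = 2.5)
  kids <- add_haz(simulate_children(cfg, prov, ref = ref, seed = 1), ref = ref)
  expect_equal(kids$haz, rep(-2, 50))
  # HAZ exactly -2 is not stunted under the strict rule
  expect_false(any(kids$stunted))
})

test_that("poverty_fraction = 1 classifies every child as poor by income", {
  cfg <- sim_config(n_provinces = 2, children_per_province = 100,
                    poverty_fraction = 1)
  prov <- simulate_provinces(cfg, seed = 2)
  kids <- simulate_children(cfg, prov, seed = 2)
  expect_true(all(classify_wealth(kids$income_per_capita) == "poor"))
})

test_that("simulated HAZ reproduces the standard-normal stunting mass", {
  n <- 10000
  cfg <- sim_config(n_provinces = 1, children_per_province = n,
                    haz_mean_poor = 0, haz_mean_nonpoor = 0, haz_sd = 1,
                    haz_mean_province_sd = 0)
  prov <- simulate_provinces(cfg, seed = 11)
  kids <- add_haz(simulate_children(cfg, prov, seed = 11))
  p <- pnorm(-2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(kids$stunted) - p), 3 * se)
})

test_that("empirical HAZ moments and poverty share converge to configuration", {
  n <- 5000
  cfg <- sim_config(n_provinces = 1, children_per_province = n,
                    haz_mean_poor = -1.4, haz_mean_nonpoor = -0.5,
                    haz_sd = 1.1, haz_mean_province_sd = 0,
                    poverty_fraction = 0.4, poverty_fraction_province_sd = 0)
  prov <- simulate_provinces(cfg, seed = 21)
  kids <- add_haz(simulate_children(cfg, prov, seed = 21))
  tol <- 4 / sqrt(n)
  by_group <- kids |>
    dplyr::summarise(m = mean(.data$haz), s = sd(.data$haz), n = dplyr::n(),
                     .by = "wealth")
  poor <- by_group[by_group$wealth == "poor", ]
  nonpoor <- by_group[by_group$wealth == "nonpoor", ]
  expect_lt(abs(poor$m - (-1.4)), 4 / sqrt(poor$n))
  expect_lt(abs(nonpoor$m - (-0.5)), 4 / sqrt(nonpoor$n))
  expect_lt(abs(poor$s - 1.1), 4 / sqrt(poor$n))
  expect_lt(abs(mean(kids$wealth == "poor") - 0.4), tol)
})

test_that("microdata round-trips through CSV unchanged", {
  cfg <- small_sim()
  prov <- simulate_provinces(cfg, seed = 9)
  kids <- simulate_children(cfg, prov, seed = 9)
  dir <- withr::local_tempdir()
  write_microdata(kids, prov, dir)
  kids2 <- read_children(file.path(dir, "children.csv"))
  prov2 <- read_provinces(file.path(dir, "provinces.csv"))
  expect_equal(as.data.frame(kids2), as.data.frame(kids))
  expect_equal(as.data.frame(prov2), as.data.frame(prov))
})

test_that("explicit haz_means overrides replace generated group means", {
  ov <- tibble::tibble(province = "P01", wealth = "poor", haz_mean = -3)
  cfg <- sim_config(n_provinces = 2, children_per_province = 10,
                    haz_means = ov)
  prov <- simulate_provinces(cfg, seed = 4)
  expect_equal(prov$haz_mean_poor[prov$province == "P01"], -3)
  expect_false(prov$haz_mean_poor[prov$province == "P02"] == -3)
})
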