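#' Configuration for the synthetic microdata generator
#'
#' Builds and validates the parameter set for [simulate_provinces()] and
#' [simulate_children()]. The generator emulates the structure of a
#' CFPS-like rural household survey: per-child anthropometry whose HAZ
#' distribution differs by province and poverty status, household income
#' per capita relative to the 19.4 RMB/day poverty line, and one-way travel
#' times to the village health post and to the nearest town.
#'
#' Defaults are the study conditions: 25 provinces with roughly 640
#' surveyed children each (about 16,000 households over 25 provinces), road
#' densities spanning 31-208 km per 100 km^2, GDP per capita spanning
#' roughly 28,000-95,000 RMB/year, and HAZ means of -1.2 (poor) and
#' -0.6 (non-poor) with SD 1.1 and a 0.35 SD spread of province-level
#' offsets, which yields subgroup stunting prevalences ranging from near
#' zero up to roughly a quarter.
#'
#' @param n_provinces Number of provinces (>= 1).
#' @param children_per_province Children sampled per province (>= 1).
#' @param poverty_fraction National fraction of children below the poverty
#'   line, in `[0, 1]`.
#' @param poverty_fraction_province_sd SD of province-level logit jitter
#'   around `poverty_fraction` (0 disables jitter; the boundary values 0
#'   and 1 are preserved exactly).
#' @param haz_mean_poor,haz_mean_nonpoor National mean HAZ by wealth group.
#' @param haz_mean_province_sd SD of the province-level offset added to both
#'   group means.
#' @param haz_sd Within-group HAZ standard deviation (> 0).
#' @param haz_means Optional tibble `(province, wealth, haz_mean)` that
#'   overrides the generated means for the listed groups.
#' @param income_sdlog Log-scale SD of the log-normal income distribution.
#' @param poverty_line_rmb_day Poverty line, RMB/day.
#' @param travel_health_post_meanlog,travel_health_post_sdlog Log-normal
#'   parameters for one-way travel time (hours) to the village health post.
#' @param travel_town_meanlog,travel_town_sdlog Log-normal parameters for
#'   one-way travel time (hours) to the nearest town.
#' @param road_density_range `c(min, max)` road density, km per 100 km^2;
#'   must lie within the transport-cost interpolation domain `[31, 208]`.
#' @param gdp_range `c(min, max)` GDP per capita, RMB/year.
#' @param pop_range `c(min, max)` province population aged 6-36 months.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_provinces = 25,
                       children_per_province = 640,
                       poverty_fraction = 0.4,
                       poverty_fraction_province_sd = 0.5,
                       haz_mean_poor = -1.2,
                       haz_mean_nonpoor = -0.6,
                       haz_mean_province_sd = 0.35,
                       haz_sd = 1.1,
                       haz_means = NULL,
                       income_sdlog = 0.8,
                       poverty_line_rmb_day = 19.4,
                       travel_health_post_meanlog = log(0.1),
                       travel_health_post_sdlog = 0.5,
                       travel_town_meanlog = log(0.5),
                       travel_town_sdlog = 0.5,
                       road_density_range = c(31, 208),
                       gdp_range = c(28000, 95000),
                       pop_range = c(1e5, 1e6)) {
  cfg <- list(
    n_provinces = as.integer(n_provinces),
    children_per_province = as.integer(children_per_province),
    poverty_fraction = poverty_fraction,
    poverty_fraction_province_sd = poverty_fraction_province_sd,
    haz_mean_poor = haz_mean_poor,
    haz_mean_nonpoor = haz_mean_nonpoor,
    haz_mean_province_sd = haz_mean_province_sd,
    haz_sd = haz_sd,
    haz_means = haz_means,
    income_sdlog = income_sdlog,
    poverty_line_rmb_day = poverty_line_rmb_day,
    travel_health_post_meanlog = travel_health_post_meanlog,
    travel_health_post_sdlog = travel_health_post_sdlog,
    travel_town_meanlog = travel_town_meanlog,
    travel_town_sdlog = travel_town_sdlog,
    road_density_range = road_density_range,
    gdp_range = gdp_range,
    pop_range = pop_range
  )
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_provinces >= 1, "n_provinces must be >= 1")
  chk(cfg$children_per_province >= 1, "children_per_province must be >= 1")
  chk(is.numeric(poverty_fraction) && poverty_fraction >= 0 &&
        poverty_fraction <= 1, "poverty_fraction must be in [0, 1]")
  chk(poverty_fraction_province_sd >= 0,
      "poverty_fraction_province_sd must be >= 0")
  chk(haz_sd >= 0, "haz_sd must be >= 0")
  chk(haz_mean_province_sd >= 0, "haz_mean_province_sd must be >= 0")
  chk(income_sdlog > 0, "income_sdlog must be > 0")
  chk(poverty_line_rmb_day > 0, "poverty_line_rmb_day must be > 0")
  for (nm in c("road_density_range", "gdp_range", "pop_range")) {
    r <- cfg[[nm]]
    chk(length(r) == 2 && all(is.finite(r)) && r[1] <= r[2],
        paste0(nm, " must be c(min, max) with min <= max"))
  }
  if (length(cfg$road_density_range) == 2 &&
      all(is.finite(cfg$road_density_range))) {
    chk(cfg$road_density_range[1] >= 31 && cfg$road_density_range[2] <= 208,
        "road_density_range must lie within the interpolation domain [31, 208]")
  }
  if (!is.null(haz_means)) {
    chk(all(c("province", "wealth", "haz_mean") %in% names(haz_means)),
        "haz_means needs columns province, wealth, haz_mean")
  }
  if (length(problems) > 0) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate synthetic province profiles
#'
#' One row per province: road density (the transport-cost driver), GDP per
#' capita (the caregiver time-cost driver), the population aged 6-36
#' months split by wealth group, and the province-level parameters
#' (poverty fraction, group HAZ means) that [simulate_children()] uses so
#' that the synthetic world is fully inspectable from its tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed always reproduces the same table.
#' @return Tibble with columns `province`, `road_density`, `gdp_per_capita`,
#'   `pop_6_36m_poor`, `pop_6_36m_nonpoor`, `poverty_fraction`,
#'   `haz_mean_poor`, `haz_mean_nonpoor`.
#' @export
simulate_provinces <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    n <- config$n_provinces
    province <- sprintf("P%02d", seq_len(n))
    road_density <- stats::runif(n, config$road_density_range[1],
                                 config$road_density_range[2])
    gdp <- stats::runif(n, config$gdp_range[1], config$gdp_range[2])
    pop <- round(stats::runif(n, config$pop_range[1], config$pop_range[2]))
    # logit-scale jitter keeps poverty_fraction = 0 and 1 exact
    pf <- stats::plogis(stats::qlogis(config$poverty_fraction) +
                          stats::rnorm(n, 0, config$poverty_fraction_province_sd))
    pf[config$poverty_fraction %in% c(0, 1)] <- config$poverty_fraction
    offset <- stats::rnorm(n, 0, config$haz_mean_province_sd)
    out <- tibble::tibble(
      province = province,
      road_density = road_density,
      gdp_per_capita = gdp,
      pop_6_36m_poor = round(pop * pf),
      pop_6_36m_nonpoor = pop - round(pop * pf),
      poverty_fraction = pf,
      haz_mean_poor = config$haz_mean_poor + offset,
      haz_mean_nonpoor = config$haz_mean_nonpoor + offset
    )
    if (!is.null(config$haz_means)) {
      ov <- tidyr::pivot_wider(
        config$haz_means,
        names_from = "wealth", values_from = "haz_mean",
        names_prefix = "ov_"
      )
      out <- dplyr::left_join(out, ov, by = "province")
      if ("ov_poor" %in% names(out)) {
        out$haz_mean_poor <- dplyr::coalesce(out$ov_poor, out$haz_mean_poor)
      }
      if ("ov_nonpoor" %in% names(out)) {
        out$haz_mean_nonpoor <-
          dplyr::coalesce(out$ov_nonpoor, out$haz_mean_nonpoor)
      }
      out <- dplyr::select(out, -dplyr::starts_with("ov_"))
    }
    out
  })
}

# inverse-CDF draw from a log-normal truncated to one side of `line`
rlnorm_truncated <- function(n, meanlog, sdlog, line, below) {
  p_line <- stats::plnorm(line, meanlog, sdlog)
  u <- if (below) stats::runif(n, 0, p_line) else stats::runif(n, p_line, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate synthetic child microdata
#'
#' For each province, draws `children_per_province` children: wealth group
#' (Bernoulli at the province's poverty fraction), age uniform over 6-36
#' months, sex, HAZ from `Normal(haz_mean[province, wealth], haz_sd)`
#' truncated to +/- 6 SD, height by inverting the growth reference
#' (`height = median + HAZ * sd`), income from a log-normal calibrated so
#' the below-line mass equals the province poverty fraction and truncated
#' to the drawn group's side of the line (so income-based classification
#' reproduces the group exactly), and log-normal one-way travel times.
#' Survey weights default to 1.
#'
#' @param config A [sim_config()].
#' @param provinces Province table from [simulate_provinces()].
#' @param ref Growth reference used to convert HAZ to height.
#' @param seed Integer seed; same seed, same table.
#' @return Tibble with one row per child: `child_id`, `province`,
#'   `age_months`, `sex`, `height_cm`, `income_per_capita`,
#'   `travel_time_health_post`, `travel_time_town`, `survey_weight`.
#' @export
simulate_children <- function(config = sim_config(),
                              provinces = simulate_provinces(config),
                              ref = load_growth_reference(),
                              seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(provinces) == 0) stop("provinces must be nonempty", call. = FALSE)
  needed <- c("province", "poverty_fraction", "haz_mean_poor",
              "haz_mean_nonpoor")
  if (!all(needed %in% names(provinces))) {
    stop("provinces table lacks generator columns: ",
         paste(setdiff(needed, names(provinces)), collapse = ", "),
         call. = FALSE)
  }
  line <- config$poverty_line_rmb_day
  withr::with_seed(seed, {
    purrr::pmap(
      provinces[needed],
      function(province, poverty_fraction, haz_mean_poor, haz_mean_nonpoor) {
        n <- config$children_per_province
        poor <- stats::runif(n) < poverty_fraction
        age <- sample(6:36, n, replace = TRUE)
        sex <- sample(c("male", "female"), n, replace = TRUE)
        mu <- ifelse(poor, haz_mean_poor, haz_mean_nonpoor)
        haz <- pmin(pmax(stats::rnorm(n, mu, config$haz_sd), -6), 6)
        idx <- match(paste(sex, age), paste(ref$sex, ref$age_months))
        if (anyNA(idx)) {
          stop("growth reference does not cover ages 6-36 for both sexes",
               call. = FALSE)
        }
        height <- ref$median_cm[idx] + haz * ref$sd_cm[idx]
        # meanlog calibrated so the *unconditional* below-line mass is the
        # poverty fraction; the draw is then truncated to the child's group
        pf_int <- min(max(poverty_fraction, 1e-6), 1 - 1e-6)
        meanlog <- log(line) - config$income_sdlog * stats::qnorm(pf_int)
        income <- numeric(n)
        if (any(poor)) {
          income[poor] <- rlnorm_truncated(sum(poor), meanlog,
                                           config$income_sdlog, line, TRUE)
        }
        if (any(!poor)) {
          income[!poor] <- rlnorm_truncated(sum(!poor), meanlog,
                                            config$income_sdlog, line, FALSE)
        }
        tibble::tibble(
          child_id = sprintf("%s-C%04d", province, seq_len(n)),
          province = province,
          age_months = as.integer(age),
          sex = sex,
          height_cm = height,
          income_per_capita = income,
          travel_time_health_post = stats::rlnorm(
            n, config$travel_health_post_meanlog,
            config$travel_health_post_sdlog),
          travel_time_town = stats::rlnorm(
            n, config$travel_town_meanlog, config$travel_town_sdlog),
          survey_weight = 1
        )
      }
    ) |>
      purrr::list_rbind()
  })
}

#' Write synthetic microdata to CSV
#'
#' Writes `children.csv` and `provinces.csv` (UTF-8, header row, "." decimal
#' separator) into `dir`. Round-tripping through [read_children()] /
#' [read_provinces()] reproduces the tables.
#'
#' @param children Child table from [simulate_children()].
#' @param provinces Province table from [simulate_provinces()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_microdata <- function(children, provinces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(children = file.path(dir, "children.csv"),
             provinces = file.path(dir, "provinces.csv"))
  readr::write_csv(children, paths[["children"]])
  readr::write_csv(provinces, paths[["provinces"]])
  invisible(paths)
}
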