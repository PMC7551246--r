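# shared in-code fixtures: a flat toy growth reference and builders for
# small deterministic child/province tables

toy_ref <- function(median_cm = 75, sd_cm = 2.5) {
  tidyr::crossing(sex = c("female", "male"), age_months = 6:36) |>
    dplyr::mutate(median_cm = median_cm, sd_cm = sd_cm)
}

# children at exactly the given HAZ values (against toy_ref)
make_children <- function(haz, province = "P01", income = 10,
                          sd_cm = 2.5, median_cm = 75,
                          t_health = 0.1, t_town = 0.5) {
  n <- length(haz)
  tibble::tibble(
    child_id = sprintf("%s-C%04d", province, seq_len(n)),
    province = province,
    age_months = 12L,
    sex = "male",
    height_cm = median_cm + haz * sd_cm,
    income_per_capita = rep_len(income, n),
    travel_time_health_post = rep_len(t_health, n),
    travel_time_town = rep_len(t_town, n),
    survey_weight = 1
  )
}

make_provinces <- function(province = "P01", road_density = 100,
                           gdp = 50000, pop_poor = 5e5, pop_nonpoor = 5e5) {
  tibble::tibble(
    province = province,
    road_density = rep_len(road_density, length(province)),
    gdp_per_capita = rep_len(gdp, length(province)),
    pop_6_36m_poor = rep_len(pop_poor, length(province)),
    pop_6_36m_nonpoor = rep_len(pop_nonpoor, length(province))
  )
}

# small fast generator settings used across tests
small_sim <- function(...) {
  sim_config(n_provinces = 4, children_per_province = 250, ...)
}
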