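#' Read child microdata from CSV
#'
#' Validated reader for the child table. Required columns: `child_id`,
#' `province`, `age_months`, `sex`, `height_cm`, `income_per_capita`,
#' `travel_time_health_post`, `travel_time_town`, `survey_weight`. All
#' invariant violations are reported together, not just the first.
#'
#' @param path CSV path.
#' @return A tibble of child records.
#' @export
read_children <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(),
    province = readr::col_character(),
    age_months = readr::col_integer(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ))
  problems <- character()
  needed <- c("child_id", "province", "age_months", "sex", "height_cm",
              "income_per_capita", "travel_time_health_post",
              "travel_time_town", "survey_weight")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("children table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$age_months < 6 | df$age_months > 36)) {
    problems <- c(problems, "age_months outside [6, 36]")
  }
  if (!all(df$sex %in% c("male", "female"))) {
    problems <- c(problems, "sex must be 'male' or 'female'")
  }
  if (any(df$height_cm <= 0 | df$height_cm < 40 | df$height_cm > 120)) {
    problems <- c(problems, "height_cm outside plausibility window [40, 120]")
  }
  if (any(df$income_per_capita < 0)) {
    problems <- c(problems, "income_per_capita must be >= 0")
  }
  if (any(df$travel_time_health_post < 0) || any(df$travel_time_town < 0)) {
    problems <- c(problems, "travel times must be >= 0")
  }
  if (any(df$survey_weight <= 0)) {
    problems <- c(problems, "survey_weight must be > 0")
  }
  if (length(problems) > 0) {
    stop("invalid children table '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  df
}

#' Read province profiles from CSV
#'
#' Validated reader for the province table. Required columns: `province`,
#' `road_density`, `gdp_per_capita`, `pop_6_36m_poor`, `pop_6_36m_nonpoor`;
#' generator-side columns (poverty fraction, group HAZ means) are carried
#' through when present.
#'
#' @param path CSV path.
#' @return A tibble of province profiles.
#' @export
read_provinces <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    province = readr::col_character(),
    .default = readr::col_double()
  ))
  needed <- c("province", "road_density", "gdp_per_capita",
              "pop_6_36m_poor", "pop_6_36m_nonpoor")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("provinces table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  problems <- character()
  if (any(df$road_density <= 0)) {
    problems <- c(problems, "road_density must be > 0")
  }
  if (any(df$pop_6_36m_poor < 0) || any(df$pop_6_36m_nonpoor < 0)) {
    problems <- c(problems, "populations must be >= 0")
  }
  if (anyDuplicated(df$province) > 0) {
    problems <- c(problems, "duplicated province identifiers")
  }
  if (length(problems) > 0) {
    stop("invalid provinces table '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  df
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (chosen by file extension) with
#' optional top-level blocks `effect`, `costs`, `simulate` and a
#' `scenarios` list whose entries mirror the [scenario()] arguments. Every
#' invariant violation across all blocks is collected and reported in one
#' error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `effect` ([effect_params()]), `costs`
#'   ([cost_params()]), `sim` ([sim_config()] or `NULL`), and `scenarios`
#'   (list of [scenario()]).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  problems <- character()
  build <- function(ctor, args, block) {
    tryCatch(do.call(ctor, args %||% list()),
             error = function(e) {
               problems <<- c(problems, paste0(block, ": ", conditionMessage(e)))
               NULL
             })
  }
  effect <- build(effect_params, raw$effect, "effect")
  costs <- build(cost_params, raw$costs, "costs")
  sim <- if (!is.null(raw$simulate)) build(sim_config, raw$simulate, "simulate")
  scenarios <- purrr::imap(raw$scenarios %||% list(), function(s, i) {
    build(scenario, s, paste0("scenarios[", i, "]"))
  })
  if (length(problems) > 0) {
    stop("invalid configuration '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  list(effect = effect, costs = costs, sim = sim, scenarios = scenarios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write scenario result tables
#'
#' Writes `results_<label>.csv` (per-group table shaped province x wealth,
#' stable sort, `NA` cells rendered literally as `NA`) and
#' `national_<label>.csv` for each result, plus a short human-readable
#' `summary_<label>.txt` with rounded headline numbers. Machine CSVs are
#' unrounded; re-running with the same inputs and seed reproduces the
#' files byte for byte.
#'
#' @param result A `yyb_ecea` object, or a named list of them (names become
#'   labels).
#' @param out_dir Output directory (created if needed).
#' @param label Label for a single result (default `"base"`).
#' @return Invisibly, the paths written.
#' @export
write_result_tables <- function(result, out_dir, label = "base") {
  if (inherits(result, "yyb_ecea")) {
    result <- stats::setNames(list(result),
                              result$scenario$label %||% label)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(result)) {
    res <- result[[nm]]
    groups <- dplyr::arrange(tidy(res), .data$province, .data$wealth)
    gp <- file.path(out_dir, paste0("results_", nm, ".csv"))
    np <- file.path(out_dir, paste0("national_", nm, ".csv"))
    sp <- file.path(out_dir, paste0("summary_", nm, ".txt"))
    readr::write_csv(groups, gp, na = "NA")
    readr::write_csv(res$national, np, na = "NA")
    g <- glance(res)
    writeLines(c(
      sprintf("Scenario %s: coverage %.0f%%, Delivery Type %d, effect %.2f cm",
              nm, g$coverage * 100, g$delivery_type, g$effect_cm),
      sprintf("Stunting cases averted: %s (poor: %s)",
              format(round(g$averted_total), big.mark = ","),
              format(round(g$averted_poor), big.mark = ",")),
      sprintf("Total cost: %s RMB (%s intl $)",
              format(round(g$total_cost_rmb), big.mark = ","),
              format(round(g$total_cost_intl), big.mark = ",")),
      sprintf("National average cost per case averted: %s RMB",
              format(round(g$icer_rmb_per_case), big.mark = ","))
    ), sp)
    paths <- c(paths, gp, np, sp)
  }
  invisible(paths)
}
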