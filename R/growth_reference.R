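#' Load and validate a growth reference table
#'
#' A growth reference maps (sex, age in months) to the reference median
#' height and standard deviation used for height-for-age Z-score (HAZ)
#' standardisation. The expected CSV columns are `sex` (`"male"`/`"female"`),
#' `age_months`, `median_cm` and `sd_cm`.
#'
#' The bundled file `growth_reference_synthetic.csv` is a *synthetic*
#' simplified reference: smooth monotone median curves through WHO-like
#' anchor heights with a linearly widening SD. It covers every month from
#' 6 to 36 for both sexes, which is all the pipeline requires. A real WHO
#' median/SD table in the same format can be substituted.
#'
#' @param path Path to a reference CSV. Defaults to the bundled synthetic
#'   reference.
#' @return A tibble with columns `sex`, `age_months`, `median_cm`, `sd_cm`.
#' @export
#' @examples
#' ref <- load_growth_reference()
#' head(ref)
load_growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "growth_reference_synthetic.csv",
                        package = "yybecea", mustWork = TRUE)
  }
  ref <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      age_months = readr::col_integer(),
      median_cm = readr::col_double(),
      sd_cm = readr::col_double()
    )
  )
  validate_growth_reference(ref)
  ref
}

#' Validate a growth reference tibble
#'
#' Checks the invariants required for HAZ standardisation: both sexes cover
#' every age month in 6-36, all SDs are positive, and medians are
#' non-decreasing in age within sex. Called automatically by
#' [load_growth_reference()]; exported so externally built tables can be
#' checked before use.
#'
#' @param ref A data frame with columns `sex`, `age_months`, `median_cm`,
#'   `sd_cm`.
#' @return `ref`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_growth_reference <- function(ref) {
  problems <- character()
  needed <- c("sex", "age_months", "median_cm", "sd_cm")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols) > 0) {
    stop("growth reference is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (s in c("male", "female")) {
    sub <- dplyr::arrange(dplyr::filter(ref, .data$sex == s), .data$age_months)
    absent <- setdiff(6:36, sub$age_months)
    if (length(absent) > 0) {
      problems <- c(problems, paste0(
        "sex '", s, "' missing age months: ", paste(absent, collapse = ", ")))
    }
    if (nrow(sub) > 1 && is.unsorted(sub$median_cm)) {
      problems <- c(problems, paste0(
        "sex '", s, "': median_cm not non-decreasing in age"))
    }
  }
  if (any(!is.finite(ref$sd_cm)) || any(ref$sd_cm <= 0)) {
    problems <- c(problems, "sd_cm must be finite and > 0 everywhere")
  }
  if (any(!is.finite(ref$median_cm)) || any(ref$median_cm <= 0)) {
    problems <- c(problems, "median_cm must be finite and > 0 everywhere")
  }
  if (anyDuplicated(ref[c("sex", "age_months")]) > 0) {
    problems <- c(problems, "duplicated (sex, age_months) entries")
  }
  if (length(problems) > 0) {
    stop("invalid growth reference:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(ref)
}
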