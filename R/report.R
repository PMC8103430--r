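metric_titles <- function() {
  c(total_hours = "Total hours spent playing",
    outdoor_hours = "Hours spent playing outdoors",
    nature_hours = "Hours spent playing in nature",
    adventurous_place_hours = "Hours spent playing in adventurous places",
    adventurous_play_hours = "Hours spent playing adventurously",
    mean_adventure = "Average level of adventurous play")
}

stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Presentation-shaped reliability reports
#'
#' `format_stability_report()` reshapes a [stability_table()] into the
#' familiar means-and-SDs layout: one row per metric, `mean (sd)` cells per
#' role and timepoint, with significance stars on the time-2 cell
#' (`*` p < .05, `**` p < .001, unadjusted). `format_agreement_report()`
#' binds agreement tables into one row per metric with `ccc [lower-upper]`
#' cells per analysis; not-estimable entries appear as `"n/e"`. Hours and
#' coefficients are rounded to 2 decimal places for display; use the
#' underlying tibbles for full precision.
#'
#' @param stability A tibble from [stability_table()].
#' @param digits Decimal places for display.
#' @return A tibble of formatted strings.
#' @export
format_stability_report <- function(stability, digits = 2) {
  cell <- function(m, s) {
    ifelse(is.na(m), "n/e",
           sprintf("%.*f (%.*f)", digits, m, digits, s))
  }
  stability |>
    dplyr::mutate(
      t1 = cell(.data$mean_t1, .data$sd_t1),
      t2 = paste0(cell(.data$mean_t2, .data$sd_t2), stars(.data$p_value))
    ) |>
    dplyr::select("role", "metric", "t1", "t2") |>
    tidyr::pivot_wider(names_from = "role", values_from = c("t1", "t2"),
                       names_glue = "{role}_{.value}") |>
    dplyr::mutate(metric = unname(metric_titles()[.data$metric]))
}

#' @rdname format_stability_report
#' @param ... One or more `cps_agreement` tibbles (e.g. cross-informant and
#'   the two test-retest tables).
#' @export
format_agreement_report <- function(..., digits = 2) {
  tbl <- dplyr::bind_rows(...)
  tbl |>
    dplyr::mutate(
      cell = ifelse(.data$estimable,
                    sprintf("%.*f [%.*f-%.*f]", digits, .data$ccc,
                            digits, .data$ci_lower, digits, .data$ci_upper),
                    "n/e")
    ) |>
    dplyr::select("metric", "analysis", "cell") |>
    tidyr::pivot_wider(names_from = "analysis", values_from = "cell") |>
    dplyr::mutate(metric = unname(metric_titles()[.data$metric]))
}

write_report_csv <- function(tbl, path) {
  readr::write_csv(tbl, path, na = "", progress = FALSE)
  invisible(path)
}

write_report_txt <- function(tbl, path, title) {
  widths <- pmax(nchar(names(tbl)),
                 vapply(tbl, function(col) max(nchar(as.character(col)), 0L),
                        integer(1)))
  fmt_row <- function(vals) {
    paste(mapply(formatC, as.character(vals), width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }
  lines <- c(title, strrep("-", nchar(title)), fmt_row(names(tbl)),
             apply(tbl, 1, fmt_row))
  writeLines(lines, path)
  invisible(path)
}
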