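#' Convert ordinal categories to numeric play quantities
#'
#' `frequency_to_days()` maps frequency category labels to approximate days
#' of play per half-year; `duration_to_hours()` maps duration labels to
#' hours per play day, with `not_applicable` scoring 0. Both are vectorised
#' and propagate `NA`. An unconfigured label is an error, never a silent 0.
#'
#' @param x Character vector of category labels.
#' @param mapping A [cps_mapping()].
#' @return A numeric vector the same length as `x`.
#' @export
#' @examples
#' frequency_to_days(c("every_day", "4_6_per_week", "never"))
#' duration_to_hours(c("2_3_hours", "not_applicable"))
frequency_to_days <- function(x, mapping = cps_mapping()) {
  bad <- setdiff(unique(x[!is.na(x)]), names(mapping$freq_days))
  if (length(bad) > 0) {
    rlang::abort(paste0("Frequency label(s) not in mapping: ",
                        paste(bad, collapse = ", ")),
                 class = "playscale_mapping_error")
  }
  unname(mapping$freq_days[x])
}

#' @rdname frequency_to_days
#' @export
duration_to_hours <- function(x, mapping = cps_mapping()) {
  tbl <- c(mapping$dur_hours, not_applicable = 0)
  bad <- setdiff(unique(x[!is.na(x)]), names(tbl))
  if (length(bad) > 0) {
    rlang::abort(paste0("Duration label(s) not in mapping: ",
                        paste(bad, collapse = ", ")),
                 class = "playscale_mapping_error")
  }
  unname(tbl[x])
}

#' Annual hours of play per place
#'
#' For each response, place and season, the days-per-half-year value of the
#' frequency category is multiplied by the hours-per-play-day value of the
#' duration category to give seasonal hours; the Autumn/Winter and
#' Spring/Summer halves are then added to give annual hours in that place.
#' A place with positive frequency but a missing or `not_applicable`
#' duration contributes 0 hours for that season (flagged by
#' [validate_cps()]); a place with a missing frequency yields `NA` seasonal
#' hours.
#'
#' @param responses A responses tibble.
#' @param mapping A [cps_mapping()].
#' @return A long tibble: one row per response x canonical place, with
#'   `hours_aw`, `hours_ss`, `hours_annual` and the place's `adventure`
#'   rating.
#' @export
place_annual_hours <- function(responses, mapping = cps_mapping()) {
  pl <- cps_places()$place
  keys <- c("child_id", "informant_id", "role", "timepoint")
  season_hours <- function(s) {
    out <- responses[keys]
    for (p in pl) {
      fc <- responses[[paste0("freq_", p, "_", s)]]
      dc <- responses[[paste0("dur_", p, "_", s)]]
      days <- frequency_to_days(fc, mapping)
      hrs <- duration_to_hours(dc, mapping)
      # positive frequency, missing duration -> no usable estimate: 0 h
      hrs[is.na(hrs)] <- 0
      out[[p]] <- days * hrs
    }
    tidyr::pivot_longer(out, cols = dplyr::all_of(pl), names_to = "place",
                        values_to = paste0("hours_", s))
  }
  adv <- responses[keys]
  for (p in pl) adv[[p]] <- responses[[paste0("adv_", p)]]
  adv <- tidyr::pivot_longer(adv, cols = dplyr::all_of(pl),
                             names_to = "place", values_to = "adventure")
  season_hours("aw") |>
    dplyr::left_join(season_hours("ss"), by = c(keys, "place")) |>
    dplyr::left_join(adv, by = c(keys, "place")) |>
    dplyr::mutate(hours_annual = .data$hours_aw + .data$hours_ss,
                  place = factor(.data$place, levels = pl))
}

#' Names of the six headline CPS metrics
#' @return A character vector, in presentation order.
#' @export
cps_metric_names <- function() {
  c("total_hours", "outdoor_hours", "nature_hours",
    "adventurous_place_hours", "adventurous_play_hours", "mean_adventure")
}

#' Score a CPS dataset: the six headline metrics per response
#'
#' Derives, for every response (informant x timepoint):
#' \describe{
#'   \item{total_hours}{annual hours summed across all seven places;}
#'   \item{outdoor_hours}{summed across the outdoor places;}
#'   \item{nature_hours}{summed across green spaces and near water;}
#'   \item{adventurous_place_hours}{summed across the places where children
#'     are typically rated as playing most adventurously (playground, green
#'     spaces, indoor play centres, near water);}
#'   \item{adventurous_play_hours}{summed across only the places where this
#'     child's play was rated at or above the adventure threshold (default
#'     2, mild);}
#'   \item{mean_adventure}{the unweighted mean of the child's present
#'     adventure ratings, `NA` if none are present.}
#' }
#'
#' With `include_other_places = TRUE` in the mapping, scored 'other place'
#' entries (frequency x duration, assumed equal across the two half-years)
#' are added to `total_hours` and, when rated at or above the threshold, to
#' `adventurous_play_hours`; they never enter the place-group metrics or
#' `mean_adventure`.
#'
#' @param responses A responses tibble; keys must be unique.
#' @param mapping A [cps_mapping()].
#' @return A tibble with one row per response: the four key columns plus the
#'   six metric columns.
#' @export
#' @examples
#' sim <- simulate_cps(cps_sim_config(n_children = 5, seed = 1))
#' score_cps(sim)
score_cps <- function(responses, mapping = cps_mapping()) {
  if (nrow(responses) == 0) rlang::abort("No responses to score")
  key <- paste(responses$child_id, responses$informant_id, responses$timepoint)
  if (anyDuplicated(key)) {
    rlang::abort("Duplicate (child_id, informant_id, timepoint) keys; run validate_cps()")
  }
  ph <- place_annual_hours(responses, mapping)
  g <- mapping$groups
  thr <- mapping$adventure_threshold
  metrics <- ph |>
    dplyr::group_by(.data$child_id, .data$informant_id, .data$role, .data$timepoint) |>
    dplyr::summarise(
      total_hours = sum(.data$hours_annual, na.rm = TRUE),
      outdoor_hours = sum(.data$hours_annual[.data$place %in% g$outdoor], na.rm = TRUE),
      nature_hours = sum(.data$hours_annual[.data$place %in% g$nature], na.rm = TRUE),
      adventurous_place_hours =
        sum(.data$hours_annual[.data$place %in% g$adventurous_place], na.rm = TRUE),
      adventurous_play_hours =
        sum(.data$hours_annual[!is.na(.data$adventure) & .data$adventure >= thr],
            na.rm = TRUE),
      mean_adventure = if (all(is.na(.data$adventure))) NA_real_ else
        mean(.data$adventure, na.rm = TRUE),
      .groups = "drop"
    )
  if (mapping$include_other_places) {
    oth <- other_place_hours(responses, mapping)
    metrics <- metrics |>
      dplyr::left_join(oth, by = c("child_id", "informant_id", "timepoint")) |>
      dplyr::mutate(
        total_hours = .data$total_hours + dplyr::coalesce(.data$other_hours, 0),
        adventurous_play_hours =
          .data$adventurous_play_hours + dplyr::coalesce(.data$other_adv_hours, 0)
      ) |>
      dplyr::select(-"other_hours", -"other_adv_hours")
  }
  # preserve input row order
  metrics[match(key, paste(metrics$child_id, metrics$informant_id, metrics$timepoint)), ]
}

# Annualised hours from up to three 'other place' entries per response.
# The instrument asks frequency/duration once for these, so the half-year
# days value is assumed to apply to both halves of the year.
other_place_hours <- function(responses, mapping) {
  out <- responses[c("child_id", "informant_id", "timepoint")]
  out$other_hours <- 0
  out$other_adv_hours <- 0
  for (i in 1:3) {
    fc <- responses[[paste0("other", i, "_freq")]]
    dc <- responses[[paste0("other", i, "_dur")]]
    av <- responses[[paste0("other", i, "_adv")]]
    if (is.null(fc)) next
    days <- frequency_to_days(fc, mapping)
    hrs <- duration_to_hours(dc, mapping)
    h <- 2 * dplyr::coalesce(days, 0) * dplyr::coalesce(hrs, 0)
    out$other_hours <- out$other_hours + h
    adv_ok <- !is.na(av) & av >= mapping$adventure_threshold
    out$other_adv_hours <- out$other_adv_hours + ifelse(adv_ok, h, 0)
  }
  out
}

#' Mean hours and adventure level per place, by informant role
#'
#' Descriptive summary of where children play: for each place and role, the
#' mean annual hours (over responses with a defined value) and the mean
#' adventure rating (over present ratings only), at one timepoint.
#'
#' @param responses A responses tibble.
#' @param mapping A [cps_mapping()].
#' @param timepoint Timepoint to describe (default `"t1"`).
#' @param roles Roles that must be present; an empty stratum is an error.
#' @return A tibble: `place`, `role`, `n`, `mean_hours`, `mean_adventure`.
#' @export
describe_by_place <- function(responses, mapping = cps_mapping(),
                              timepoint = "t1",
                              roles = c("mother", "father")) {
  rs <- responses[responses$timepoint == timepoint, , drop = FALSE]
  for (r in roles) {
    if (!any(rs$role == r)) {
      rlang::abort(paste0("No responses for role '", r, "' at ", timepoint))
    }
  }
  place_annual_hours(rs, mapping) |>
    dplyr::filter(.data$role %in% roles) |>
    dplyr::group_by(.data$place, .data$role) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_hours = mean(.data$hours_annual, na.rm = TRUE),
      mean_adventure = if (all(is.na(.data$adventure))) NA_real_ else
        mean(.data$adventure, na.rm = TRUE),
      .groups = "drop"
    )
}
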