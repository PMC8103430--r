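#' Category-to-numeric mapping configuration
#'
#' The scoring algorithm converts each ordinal frequency category into an
#' approximate number of play days per half-year (Autumn/Winter or
#' Spring/Summer), and each duration category into hours per play day.
#' Where a category is a range, its numeric value is the centre of the range
#' over a 26-week half-year: for example 'every day' is 182.5 days (half the
#' year), '4--6 times a week' is 130 days (5 days x 26 weeks), and '2--3
#' hours' is 2.5 hours. The open-ended '4 hours +' category is floored at
#' 4.0 hours and 'less than half an hour' is the midpoint 0.25; both
#' defaults can be overridden by supplying a different table, e.g. from a
#' mapping JSON accompanying a specific administration of the instrument.
#'
#' @param freq_days Named numeric vector: days per half-year for each
#'   frequency category. Must be non-decreasing in category rank with
#'   `never = 0`.
#' @param dur_hours Named numeric vector: hours per play day for each
#'   duration category. Must be non-decreasing in rank, values in (0, 24).
#' @param adventure_threshold Minimum adventure rating (default 2, "mild
#'   levels of adventure") for a place's hours to count as adventurous play.
#' @param groups Named list of place groups. Defaults to the canonical
#'   `outdoor`, `nature`, `adventurous_place` and `indoor` sets from
#'   [cps_places()]. `nature` must be a subset of `outdoor`.
#' @param include_other_places Include scored 'other place' entries in the
#'   hour metrics? Default `FALSE`: the headline metrics sum over the seven
#'   canonical places only.
#' @return An object of class `cps_mapping`.
#' @seealso [read_cps_mapping()] to load a configuration from JSON.
#' @export
#' @examples
#' m <- cps_mapping()
#' m$freq_days[["every_day"]]   # 182.5
#' m$dur_hours[["2_3_hours"]]   # 2.5
cps_mapping <- function(freq_days = NULL, dur_hours = NULL,
                        adventure_threshold = 2L, groups = NULL,
                        include_other_places = FALSE) {
  if (is.null(freq_days)) {
    freq_days <- c(
      never = 0,                 # no play
      less_than_monthly = 3,     # centre of (0, 1)/month x 6 months
      "1_3_per_month" = 12,      # 2/month x 6 months
      once_per_week = 26,        # 1 x 26 weeks
      "2_3_per_week" = 65,       # 2.5 x 26 weeks
      "4_6_per_week" = 130,      # 5 x 26 weeks
      every_day = 182.5          # half the year
    )
  }
  if (is.null(dur_hours)) {
    dur_hours <- c(
      lt_half_hour = 0.25,       # centre of [0, 0.5]
      half_to_2_hours = 1.25,    # centre of [0.5, 2]
      "2_3_hours" = 2.5,         # centre of [2, 3]
      "4_hours_plus" = 4         # open-ended; floored at 4
    )
  }
  if (is.null(groups)) {
    pl <- cps_places()
    groups <- list(
      outdoor = pl$place[pl$outdoor],
      nature = pl$place[pl$nature],
      adventurous_place = pl$place[pl$adventurous_place],
      indoor = pl$place[pl$indoor]
    )
  }
  m <- structure(
    list(freq_days = freq_days, dur_hours = dur_hours,
         adventure_threshold = as.integer(adventure_threshold),
         groups = groups,
         include_other_places = isTRUE(include_other_places)),
    class = "cps_mapping"
  )
  validate_cps_mapping(m)
  m
}

validate_cps_mapping <- function(m) {
  fd <- m$freq_days
  if (any(fd < 0) || is.unsorted(fd)) {
    rlang::abort("freq_days must be non-negative and non-decreasing in category rank")
  }
  if ("never" %in% names(fd) && fd[["never"]] != 0) {
    rlang::abort("freq_days['never'] must be 0")
  }
  dh <- m$dur_hours
  if (any(dh <= 0) || any(dh >= 24) || is.unsorted(dh)) {
    rlang::abort("dur_hours must be increasing values in (0, 24)")
  }
  if (!all(c("outdoor", "nature", "adventurous_place") %in% names(m$groups))) {
    rlang::abort("groups must define outdoor, nature and adventurous_place")
  }
  if (!all(m$groups$nature %in% m$groups$outdoor)) {
    rlang::abort("the nature group must be a subset of the outdoor group")
  }
  if (!(m$adventure_threshold %in% 1:5)) {
    rlang::abort("adventure_threshold must be an integer in 1-5")
  }
  invisible(m)
}

#' @export
print.cps_mapping <- function(x, ...) {
  cat("<cps_mapping>\n")
  cat("  freq_days:", paste0(names(x$freq_days), "=", x$freq_days, collapse = ", "), "\n")
  cat("  dur_hours:", paste0(names(x$dur_hours), "=", x$dur_hours, collapse = ", "), "\n")
  cat("  adventure_threshold:", x$adventure_threshold, "\n")
  cat("  include_other_places:", x$include_other_places, "\n")
  for (g in names(x$groups)) {
    cat("  group ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a mapping configuration as JSON
#'
#' The JSON layout mirrors the [cps_mapping()] fields:
#' `{"freq_days": {...}, "dur_hours": {...}, "adventure_threshold": 2,
#' "groups": {...}, "include_other_places": false}`. Fields omitted from the
#' file fall back to the defaults.
#'
#' @param path Path to a JSON file.
#' @return `read_cps_mapping()` returns a `cps_mapping`;
#'   `write_cps_mapping()` returns `path` invisibly.
#' @export
read_cps_mapping <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Mapping file not found: ", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cps_mapping(
    freq_days = if (!is.null(j$freq_days)) unlist(j$freq_days),
    dur_hours = if (!is.null(j$dur_hours)) unlist(j$dur_hours),
    adventure_threshold = j$adventure_threshold %||% 2L,
    groups = j$groups,
    include_other_places = j$include_other_places %||% FALSE
  )
}

#' @rdname read_cps_mapping
#' @param mapping A `cps_mapping`.
#' @export
write_cps_mapping <- function(mapping, path) {
  jsonlite::write_json(
    list(freq_days = as.list(mapping$freq_days),
         dur_hours = as.list(mapping$dur_hours),
         adventure_threshold = mapping$adventure_threshold,
         groups = mapping$groups,
         include_other_places = mapping$include_other_places),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
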