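#' The seven canonical CPS places
#'
#' The Children's Play Scale (CPS) asks parents how often, how long and how
#' adventurously their child plays in seven places. Each place belongs to one
#' or more analysis groups: `outdoor` (everywhere outside a building),
#' `nature` (green spaces and near water; a subset of `outdoor`),
#' `adventurous_place` (the places where children are typically rated as
#' playing most adventurously) and `indoor`.
#'
#' @return A tibble with one row per place and columns `place` (code),
#'   `label` (display text), and logical group columns `outdoor`, `nature`,
#'   `adventurous_place`, `indoor`.
#' @export
#' @examples
#' cps_places()
cps_places <- function() {
  tibble::tibble(
    place = c("home_inside", "home_outside", "playground", "green_space",
              "street", "water", "indoor_centre"),
    label = c(
      "At home or in other people's homes",
      "Outside at home or at other people's homes",
      "At a playground",
      "Green spaces (trees/forests/woodland/grassy spaces)",
      "In the street or public place close to home",
      "Outdoors near water",
      "Indoor play centres and pools"
    ),
    outdoor = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    nature = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    adventurous_place = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    indoor = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Ordinal response categories of the CPS
#'
#' Play frequency is reported on a seven-point scale from never to every day,
#' each anchor tied to a concrete period of time. Play duration (on a day the
#' child plays in a place) is reported on a four-point scale from less than
#' half an hour to four hours or more, with a separate `not_applicable`
#' option for places where the child does not play. Levels are returned in
#' increasing order of play.
#'
#' @return A character vector of category labels, lowest first.
#' @export
#' @examples
#' cps_frequency_levels()
#' cps_duration_levels()
cps_frequency_levels <- function() {
  c("never", "less_than_monthly", "1_3_per_month", "once_per_week",
    "2_3_per_week", "4_6_per_week", "every_day")
}

#' @rdname cps_frequency_levels
#' @param na Include the `not_applicable` marker at the front?
#' @export
cps_duration_levels <- function(na = FALSE) {
  lv <- c("lt_half_hour", "half_to_2_hours", "2_3_hours", "4_hours_plus")
  if (na) c("not_applicable", lv) else lv
}

#' Adventure-level anchors (1--5)
#'
#' Parents rate how adventurously their child plays in each place on a
#' five-point scale, where adventurous (risky) play is exciting, thrilling
#' play involving age-appropriate risk, fear and challenge. Higher scores
#' indicate higher levels of adventure.
#'
#' @return A tibble with columns `level` (integer 1--5) and `label`.
#' @export
cps_adventure_levels <- function() {
  tibble::tibble(
    level = 1:5,
    label = c("Very low levels of adventure", "Mild levels of adventure",
              "Moderate levels of adventure", "High levels of adventure",
              "Maximum levels of adventure")
  )
}

seasons <- function() c("aw", "ss")

# Column names of the wide one-row-per-response CSV schema.
cps_schema_columns <- function() {
  pl <- cps_places()$place
  c(
    "child_id", "informant_id", "role", "timepoint",
    paste0("freq_", rep(pl, each = 2), "_", seasons()),
    paste0("dur_",  rep(pl, each = 2), "_", seasons()),
    paste0("adv_", pl),
    paste0("other", rep(1:3, each = 4), "_", c("text", "freq", "dur", "adv")),
    "other_unsupervised"
  )
}

#' Read CPS responses from CSV
#'
#' Reads a wide-format response file: one row per informant and timepoint,
#' with identifier columns (`child_id`, `informant_id`, `role`, `timepoint`),
#' a frequency and a duration column per place and season
#' (`freq_<place>_<aw|ss>`, `dur_<place>_<aw|ss>`), an adventure rating per
#' place (`adv_<place>`), up to three free-text "other place" entries
#' (`other1_text`, `other1_freq`, ...) and a logical `other_unsupervised`
#' flag recording the response "possibly, but I don't know where because
#' they are unsupervised".
#'
#' Category labels are checked against the mapping configuration: an
#' unrecognised frequency or duration label raises an error naming the row
#' and column rather than being silently coerced to missing.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param mapping A [cps_mapping()] defining the accepted category labels.
#' @return A tibble of responses in schema column order.
#' @seealso [validate_cps()] for invariant checks beyond the schema,
#'   [write_cps()] for the inverse operation.
#' @export
read_cps <- function(path, mapping = cps_mapping()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Response file not found: ", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- cps_schema_columns()
  missing_cols <- setdiff(required, names(df))
  # 'other' slots and the unsupervised flag may be absent entirely
  hard_required <- setdiff(missing_cols, grep("^other", required, value = TRUE))
  if (length(hard_required) > 0) {
    rlang::abort(paste0("Response file is missing mandatory column(s): ",
                        paste(hard_required, collapse = ", ")),
                 class = "playscale_schema_error")
  }
  extra_other <- grep("^other[4-9]_", names(df), value = TRUE)
  if (length(extra_other) > 0) {
    rlang::abort(paste0("At most 3 'other place' entries are allowed; found column(s): ",
                        paste(extra_other, collapse = ", ")),
                 class = "playscale_schema_error")
  }
  for (col in setdiff(required, names(df))) {
    df[[col]] <- if (col == "other_unsupervised") "FALSE" else NA_character_
  }
  df <- df[required]
  as_cps_responses(df, mapping)
}

# Coerce a raw character tibble to typed responses, checking labels.
as_cps_responses <- function(df, mapping = cps_mapping()) {
  check_labels <- function(cols, allowed, what) {
    for (col in cols) {
      bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% allowed))
      if (length(bad) > 0) {
        rlang::abort(sprintf(
          "Unrecognised %s label '%s' in column '%s', row %d (allowed: %s)",
          what, df[[col]][bad[1]], col, bad[1], paste(allowed, collapse = ", ")),
          class = "playscale_value_error")
      }
    }
  }
  check_labels("role", c("mother", "father"), "role")
  check_labels("timepoint", c("t1", "t2"), "timepoint")
  freq_cols <- grep("^freq_", names(df), value = TRUE)
  dur_cols <- grep("^dur_", names(df), value = TRUE)
  check_labels(freq_cols, names(mapping$freq_days), "frequency")
  check_labels(dur_cols, c(names(mapping$dur_hours), "not_applicable"), "duration")
  check_labels(grep("^other\\d_freq$", names(df), value = TRUE),
               names(mapping$freq_days), "frequency")
  check_labels(grep("^other\\d_dur$", names(df), value = TRUE),
               c(names(mapping$dur_hours), "not_applicable"), "duration")

  adv_cols <- grep("^adv_|^other\\d_adv$", names(df), value = TRUE)
  for (col in adv_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(!is.na(df[[col]]) & (is.na(v) | !(v %in% 1:5)))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "Adventure rating '%s' in column '%s', row %d is not an integer in 1-5",
        df[[col]][bad[1]], col, bad[1]), class = "playscale_value_error")
    }
    df[[col]] <- v
  }
  df$other_unsupervised <- tolower(trimws(df$other_unsupervised)) %in%
    c("true", "t", "1", "yes")
  df
}

#' Write CPS responses to CSV
#'
#' Inverse of [read_cps()]: the written file round-trips through the reader
#' with identical labels and identifiers.
#'
#' @param responses A responses tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cps <- function(responses, path) {
  readr::write_csv(responses, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate CPS responses
#'
#' Checks the instrument's invariants and reports, rather than raises,
#' every violation found. A response set is valid iff the returned tibble
#' has zero rows.
#'
#' Checks include: uniqueness of (child, informant, timepoint); at most one
#' mother-role and one father-role informant per child and timepoint; a
#' place reported as never played must not carry a duration (and vice versa,
#' a positive frequency with a `not_applicable` duration is flagged as a
#' warning, since such a place contributes zero hours under scoring); and
#' adventure ratings within 1--5. Severity `"error"` marks an invariant
#' violation, `"warning"` a scorable but suspicious pattern.
#'
#' @param responses A responses tibble (from [read_cps()] or built in code).
#' @param mapping A [cps_mapping()].
#' @return A tibble with columns `row`, `child_id`, `informant_id`,
#'   `timepoint`, `field`, `severity`, `issue`; zero rows when valid.
#' @export
validate_cps <- function(responses, mapping = cps_mapping()) {
  issues <- list()
  add <- function(rows, field, severity, issue) {
    if (length(rows) == 0) return()
    issues[[length(issues) + 1]] <<- tibble::tibble(
      row = rows,
      child_id = as.character(responses$child_id[rows]),
      informant_id = as.character(responses$informant_id[rows]),
      timepoint = as.character(responses$timepoint[rows]),
      field = field, severity = severity, issue = issue
    )
  }

  key <- paste(responses$child_id, responses$informant_id, responses$timepoint)
  add(which(duplicated(key)), "child_id/informant_id/timepoint", "error",
      "duplicate (child_id, informant_id, timepoint) key")

  role_key <- paste(responses$child_id, responses$role, responses$timepoint)
  dup_role <- duplicated(role_key) & !duplicated(key)
  add(which(dup_role), "role", "error",
      "more than one informant with this role for the child at this timepoint")

  add(which(!responses$role %in% c("mother", "father")), "role", "error",
      "role must be one of {mother, father}")
  add(which(!responses$timepoint %in% c("t1", "t2")), "timepoint", "error",
      "timepoint must be one of {t1, t2}")

  for (p in cps_places()$place) {
    for (s in seasons()) {
      fc <- responses[[paste0("freq_", p, "_", s)]]
      dc <- responses[[paste0("dur_", p, "_", s)]]
      never <- !is.na(fc) & fc == "never"
      has_dur <- !is.na(dc) & dc != "not_applicable"
      add(which(never & has_dur), paste0("dur_", p, "_", s), "error",
          "duration reported for a place with frequency 'never'")
      played <- !is.na(fc) & fc != "never"
      add(which(played & !has_dur), paste0("dur_", p, "_", s), "warning",
          "positive frequency but no usable duration; place scores 0 hours")
    }
    av <- responses[[paste0("adv_", p)]]
    add(which(!is.na(av) & !(av %in% 1:5)), paste0("adv_", p), "error",
        "adventure rating outside 1-5")
  }

  if (length(issues) == 0) {
    tibble::tibble(row = integer(), child_id = character(),
                   informant_id = character(), timepoint = character(),
                   field = character(), severity = character(),
                   issue = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(issues), .data$row)
  }
}

#' Tally free-text 'other place' entries
#'
#' Counts, per category, the informants who listed at least one matching
#' 'other place' where their child plays, at a single timepoint. Free text is
#' normalised by case-folding and whitespace-squishing before matching. With
#' `rules = NULL` each distinct normalised text is its own category; with a
#' named list of rules (category name to character vector of texts, matched
#' case-insensitively) unmatched texts fall into `"uncategorized"`.
#'
#' Percentages are computed over all distinct informants present at the
#' timepoint (reporters and non-reporters alike) and rounded to one decimal
#' place, matching how such tallies are conventionally presented.
#'
#' @param responses A responses tibble.
#' @param rules `NULL`, or a named list mapping category to accepted texts.
#' @param timepoint Timepoint to tally, `"t1"` (default) or `"t2"`.
#' @return A tibble with columns `category`, `n`, `percentage`, ordered by
#'   decreasing count; zero rows when no informant listed an other place.
#' @export
tally_other_places <- function(responses, rules = NULL, timepoint = "t1") {
  stopifnot(timepoint %in% c("t1", "t2"))
  rs <- responses[responses$timepoint == timepoint, , drop = FALSE]
  if (nrow(rs) == 0) {
    rlang::abort(paste0("No responses at timepoint ", timepoint))
  }
  n_informants <- dplyr::n_distinct(rs$informant_id)

  squish <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  long <- tidyr::pivot_longer(
    rs[c("informant_id", paste0("other", 1:3, "_text"))],
    cols = -"informant_id", values_to = "text"
  )
  long <- long[!is.na(long$text) & trimws(long$text) != "", c("informant_id", "text")]
  if (nrow(long) == 0) {
    return(tibble::tibble(category = character(), n = integer(),
                          percentage = numeric()))
  }
  long$norm <- squish(long$text)
  if (is.null(rules)) {
    long$category <- long$norm
  } else {
    lut <- stats::setNames(
      rep(names(rules), lengths(rules)),
      squish(unlist(rules, use.names = FALSE))
    )
    long$category <- unname(lut[long$norm])
    long$category[is.na(long$category)] <- "uncategorized"
  }
  long |>
    dplyr::distinct(.data$informant_id, .data$category) |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(percentage = round(100 * .data$n / n_informants, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
}
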