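test_that("category conversions reproduce the instrument's numeric anchors", {
  m <- cps_mapping()
  expect_equal(frequency_to_days("every_day", m), 182.5)
  expect_equal(frequency_to_days("4_6_per_week", m), 130)
  expect_equal(frequency_to_days("never", m), 0)
  expect_equal(duration_to_hours("2_3_hours", m), 2.5)
  expect_equal(duration_to_hours("lt_half_hour", m), 0.25)
  expect_equal(duration_to_hours("not_applicable", m), 0)
  expect_true(is.na(frequency_to_days(NA_character_, m)))
  expect_error(frequency_to_days("fortnightly", m),
               class = "playscale_mapping_error")
  expect_error(duration_to_hours("all day", m),
               class = "playscale_mapping_error")
})

test_that("mapping configuration enforces its invariants", {
  expect_error(cps_mapping(freq_days = c(never = 1, every_day = 182.5)),
               "never")
  expect_error(cps_mapping(freq_days = c(never = 0, a = 100, b = 50)),
               "non-decreasing")
  expect_error(cps_mapping(dur_hours = c(a = 0.5, b = 25)), "\\(0, 24\\)")
  expect_error(cps_mapping(groups = list(outdoor = "street",
                                         nature = c("green_space"),
                                         adventurous_place = "playground")),
               "subset")
  # JSON round trip preserves every field
  m <- cps_mapping(adventure_threshold = 3, include_other_places = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_cps_mapping(m, path)
  back <- read_cps_mapping(path)
  expect_equal(back$freq_days, m$freq_days)
  expect_equal(back$dur_hours, m$dur_hours)
  expect_equal(back$adventure_threshold, 3L)
  expect_true(back$include_other_places)
})

test_that("annual hours per place are seasonal products summed over seasons", {
  r <- set_place(blank_response("c1"), "green_space", "every_day",
                 "2_3_hours", adv = 3)
  ph <- place_annual_hours(r)
  gs <- ph[ph$place == "green_space", ]
  expect_equal(gs$hours_aw, 182.5 * 2.5)
  expect_equal(gs$hours_annual, 912.5)
  expect_true(all(ph$hours_annual[ph$place != "green_space"] == 0))

  # one season only
  r2 <- blank_response("c2")
  r2$freq_playground_aw <- "4_6_per_week"
  r2$dur_playground_aw <- "2_3_hours"
  ph2 <- place_annual_hours(r2)
  expect_equal(ph2$hours_annual[ph2$place == "playground"], 130 * 2.5)

  # positive frequency with not_applicable duration scores zero, not NA
  r3 <- blank_response("c3")
  r3$freq_street_aw <- "once_per_week"
  ph3 <- place_annual_hours(r3)
  expect_equal(ph3$hours_annual[ph3$place == "street"], 0)
})

test_that("the six metrics follow the scoring definitions", {
  r <- set_place(blank_response("c1"), "green_space", "every_day",
                 "2_3_hours", adv = 3)
  m <- score_cps(r)
  # green_space is outdoor, nature and an adventurous place; rating 3 >= 2
  expect_equal(m$total_hours, 912.5)
  expect_equal(m$outdoor_hours, 912.5)
  expect_equal(m$nature_hours, 912.5)
  expect_equal(m$adventurous_place_hours, 912.5)
  expect_equal(m$adventurous_play_hours, 912.5)
  expect_equal(m$mean_adventure, 3)

  # ratings all 1 never count as adventurous play, whatever the hours
  r2 <- set_place(blank_response("c2"), "playground", "every_day",
                  "4_hours_plus", adv = 1)
  r2 <- set_place(r2, "home_outside", "2_3_per_week", "half_to_2_hours",
                  adv = 1)
  m2 <- score_cps(r2)
  expect_gt(m2$total_hours, 0)
  expect_equal(m2$adventurous_play_hours, 0)
  expect_equal(m2$mean_adventure, 1)

  # all never: zero hours, missing mean adventure
  m3 <- score_cps(blank_response("c3"))
  expect_true(all(m3[c("total_hours", "outdoor_hours", "nature_hours",
                       "adventurous_place_hours",
                       "adventurous_play_hours")] == 0))
  expect_true(is.na(m3$mean_adventure))
})

test_that("scoring a dataset is keyed, deterministic and order-stable", {
  rs <- dplyr::bind_rows(
    set_place(blank_response("c1", "mother"), "green_space", "every_day",
              "2_3_hours", adv = 3),
    set_place(blank_response("c1", "father"), "street", "once_per_week",
              "lt_half_hour", adv = 2),
    set_place(blank_response("c2", "mother"), "water", "1_3_per_month",
              "4_hours_plus", adv = 5),
    blank_response("c2", "father")
  )
  m <- score_cps(rs)
  expect_equal(nrow(m), 4)
  expect_true(all(cps_metric_names() %in% names(m)))
  # permuting input rows permutes output rows only
  perm <- c(3, 1, 4, 2)
  m_perm <- score_cps(rs[perm, ])
  expect_equal(as.data.frame(m_perm), as.data.frame(m[perm, ]),
               ignore_attr = TRUE)
  # hand-computed mean over the three non-empty responses
  expect_equal(mean(m$total_hours),
               (912.5 + 2 * 26 * 0.25 + 2 * 12 * 4) / 4)
  dup <- dplyr::bind_rows(rs, rs[1, ])
  expect_error(score_cps(dup), "Duplicate")
})

test_that("'other place' entries enter the totals only when enabled", {
  r <- set_place(blank_response("c1"), "green_space", "every_day",
                 "2_3_hours", adv = 3)
  r$other1_text <- "school"
  r$other1_freq <- "once_per_week"
  r$other1_dur <- "2_3_hours"
  r$other1_adv <- 4L
  default <- score_cps(r)
  expect_equal(default$total_hours, 912.5)
  with_other <- score_cps(r, cps_mapping(include_other_places = TRUE))
  expect_equal(with_other$total_hours, 912.5 + 2 * 26 * 2.5)
  expect_equal(with_other$adventurous_play_hours, 912.5 + 2 * 26 * 2.5)
  # group metrics and mean adventure are untouched by 'other' entries
  expect_equal(with_other$nature_hours, default$nature_hours)
  expect_equal(with_other$mean_adventure, default$mean_adventure)
})

test_that("per-place descriptives average within role over defined values", {
  rs <- dplyr::bind_rows(
    set_place(blank_response("c1", "mother"), "green_space", "once_per_week",
              "2_3_hours", adv = 2),   # 2*26*2.5 = 130 h
    set_place(blank_response("c2", "mother"), "green_space", "2_3_per_week",
              "half_to_2_hours", adv = 4),  # 2*65*1.25 = 162.5 h
    set_place(blank_response("c3", "father"), "green_space", "once_per_week",
              "2_3_hours", adv = 2)
  )
  d <- describe_by_place(rs)
  gs_m <- d[d$place == "green_space" & d$role == "mother", ]
  expect_equal(gs_m$mean_hours, (130 + 162.5) / 2)
  expect_equal(gs_m$mean_adventure, 3)
  # identical mother and father responses give identical role columns
  rs2 <- dplyr::bind_rows(
    set_place(blank_response("c1", "mother"), "street", "every_day",
              "lt_half_hour", adv = 1),
    set_place(blank_response("c1", "father"), "street", "every_day",
              "lt_half_hour", adv = 1))
  d2 <- describe_by_place(rs2)
  expect_equal(d2$mean_hours[d2$role == "mother"],
               d2$mean_hours[d2$role == "father"])
  expect_error(describe_by_place(rs2[1, ]), "father")
})

test_that("hour metrics are monotone in category rank and scale with durations", {
  set.seed(42)
  freq_lv <- cps_frequency_levels()
  dur_lv <- cps_duration_levels()
  for (i in 1:20) {
    r <- random_response(sprintf("c%02d", i))
    m <- score_cps(r)
    # raise one random place/season frequency by one rank
    p <- sample(cps_places()$place, 1)
    s <- sample(c("aw", "ss"), 1)
    fcol <- paste0("freq_", p, "_", s)
    rank <- match(r[[fcol]], freq_lv)
    if (rank < length(freq_lv)) {
      r_up <- r
      r_up[[fcol]] <- freq_lv[rank + 1]
      dcol <- paste0("dur_", p, "_", s)
      if (r_up[[dcol]] == "not_applicable") r_up[[dcol]] <- dur_lv[1]
      m_up <- score_cps(r_up)
      for (col in setdiff(cps_metric_names(), "mean_adventure")) {
        expect_gte(m_up[[col]], m[[col]])
      }
    }
    # doubling every duration value exactly doubles every hour metric
    m2 <- cps_mapping(dur_hours = cps_mapping()$dur_hours * 2)
    doubled <- score_cps(r, m2)
    for (col in setdiff(cps_metric_names(), "mean_adventure")) {
      expect_equal(doubled[[col]], 2 * m[[col]])
    }
  }
})

test_that("adventurous-play hours shrink as the threshold rises", {
  set.seed(7)
  rs <- dplyr::bind_rows(lapply(sprintf("c%02d", 1:15), random_response))
  prev <- NULL
  for (thr in 1:5) {
    m <- score_cps(rs, cps_mapping(adventure_threshold = thr))
    if (!is.null(prev)) {
      expect_true(all(m$adventurous_play_hours <= prev + 1e-9))
    }
    prev <- m$adventurous_play_hours
  }
  # threshold 1: every rated place counts, so rows where every place with
  # positive hours carries a rating recover the total exactly
  m1 <- score_cps(rs, cps_mapping(adventure_threshold = 1))
  rated_all_played <- place_annual_hours(rs) |>
    dplyr::group_by(child_id, informant_id, timepoint) |>
    dplyr::summarise(
      ok = all(!is.na(adventure) | hours_annual == 0),
      .groups = "drop")
  sel <- m1 |> dplyr::left_join(rated_all_played,
                                by = c("child_id", "informant_id", "timepoint"))
  expect_true(any(sel$ok))
  expect_equal(sel$adventurous_play_hours[sel$ok], sel$total_hours[sel$ok])
})
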