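# Fixtures are built in code: a blank (all-never) response row that helpers
# then perturb, plus independent oracles for the agreement statistics.

blank_response <- function(child_id = "c1", role = "mother",
                           timepoint = "t1",
                           informant_id = paste0(child_id, "_", substr(role, 1, 1))) {
  cols <- playscale::cps_places()$place
  r <- tibble::tibble(child_id = child_id, informant_id = informant_id,
                      role = role, timepoint = timepoint)
  for (p in cols) {
    for (s in c("aw", "ss")) {
      r[[paste0("freq_", p, "_", s)]] <- "never"
      r[[paste0("dur_", p, "_", s)]] <- "not_applicable"
    }
    r[[paste0("adv_", p)]] <- NA_integer_
  }
  for (i in 1:3) {
    r[[paste0("other", i, "_text")]] <- NA_character_
    r[[paste0("other", i, "_freq")]] <- NA_character_
    r[[paste0("other", i, "_dur")]] <- NA_character_
    r[[paste0("other", i, "_adv")]] <- NA_integer_
  }
  r$other_unsupervised <- FALSE
  r[playscale:::cps_schema_columns()]
}

set_place <- function(r, place, freq, dur, adv = NA_integer_,
                      seasons = c("aw", "ss")) {
  for (s in seasons) {
    r[[paste0("freq_", place, "_", s)]] <- freq
    r[[paste0("dur_", place, "_", s)]] <-
      if (identical(freq, "never")) "not_applicable" else dur
  }
  r[[paste0("adv_", place)]] <- as.integer(adv)
  r
}

# A random but schema-consistent response (used for property tests).
random_response <- function(child_id, role = "mother", timepoint = "t1") {
  r <- blank_response(child_id, role, timepoint)
  freq_lv <- playscale::cps_frequency_levels()
  dur_lv <- playscale::cps_duration_levels()
  for (p in playscale::cps_places()$place) {
    played <- FALSE
    for (s in c("aw", "ss")) {
      f <- sample(freq_lv, 1)
      r[[paste0("freq_", p, "_", s)]] <- f
      r[[paste0("dur_", p, "_", s)]] <-
        if (f == "never") "not_applicable" else sample(dur_lv, 1)
      played <- played || f != "never"
    }
    r[[paste0("adv_", p)]] <- if (played && stats::runif(1) < 0.8)
      sample(1:5, 1) else NA_integer_
  }
  r
}

# Naive loop-based evaluation of the concordance formula with 1/n moments;
# deliberately written without vectorised shortcuts so it is an independent
# oracle for ccc().
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i] / n; my <- my + y[i] / n }
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Independent route to Cronbach's alpha via the covariance matrix:
# alpha = k/(k-1) * (1 - tr(C)/sum(C)).
alpha_oracle <- function(m) {
  C <- stats::cov(m[stats::complete.cases(m), , drop = FALSE])
  k <- ncol(C)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}
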