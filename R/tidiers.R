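#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance result
#'
#' @param x A `cps_ccc` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `ci_lower`, `ci_upper`, `n_pairs`,
#'   `pearson_r`, `band`, `conf_level` (and `label` when set).
#' @export
tidy.cps_ccc <- function(x, ...) {
  out <- tibble::tibble(
    estimate = x$estimate, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    n_pairs = x$n_pairs, pearson_r = x$pearson_r,
    band = agreement_band(x$estimate), conf_level = x$conf_level
  )
  if (!is.null(x$label)) out <- dplyr::mutate(out, label = x$label, .before = 1)
  out
}

#' @rdname tidy.cps_ccc
#' @export
glance.cps_ccc <- function(x, ...) tidy(x, ...)

#' Tidy an internal-consistency result
#'
#' @param x A `cps_alpha` object.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `k_items`, `n_cases`.
#' @export
tidy.cps_alpha <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, k_items = x$k_items, n_cases = x$n_cases)
}

#' @rdname tidy.cps_alpha
#' @export
glance.cps_alpha <- function(x, ...) tidy(x, ...)

#' Tidy a paired stability test
#'
#' @param x A `cps_paired` object.
#' @param ... Unused.
#' @return A one-row tibble with timepoint means/SDs and the t-test.
#' @export
tidy.cps_paired <- function(x, ...) {
  tibble::tibble(
    mean_t1 = x$mean_t1, sd_t1 = x$sd_t1,
    mean_t2 = x$mean_t2, sd_t2 = x$sd_t2,
    mean_diff = x$mean_diff, t_statistic = x$t_statistic,
    df = x$df, p_value = x$p_value, n_pairs = x$n_pairs
  )
}

#' @rdname tidy.cps_paired
#' @export
glance.cps_paired <- function(x, ...) tidy(x, ...)
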