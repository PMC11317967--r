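# broom-style verbs for fitted objects

#' Tidy the coefficients of a per-site editing GLM
#'
#' @param x An `editing_glm` from [glm_lrt_site()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (log-odds scale).
#' @method tidy editing_glm
#' @export
tidy.editing_glm <- function(x, ...) {
  if (is.null(x$coefficients)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' One-row summary of a per-site editing GLM
#'
#' @param x An `editing_glm` from [glm_lrt_site()].
#' @param ... Unused.
#' @return A tibble with `p_glm`, `statistic`, `df`, `deviance_full`,
#'   `deviance_null`, `n_samples`, `converged`, `flag`.
#' @method glance editing_glm
#' @export
glance.editing_glm <- function(x, ...) {
  tibble(p_glm = x$p_glm, statistic = x$statistic, df = x$df,
         deviance_full = x$deviance_full, deviance_null = x$deviance_null,
         n_samples = x$n_samples, converged = x$converged, flag = x$flag)
}

#' One-row summary of a differential-editing result table
#'
#' @param x A `dre_result` from [call_dre()].
#' @param ... Unused.
#' @return A tibble with `n_tested`, `n_dre`, `n_delta5`,
#'   `n_trend_classified`, `fdr_mode`.
#' @method glance dre_result
#' @export
glance.dre_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_dre = sum(x$is_dre, na.rm = TRUE),
    n_delta5 = sum(x$delta5_flag, na.rm = TRUE),
    n_trend_classified = sum(!is.na(x$trend) & x$trend != "unclassified"),
    fdr_mode = attr(x, "fdr_mode") %||% NA_character_
  )
}
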