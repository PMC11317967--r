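# shared internal helpers

# clamp a proportion into the open simulation range; used wherever an additive
# effect could push a true editing level out of [0, 1]
clamp_level <- function(x, lo = 0.001, hi = 0.999) {
  pmin(pmax(x, lo), hi)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "aied_schema_error")
  }
  invisible(df)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a proportion in [0, 1]", name),
          class = "aied_config_error")
  }
  invisible(x)
}

#' Build a subgroup assignment from sample metadata
#'
#' Maps every sample to the design cell ("subgroup") over which editing levels
#' are averaged for filtering, e.g. group x age x sex for a fully crossed
#' design, or group alone when age/sex are absent. Columns that are missing or
#' entirely `NA` are dropped from the label.
#'
#' @param metadata A data frame with a `sample_id` column and any of `group`,
#'   `age`, `sex`.
#' @param by Character vector of metadata columns to cross; defaults to those
#'   of `group`, `age`, `sex` that are present and non-degenerate.
#' @return A tibble with columns `sample_id` and `subgroup`.
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   sample_id = c("s1", "s2"), group = c("control", "D1"),
#'   age = c("young", "old"), sex = c("female", "male")
#' )
#' subgroup_scheme(meta)
subgroup_scheme <- function(metadata, by = NULL) {
  assert_columns(metadata, "sample_id", "metadata")
  if (anyDuplicated(metadata$sample_id)) {
    abort("metadata sample_ids must be unique", class = "aied_schema_error")
  }
  if (is.null(by)) {
    by <- intersect(c("group", "age", "sex"), names(metadata))
    by <- by[vapply(by, function(col) any(!is.na(metadata[[col]])), logical(1))]
  }
  if (length(by) == 0) {
    abort("no subgroup columns available in metadata", class = "aied_config_error")
  }
  assert_columns(metadata, by, "metadata")
  labels <- do.call(paste, c(lapply(by, function(col) as.character(metadata[[col]])),
                             sep = "/"))
  tibble(sample_id = metadata$sample_id, subgroup = labels)
}
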