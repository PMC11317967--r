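#' Is editing observed in a single (site, sample) record?
#'
#' A record counts as an observation of editing when it carries at least one
#' edited read at adequate coverage. The coverage floor guards against
#' single-read artifacts.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @param min_coverage Minimum total reads for a record to count (default 10).
#' @return A logical vector.
#' @export
#' @examples
#' editing_observed(c(20, 9, 5), c(0, 1, 1))
editing_observed <- function(ref_count, alt_count, min_coverage = 10) {
  alt_count >= 1 & (ref_count + alt_count) >= min_coverage
}

#' High-confidence editing-site filter
#'
#' Retains a candidate A-to-G site when it is a known editing site, or when
#' its mean editing level reaches `threshold` within at least one design
#' subgroup and editing is observed in at least `min_samples` samples
#' study-wide. Subgroup means are computed over samples with coverage of at
#' least `min_coverage`; subgroups with no covered sample contribute no mean.
#'
#' @param counts Long allele-count tibble (oriented, see [orient_to_sense()])
#'   with `site_id`, `chrom`, `pos`, `strand`, `sample_id`, `ref_count`,
#'   `alt_count`.
#' @param metadata Sample metadata with `sample_id` and the subgroup columns.
#' @param known_sites Optional known-site table (see [flag_known()]).
#' @param threshold Subgroup-mean editing level needed for retention
#'   (default 0.05, inclusive).
#' @param min_samples Minimum number of samples with observed editing
#'   (default 2).
#' @param min_coverage Coverage floor for levels and observations (default 10).
#' @param subgroup_by Optional explicit subgroup columns (see
#'   [subgroup_scheme()]).
#' @param keep_all Return all candidates with a `retained` flag instead of the
#'   retained catalog only.
#' @return A tibble with one row per site: the site fields plus `known`,
#'   `max_subgroup_mean`, `n_observed`, `retained`, `retained_reason`
#'   (`"known"` or `"level"`).
#' @export
high_confidence_filter <- function(counts, metadata, known_sites = NULL,
                                   threshold = 0.05, min_samples = 2,
                                   min_coverage = 10, subgroup_by = NULL,
                                   keep_all = FALSE) {
  assert_columns(counts, c("site_id", "sample_id", "ref_count", "alt_count"),
                 "counts")
  scheme <- subgroup_scheme(metadata, by = subgroup_by)
  unmatched <- setdiff(unique(counts$sample_id), scheme$sample_id)
  if (length(unmatched) > 0) {
    abort(sprintf("samples missing from metadata: %s",
                  paste(head(unmatched, 5), collapse = ", ")),
          class = "aied_schema_error")
  }
  site_cols <- intersect(c("site_id", "chrom", "pos", "strand", "ref", "alt"),
                         names(counts))
  sites <- counts %>% distinct(across(all_of(site_cols)))

  per_record <- counts %>%
    left_join(scheme, by = "sample_id") %>%
    mutate(
      level = editing_level(.data$ref_count, .data$alt_count, min_coverage),
      observed = editing_observed(.data$ref_count, .data$alt_count, min_coverage)
    )
  stats <- per_record %>%
    group_by(.data$site_id) %>%
    summarise(
      n_observed = sum(.data$observed),
      max_subgroup_mean = {
        m <- tapply(.data$level, .data$subgroup,
                    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
        if (all(is.na(m))) NA_real_ else max(m, na.rm = TRUE)
      },
      .groups = "drop"
    )

  out <- sites %>%
    left_join(stats, by = "site_id")
  out <- if ("chrom" %in% names(out) && "pos" %in% names(out)) {
    flag_known(out, known_sites)
  } else {
    out %>% mutate(known = FALSE)
  }
  out <- out %>%
    mutate(
      by_level = !is.na(.data$max_subgroup_mean) &
        .data$max_subgroup_mean >= threshold &
        .data$n_observed >= min_samples,
      retained = .data$known | .data$by_level,
      retained_reason = dplyr::case_when(
        known ~ "known",
        by_level ~ "level",
        TRUE ~ NA_character_
      )
    ) %>%
    select(-"by_level")
  if (keep_all) out else out %>% filter(.data$retained)
}

#' Catalog size summary
#'
#' @param catalog A site tibble; gene symbols are taken from a `gene` column
#'   or joined from `annotation` by `site_id`.
#' @param annotation Optional annotation table with `site_id` and `gene`.
#' @return A one-row tibble with `n_sites` and `n_genes` (distinct non-empty
#'   gene symbols).
#' @export
catalog_summary <- function(catalog, annotation = NULL) {
  if (!"gene" %in% names(catalog) && !is.null(annotation)) {
    assert_columns(annotation, c("site_id", "gene"), "annotation")
    catalog <- catalog %>%
      left_join(annotation %>% select("site_id", "gene"), by = "site_id")
  }
  genes <- if ("gene" %in% names(catalog)) catalog$gene else character()
  genes <- genes[!is.na(genes) & genes != ""]
  tibble(n_sites = nrow(catalog), n_genes = dplyr::n_distinct(genes))
}
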