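#' Per-record editing level
#'
#' The editing level of a site in a sample is the fraction of reads carrying
#' the edited allele, `alt / (ref + alt)`, reported only at adequate coverage
#' and missing (`NA`) otherwise.
#'
#' @param ref_count,alt_count Non-negative count vectors.
#' @param min_coverage Minimum total reads to report a level (default 10).
#' @return Numeric vector of proportions in \[0, 1\], `NA` below the floor.
#' @export
#' @examples
#' editing_level(c(15, 50, 3), c(5, 0, 2))
editing_level <- function(ref_count, alt_count, min_coverage = 10) {
  total <- ref_count + alt_count
  ifelse(total >= min_coverage, alt_count / total, NA_real_)
}

#' Sites-by-samples editing matrix
#'
#' @param counts Long allele-count tibble.
#' @param min_coverage Coverage floor below which a cell is `NA`.
#' @return A tibble with `site_id` and one numeric column per sample.
#' @export
editing_matrix <- function(counts, min_coverage = 10) {
  assert_columns(counts, c("site_id", "sample_id", "ref_count", "alt_count"),
                 "counts")
  counts %>%
    mutate(level = editing_level(.data$ref_count, .data$alt_count, min_coverage)) %>%
    select("site_id", "sample_id", "level") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "level")
}

#' Sample-wide average editing and edited-site/gene counts
#'
#' For every sample, averages the editing level over catalog sites with
#' adequate coverage (missing cells are skipped), and counts the number of
#' edited sites (level > 0) and edited genes (at least one edited site).
#'
#' @param counts Long allele-count tibble, restricted to the analysis catalog.
#' @param annotation Optional table with `site_id` and `gene`; if absent the
#'   gene is parsed from the `gene:chrom:pos` site-id convention.
#' @param min_coverage Coverage floor (default 10).
#' @return A tibble with one row per sample: `sample_id`, `mean_editing`,
#'   `n_sites`, `n_genes`. Samples with no covered site get `NA` with a
#'   warning.
#' @export
sample_average_editing <- function(counts, annotation = NULL, min_coverage = 10) {
  assert_columns(counts, c("site_id", "sample_id", "ref_count", "alt_count"),
                 "counts")
  tbl <- counts %>%
    mutate(level = editing_level(.data$ref_count, .data$alt_count, min_coverage))
  if (!is.null(annotation)) {
    assert_columns(annotation, c("site_id", "gene"), "annotation")
    tbl <- tbl %>%
      left_join(annotation %>% select("site_id", "gene"), by = "site_id")
  } else {
    tbl <- tbl %>% mutate(gene = sub(":.*$", "", .data$site_id))
  }
  out <- tbl %>%
    group_by(.data$sample_id) %>%
    summarise(
      mean_editing = if (all(is.na(.data$level))) NA_real_
                     else mean(.data$level, na.rm = TRUE),
      n_sites = sum(.data$level > 0, na.rm = TRUE),
      n_genes = dplyr::n_distinct(.data$gene[!is.na(.data$level) & .data$level > 0]),
      .groups = "drop"
    )
  if (any(is.na(out$mean_editing))) {
    warn(sprintf("%d sample(s) have no covered site; mean_editing is NA",
                 sum(is.na(out$mean_editing))))
  }
  out
}

#' Correlation of average editing with edited-site and edited-gene counts
#'
#' Pearson product-moment correlation (with two-sided p) of the per-sample
#' mean editing level against the per-sample numbers of edited sites and of
#' edited genes. Samples with a missing mean are excluded.
#'
#' @param sample_summary Output of [sample_average_editing()].
#' @return A tibble with rows `sites` and `genes`: `metric`, `r`, `p`, `n`.
#'   Zero variance in either vector gives `NA` with a `note`.
#' @export
average_vs_counts_correlation <- function(sample_summary) {
  assert_columns(sample_summary, c("mean_editing", "n_sites", "n_genes"),
                 "sample_summary")
  ok <- !is.na(sample_summary$mean_editing)
  x <- sample_summary$mean_editing[ok]
  if (length(x) < 3) {
    abort("need at least 3 samples with a defined mean editing level",
          class = "aied_validation_error")
  }
  one <- function(y, metric) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(metric = metric, r = NA_real_, p = NA_real_,
                    n = length(x), note = "zero variance"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(metric = metric, r = unname(ct$estimate), p = ct$p.value,
           n = length(x), note = NA_character_)
  }
  bind_rows(
    one(sample_summary$n_sites[ok], "sites"),
    one(sample_summary$n_genes[ok], "genes")
  )
}

#' One-way ANOVA of per-sample average editing across groups
#'
#' Convenience comparison of the sample-wide average editing level between
#' groups, with Tukey HSD post-hoc contrasts.
#'
#' @param sample_summary Output of [sample_average_editing()].
#' @param metadata Metadata with `sample_id` and `group`.
#' @return A list with `p_overall` (ANOVA F-test p for group) and `tukey`
#'   (tibble of pairwise contrasts: `contrast`, `diff`, `p_adj`).
#' @export
anova_editing_by_group <- function(sample_summary, metadata) {
  dat <- sample_summary %>%
    inner_join(metadata %>% select("sample_id", "group"), by = "sample_id") %>%
    filter(!is.na(.data$mean_editing))
  dat$group <- factor(dat$group)
  if (dplyr::n_distinct(dat$group) < 2) {
    abort("need at least two groups", class = "aied_validation_error")
  }
  fit <- aov(mean_editing ~ group, data = dat)
  p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  tukey <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                  p_adj = tk[, "p adj"])
  list(p_overall = p_overall, tukey = tukey)
}
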