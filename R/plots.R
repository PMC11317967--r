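# ggplot2 helpers for the main result types

#' Boxplot of sample-wide average editing by group
#'
#' @param sample_summary Output of [sample_average_editing()].
#' @param metadata Metadata with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_sample_editing <- function(sample_summary, metadata) {
  dat <- sample_summary %>%
    inner_join(metadata %>% select("sample_id", "group"), by = "sample_id") %>%
    filter(!is.na(.data$mean_editing))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean_editing,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5) +
    ggplot2::labs(x = NULL, y = "sample-wide mean editing level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Bar chart of catalog consequence categories
#'
#' @param consequence_summary Output of [summarize_consequences()].
#' @return A ggplot object with percentage labels.
#' @export
plot_consequences <- function(consequence_summary) {
  dat <- consequence_summary %>%
    mutate(consequence = stats::reorder(.data$consequence, .data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$consequence, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sites") +
    ggplot2::theme_minimal()
}

#' Effect-size vs significance plot for a differential-editing result
#'
#' @param object A `dre_result` from [call_dre()].
#' @param ... Unused.
#' @return A ggplot object: maximum group-mean difference against
#'   -log10 p, coloured by call status.
#' @method autoplot dre_result
#' @export
autoplot.dre_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$max_delta,
                               y = -log10(pmax(.data$p_glm, 1e-300)),
                               colour = .data$is_dre)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "differentially\nedited") +
    ggplot2::labs(x = "max group-mean editing difference",
                  y = expression(-log[10] ~ p[GLM])) +
    ggplot2::theme_minimal()
}

#' Group-mean profiles of significant sites by temporal trend
#'
#' @param dre A `dre_result` from a three-group temporal design.
#' @return A ggplot object: per-site group-mean trajectories faceted by trend
#'   cluster.
#' @export
plot_trends <- function(dre) {
  groups <- attr(dre, "groups")
  mean_cols <- paste0("mean_", groups)
  dat <- dre %>%
    filter(.data$is_dre, !is.na(.data$trend), .data$trend != "unclassified") %>%
    select(all_of(c("site_id", "trend", mean_cols))) %>%
    tidyr::pivot_longer(all_of(mean_cols), names_to = "group",
                        values_to = "mean_level") %>%
    mutate(group = factor(sub("^mean_", "", .data$group), levels = groups))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean_level,
                                    group = .data$site_id)) +
    ggplot2::geom_line(alpha = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~trend) +
    ggplot2::labs(x = NULL, y = "group mean editing level") +
    ggplot2::theme_minimal()
}

#' Bar chart of exclusive overlap cells across datasets
#'
#' @param report An `overlap_report` from [overlap_dre_sets()].
#' @return A ggplot object.
#' @export
plot_overlap <- function(report) {
  set_names <- report$per_set$set
  dat <- report$cells %>%
    mutate(cell = apply(across(all_of(set_names)), 1, function(m) {
      paste(set_names[as.logical(m)], collapse = " & ")
    })) %>%
    mutate(cell = stats::reorder(.data$cell, .data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sites in exclusive cell") +
    ggplot2::theme_minimal()
}
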