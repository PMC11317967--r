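# ---- expression normalisation ----------------------------------------------

#' TPM (transcripts per million) normalisation
#'
#' Per sample, divides counts by gene length to get a transcript rate and
#' rescales rates to sum to one million.
#'
#' @param counts Expression tibble: a `gene` column plus one numeric column
#'   per sample.
#' @param gene_lengths A tibble with `gene` and `length` (> 0), or a named
#'   numeric vector.
#' @return A tibble of the same shape with TPM values; every sample column
#'   sums to 1e6 (columns of an all-zero library are zero, with a warning).
#' @export
#' @examples
#' expr <- tibble::tibble(gene = c("a", "b"), s1 = c(100, 100))
#' lens <- tibble::tibble(gene = c("a", "b"), length = c(1000, 2000))
#' tpm_normalize(expr, lens)
tpm_normalize <- function(counts, gene_lengths) {
  assert_columns(counts, "gene", "expression counts")
  if (is.data.frame(gene_lengths)) {
    assert_columns(gene_lengths, c("gene", "length"), "gene_lengths")
    len <- setNames(gene_lengths$length, gene_lengths$gene)
  } else {
    len <- gene_lengths
  }
  len <- unname(len[counts$gene])
  if (any(is.na(len)) || any(len <= 0)) {
    abort("every gene needs a positive length", class = "aied_validation_error")
  }
  sample_cols <- setdiff(names(counts), "gene")
  out <- counts
  zero_lib <- character()
  for (s in sample_cols) {
    rate <- counts[[s]] / len
    total <- sum(rate)
    if (total == 0) {
      zero_lib <- c(zero_lib, s)
      out[[s]] <- rep(0, length(rate))
    } else {
      out[[s]] <- 1e6 * rate / total
    }
  }
  if (length(zero_lib) > 0) {
    warn(sprintf("zero library size in sample(s): %s",
                 paste(zero_lib, collapse = ", ")))
  }
  out
}

# ---- differential expression -----------------------------------------------

#' Per-gene differential expression by count GLM + LRT
#'
#' Fits a negative-binomial (default) or Poisson GLM with log link and a
#' log-library-size offset to each gene's counts and tests the group term by
#' a likelihood-ratio test; p-values are BH-adjusted across genes. For the
#' negative-binomial family the null model is refit at the full model's
#' estimated dispersion.
#'
#' @param counts Expression tibble (`gene` + sample columns of raw counts).
#' @param metadata Metadata with `sample_id` and `group`; every sample column
#'   must appear.
#' @param family `"nb"` (negative binomial, default) or `"poisson"`.
#' @return A tibble `gene`, `p`, `fdr`, `status` (`"ok"`, `"all_zero"`, or
#'   `"fit_failed"`).
#' @export
de_gene_test <- function(counts, metadata, family = c("nb", "poisson")) {
  family <- match.arg(family)
  assert_columns(counts, "gene", "expression counts")
  sample_cols <- setdiff(names(counts), "gene")
  meta <- metadata %>% filter(.data$sample_id %in% sample_cols)
  if (length(setdiff(sample_cols, meta$sample_id)) > 0) {
    abort("every expression column needs a metadata row",
          class = "aied_schema_error")
  }
  grp <- factor(meta$group[match(sample_cols, meta$sample_id)])
  if (nlevels(droplevels(grp)) < 2) {
    abort("need at least two groups", class = "aied_config_error")
  }
  if (min(table(grp)) < 2) {
    abort("inestimable dispersion: need >= 2 samples per group",
          class = "aied_validation_error")
  }
  mat <- as.matrix(counts[, sample_cols])
  lib <- pmax(colSums(mat), 1)
  off <- log(lib)

  fit_gene <- function(y) {
    if (all(y == 0)) return(list(p = NA_real_, status = "all_zero"))
    p <- tryCatch({
      if (family == "nb") {
        full <- suppressWarnings(
          MASS::glm.nb(y ~ grp + offset(off),
                       control = stats::glm.control(maxit = 50))
        )
        null <- suppressWarnings(
          glm(y ~ offset(off),
              family = MASS::negative.binomial(theta = full$theta))
        )
        stat <- max(2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))), 0)
        pchisq(stat, df = nlevels(droplevels(grp)) - 1, lower.tail = FALSE)
      } else {
        full <- glm(y ~ grp + offset(off), family = stats::poisson())
        null <- glm(y ~ offset(off), family = stats::poisson())
        stat <- max(null$deviance - full$deviance, 0)
        pchisq(stat, df = nlevels(droplevels(grp)) - 1, lower.tail = FALSE)
      }
    }, error = function(e) NA_real_)
    list(p = p, status = if (is.na(p)) "fit_failed" else "ok")
  }
  fits <- apply(mat, 1, fit_gene)
  tibble(
    gene = counts$gene,
    p = purrr::map_dbl(fits, "p"),
    status = purrr::map_chr(fits, "status")
  ) %>%
    mutate(fdr = bh_adjust(.data$p)) %>%
    select("gene", "p", "fdr", "status")
}

#' Overlap of differentially edited and differentially expressed genes
#'
#' @param edited_genes Character vector of differentially edited gene symbols.
#' @param de_table Output of [de_gene_test()].
#' @param alpha FDR threshold for calling a gene differentially expressed.
#' @return One-row tibble: `n_edited`, `n_de`, `n_both`, `pct_edited_de`
#'   (percentage of edited genes that are differentially expressed, one
#'   decimal).
#' @export
edited_expressed_overlap <- function(edited_genes, de_table, alpha = 0.05) {
  edited_genes <- unique(edited_genes[!is.na(edited_genes) & edited_genes != ""])
  de_genes <- de_table$gene[!is.na(de_table$fdr) & de_table$fdr < alpha]
  both <- intersect(edited_genes, de_genes)
  tibble(
    n_edited = length(edited_genes),
    n_de = length(de_genes),
    n_both = length(both),
    pct_edited_de = if (length(edited_genes) == 0) NA_real_
                    else round(100 * length(both) / length(edited_genes), 1)
  )
}

# ---- cis-regulatory correlation --------------------------------------------

#' Spearman correlation of site editing level with host-gene expression
#'
#' For each site, rank-correlates (mid-rank ties, two-sided p) its per-sample
#' editing levels with the TPM of its host gene across samples, testing the
#' cis-regulatory association of editing with expression of the edited gene.
#'
#' @param counts Long allele-count tibble for the sites of interest.
#' @param tpm TPM tibble (`gene` + sample columns), e.g. [tpm_normalize()].
#' @param annotation Table with `site_id` and `gene`; if `NULL` the gene is
#'   parsed from the `gene:chrom:pos` site-id convention.
#' @param min_obs Minimum paired non-missing observations (default 5).
#' @param min_coverage Coverage floor for editing levels.
#' @return A tibble `site_id`, `gene`, `rho`, `p`, `n`, `significant`
#'   (p < 0.05), `note`.
#' @export
cis_correlation <- function(counts, tpm, annotation = NULL, min_obs = 5,
                            min_coverage = 10) {
  assert_columns(tpm, "gene", "tpm")
  tbl <- counts %>%
    mutate(level = editing_level(.data$ref_count, .data$alt_count, min_coverage))
  if (!is.null(annotation)) {
    tbl <- tbl %>%
      left_join(annotation %>% select("site_id", "gene"), by = "site_id")
  } else {
    tbl <- tbl %>% mutate(gene = sub(":.*$", "", .data$site_id))
  }
  sample_cols <- setdiff(names(tpm), "gene")
  tpm_long <- tpm %>%
    tidyr::pivot_longer(all_of(sample_cols), names_to = "sample_id",
                        values_to = "tpm")
  paired <- tbl %>%
    inner_join(tpm_long, by = c("gene", "sample_id")) %>%
    filter(!is.na(.data$level))
  one <- function(df) {
    gene <- df$gene[1]
    if (nrow(df) < min_obs) {
      return(tibble(gene = gene, rho = NA_real_, p = NA_real_,
                    n = nrow(df), significant = NA, note = "too few observations"))
    }
    if (sd(df$level) == 0 || sd(df$tpm) == 0) {
      return(tibble(gene = gene, rho = NA_real_, p = NA_real_,
                    n = nrow(df), significant = NA, note = "constant vector"))
    }
    ct <- suppressWarnings(
      cor.test(df$level, df$tpm, method = "spearman", exact = FALSE)
    )
    tibble(gene = gene, rho = unname(ct$estimate),
           p = ct$p.value, n = nrow(df), significant = ct$p.value < 0.05,
           note = NA_character_)
  }
  paired %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(~ one(.x)) %>%
    ungroup()
}

# ---- cross-dataset overlap -------------------------------------------------

#' Venn-style overlap of differential-editing site sets across datasets
#'
#' Computes every exclusive membership cell over k named site-id sets,
#' the sites shared by all sets, and per-set counts of sites shared with at
#' least one other set (the cross-dataset comparison statistic). Duplicate
#' ids within a set are dropped with a warning.
#'
#' @param sets Named list of character vectors of site ids (k >= 2).
#' @return An object of class `overlap_report`: a list with `cells` (tibble:
#'   one logical membership column per set, `n`, and a `sites` list-column),
#'   `in_all` (ids shared by all sets), `per_set` (tibble `set`, `n`,
#'   `n_shared_any`), `n_union`.
#' @export
#' @examples
#' overlap_dre_sets(list(a = c("s1", "s2"), b = c("s2", "s3"), c = "s2"))
overlap_dre_sets <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("sets must be a named list", class = "aied_config_error")
  }
  if (length(sets) < 2) {
    abort("need at least two sets", class = "aied_config_error")
  }
  dup <- vapply(sets, anyDuplicated, integer(1))
  if (any(dup > 0)) {
    warn(sprintf("duplicate ids within set(s) %s were dropped",
                 paste(names(sets)[dup > 0], collapse = ", ")))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, paste, collapse = "/")
  cells <- as_tibble(member) %>%
    mutate(.pattern = pattern, .site = universe) %>%
    group_by(across(all_of(names(sets)))) %>%
    summarise(n = dplyr::n(), sites = list(.data$.site), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n))
  in_all <- universe[rowSums(member) == ncol(member)]
  per_set <- tibble(
    set = names(sets),
    n = unname(vapply(sets, length, integer(1))),
    n_shared_any = unname(vapply(names(sets), function(nm) {
      sum(member[, nm] & rowSums(member) >= 2)
    }, integer(1)))
  )
  structure(list(cells = cells, in_all = in_all, per_set = per_set,
                 n_union = length(universe)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap of %d site sets (union %d sites)\n",
              nrow(x$per_set), x$n_union))
  cat(sprintf("  shared by all sets: %d\n", length(x$in_all)))
  print(x$per_set)
  invisible(x)
}

# ---- treatment rescue ------------------------------------------------------

#' Call treatment rescue of challenge-induced editing changes
#'
#' In a three-group control / challenge / pre-treated-challenge design (e.g.
#' CON, LPS, fullerenol+LPS), a site's editing alteration counts as rescued
#' when (i) challenge vs control differs significantly (two-group binomial GLM
#' LRT, p < `alpha`), (ii) pre-treatment vs challenge differs significantly in
#' the opposite direction, and (iii) the pre-treated mean is closer to control
#' than the challenge mean is.
#'
#' @param counts Long allele-count tibble.
#' @param metadata Metadata with `sample_id` and `group`.
#' @param groups Length-3 character vector naming the control, challenge and
#'   pre-treated groups, in that order.
#' @param alpha Significance threshold for both contrasts (default 0.05).
#' @param min_coverage Coverage floor for group means.
#' @return A tibble with `site_id`, per-group means, `p_challenge`,
#'   `p_treatment`, `delta_challenge`, `delta_treatment`, `rescued`.
#' @export
rescue_call <- function(counts, metadata, groups = c("CON", "LPS", "FUL"),
                        alpha = 0.05, min_coverage = 10) {
  assert_columns(metadata, c("sample_id", "group"), "metadata")
  if (length(groups) != 3) {
    abort("groups must name exactly three groups", class = "aied_config_error")
  }
  meta <- metadata %>% filter(.data$group %in% groups)
  if (!setequal(unique(as.character(meta$group)), groups)) {
    abort("metadata does not contain the three requested groups",
          class = "aied_config_error")
  }
  if (min(table(factor(meta$group, levels = groups))) < 2) {
    abort("need at least two samples per group", class = "aied_validation_error")
  }
  grp_of <- setNames(as.character(meta$group), meta$sample_id)
  counts <- counts %>% filter(.data$sample_id %in% meta$sample_id)

  one <- function(df) {
    g <- grp_of[df$sample_id]
    lev <- editing_level(df$ref_count, df$alt_count, min_coverage)
    gm <- tapply(lev, factor(g, levels = groups),
                 function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    two_group <- function(a, b) {
      sel <- g %in% c(a, b)
      tryCatch(
        glm_lrt_site(df$alt_count[sel], df$ref_count[sel],
                     factor(g[sel], levels = c(a, b)))$p_glm,
        error = function(e) NA_real_
      )
    }
    p_chal <- two_group(groups[1], groups[2])
    p_trt <- two_group(groups[2], groups[3])
    d_chal <- gm[[2]] - gm[[1]]
    d_trt <- gm[[3]] - gm[[2]]
    rescued <- !is.na(p_chal) && !is.na(p_trt) &&
      !any(is.na(gm)) &&
      p_chal < alpha && p_trt < alpha &&
      sign(d_trt) == -sign(d_chal) &&
      abs(gm[[3]] - gm[[1]]) < abs(gm[[2]] - gm[[1]])
    tibble(!!!setNames(as.list(as.numeric(gm)), paste0("mean_", groups)),
           p_challenge = p_chal, p_treatment = p_trt,
           delta_challenge = unname(d_chal), delta_treatment = unname(d_trt),
           rescued = rescued)
  }
  counts %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(~ one(.x)) %>%
    ungroup()
}
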