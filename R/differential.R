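# ---- internal binomial GLM machinery --------------------------------------

# IRLS fit via stats::glm.fit on (alt, ref) successes/failures with logit link
fit_binom <- function(X, alt, ref) {
  n <- alt + ref
  fit <- suppressWarnings(
    glm.fit(X, alt / n, weights = n, family = binomial())
  )
  list(deviance = fit$deviance, converged = isTRUE(fit$converged),
       coef = fit$coefficients, mu = fit$fitted.values)
}

# LRT for dropping the columns `drop_cols` from the full design; reports the
# chi-square p and, for overdispersed data, a quasi-binomial F-test p based on
# the Pearson dispersion of the full model
lrt_drop <- function(X, drop_cols, alt, ref) {
  full <- fit_binom(X, alt, ref)
  null <- fit_binom(X[, -drop_cols, drop = FALSE], alt, ref)
  stat <- max(null$deviance - full$deviance, 0)
  df <- length(drop_cols)
  n <- alt + ref
  y <- alt / n
  mu <- pmin(pmax(full$mu, 1e-10), 1 - 1e-10)
  df_resid <- length(alt) - ncol(X)
  phi <- if (df_resid > 0) {
    sum(n * (y - mu)^2 / (mu * (1 - mu))) / df_resid
  } else {
    NA_real_
  }
  p_quasi <- if (df_resid > 0 && !is.na(phi)) {
    stats::pf((stat / df) / max(phi, 1e-8), df, df_resid, lower.tail = FALSE)
  } else {
    NA_real_
  }
  list(
    p = pchisq(stat, df = df, lower.tail = FALSE),
    p_quasi = p_quasi, phi = phi,
    stat = stat, df = df,
    deviance_full = full$deviance, deviance_null = null$deviance,
    coef = full$coef,
    converged = full$converged && null$converged
  )
}

# ---- exported per-site GLM + LRT -------------------------------------------

#' Binomial GLM likelihood-ratio test for a group effect at one site
#'
#' Fits a binomial GLM with logit link to the per-sample (alt, ref) read
#' counts of a single site, with editing level modelled as intercept + group
#' (+ optional age and sex covariates), and tests the group term by a
#' chi-square likelihood-ratio test with `#groups - 1` degrees of freedom.
#'
#' Degenerate inputs (identical editing proportions in every sample, or no
#' edited/unedited reads anywhere) carry no group information and are reported
#' as `p_glm = 1` with a flag rather than an error; non-convergence yields a
#' missing p with a flag.
#'
#' @param alt,ref Per-sample edited and unedited read counts.
#' @param group Group factor (>= 2 levels, each with >= 2 samples carrying
#'   reads).
#' @param age,sex Optional two-level covariate vectors.
#' @param dispersion_correction If `TRUE`, replace the chi-square LRT p by a
#'   quasi-binomial F-test using the Pearson dispersion of the full model
#'   (useful for overdispersed allele counts; default `FALSE`, the plain
#'   binomial LRT).
#' @param n_perm If > 0, additionally compute a permutation p-value for the
#'   group term by refitting under `n_perm` random relabelings of `group`
#'   (reported as `p_perm`; the analytic `p_glm` is unchanged).
#' @return An object of class `editing_glm` with elements `p_glm`, `df`,
#'   `statistic`, `deviance_full`, `deviance_null`, `coefficients`,
#'   `group_means`, `n_samples`, `converged`, `flag`, `dispersion` and
#'   (when requested) `p_perm`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' glm_lrt_site(alt = c(10, 12, 28, 30), ref = c(90, 88, 72, 70),
#'              group = factor(c("a", "a", "b", "b")))
glm_lrt_site <- function(alt, ref, group, age = NULL, sex = NULL,
                         dispersion_correction = FALSE, n_perm = 0) {
  keep <- (alt + ref) > 0
  alt <- alt[keep]; ref <- ref[keep]
  group <- droplevels(factor(group[keep]))
  dat <- data.frame(group = group)
  if (!is.null(age)) dat$age <- factor(age[keep])
  if (!is.null(sex)) dat$sex <- factor(sex[keep])
  if (nlevels(group) < 2) {
    abort("need at least two groups with reads", class = "aied_validation_error")
  }
  if (min(table(group)) < 2) {
    abort("need at least two covered samples per group",
          class = "aied_validation_error")
  }
  X <- model.matrix(stats::reformulate(names(dat)), dat)
  group_cols <- which(attr(X, "assign") == 1)

  lev <- alt / (alt + ref)
  group_means <- tapply(lev, group, mean)
  flag <- NA_character_
  degenerate <- sum(alt) == 0 || sum(ref) == 0 ||
    all(abs(lev - lev[1]) < 1e-12)
  if (degenerate) {
    res <- list(p = 1, p_quasi = 1, phi = NA_real_, stat = 0,
                df = length(group_cols),
                deviance_full = NA_real_, deviance_null = NA_real_,
                coef = NULL, converged = TRUE)
    flag <- "degenerate"
  } else {
    res <- lrt_drop(X, group_cols, alt, ref)
    if (dispersion_correction) res$p <- res$p_quasi
    if (!res$converged) {
      res$p <- NA_real_
      flag <- "nonconverged"
    }
  }
  p_perm <- NULL
  if (n_perm > 0) {
    stat_perm <- vapply(seq_len(n_perm), function(i) {
      Xp <- X
      perm <- sample.int(length(alt))
      Xp[, group_cols] <- X[perm, group_cols, drop = FALSE]
      if (degenerate) 0 else lrt_drop(Xp, group_cols, alt, ref)$stat
    }, numeric(1))
    p_perm <- (1 + sum(stat_perm >= res$stat - 1e-12)) / (n_perm + 1)
  }
  structure(list(
    p_glm = res$p, df = res$df, statistic = res$stat,
    deviance_full = res$deviance_full, deviance_null = res$deviance_null,
    coefficients = res$coef, group_means = group_means,
    n_samples = length(alt), converged = res$converged, flag = flag,
    dispersion = res$phi, p_perm = p_perm
  ), class = "editing_glm")
}

#' @export
print.editing_glm <- function(x, ...) {
  cat("Binomial GLM likelihood-ratio test (group effect)\n")
  cat(sprintf("  LRT statistic = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_glm))
  cat("  group means:",
      paste(sprintf("%s = %.4f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- Fisher confirmation on pooled alleles ---------------------------------

#' Fisher exact test on group-pooled allele counts
#'
#' Pools reference and alternative read counts within each group and tests
#' the resulting 2 x K contingency table. K = 2 uses the standard two-sided
#' hypergeometric test; K > 2 uses exact enumeration (Freeman-Halton) while
#' the table total stays within `exact_total`, and a seeded Monte-Carlo
#' approximation (`B` draws) beyond it.
#'
#' @param ref_totals,alt_totals Per-group pooled reference and alternative
#'   counts (same length, K >= 2). Groups with zero total reads are dropped
#'   with a warning.
#' @param exact_total Largest table total for which K > 2 tables are
#'   enumerated exactly.
#' @param B Monte-Carlo replicates beyond the enumeration budget.
#' @return A list with `p_value` and `method` (`"exact"` or `"monte-carlo"`);
#'   `p_value` is `NA` if fewer than two groups carry reads.
#' @export
#' @examples
#' fisher_pooled(ref_totals = c(90, 50), alt_totals = c(10, 50))
fisher_pooled <- function(ref_totals, alt_totals, exact_total = 500, B = 1e5) {
  stopifnot(length(ref_totals) == length(alt_totals))
  tot <- ref_totals + alt_totals
  if (any(tot == 0)) {
    warn(sprintf("dropping %d group(s) with zero total reads", sum(tot == 0)))
    ref_totals <- ref_totals[tot > 0]
    alt_totals <- alt_totals[tot > 0]
  }
  if (length(ref_totals) < 2) {
    return(list(p_value = NA_real_, method = NA_character_))
  }
  tab <- rbind(ref = ref_totals, alt = alt_totals)
  if (ncol(tab) == 2 || sum(tab) <= exact_total) {
    ft <- fisher.test(tab, workspace = 2e7)
    list(p_value = ft$p.value, method = "exact")
  } else {
    ft <- fisher.test(tab, simulate.p.value = TRUE, B = B)
    list(p_value = ft$p.value, method = "monte-carlo")
  }
}

# ---- BH adjustment ---------------------------------------------------------

#' Benjamini-Hochberg step-up adjustment with missing-value handling
#'
#' Missing p-values are excluded from the adjustment (they do not count
#' towards the number of tests) and reinserted as missing.
#'
#' @param p Numeric vector of p-values in \[0, 1\], possibly with `NA`s.
#' @return Adjusted values, capped at 1, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "aied_validation_error")
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# ---- inclusion mask --------------------------------------------------------

#' Sites eligible for differential-editing testing
#'
#' A site enters the group comparison when its mean editing level reaches
#' `threshold` in at least one design subgroup (group x age x sex cell, or
#' group alone without covariates).
#'
#' @inheritParams high_confidence_filter
#' @return Character vector of included `site_id`s.
#' @export
dre_inclusion_mask <- function(counts, metadata, threshold = 0.05,
                               min_coverage = 10, subgroup_by = NULL) {
  scheme <- subgroup_scheme(metadata, by = subgroup_by)
  counts %>%
    left_join(scheme, by = "sample_id") %>%
    mutate(level = editing_level(.data$ref_count, .data$alt_count, min_coverage)) %>%
    filter(!is.na(.data$level)) %>%
    group_by(.data$site_id, .data$subgroup) %>%
    summarise(m = mean(.data$level), .groups = "drop") %>%
    group_by(.data$site_id) %>%
    summarise(included = any(.data$m >= threshold), .groups = "drop") %>%
    filter(.data$included) %>%
    pull("site_id")
}

# ---- trend classification --------------------------------------------------

#' Temporal trend label from three-group means
#'
#' Classifies the control / D1 / D4 mean editing pattern of a site into the
#' three temporal clusters: transient early upregulation
#' (`early_up_then_down`: up at D1, back down by D4), late upregulation
#' (`late_up`: highest at D4), or downregulation at both time points
#' (`down`). Patterns matching none of the rules, including exact ties, are
#' `unclassified`.
#'
#' @param mean_control,mean_d1,mean_d4 Numeric vectors of group means.
#' @return Character vector of trend labels.
#' @export
#' @examples
#' trend_cluster(0.10, 0.20, 0.12)
trend_cluster <- function(mean_control, mean_d1, mean_d4) {
  dplyr::case_when(
    is.na(mean_control) | is.na(mean_d1) | is.na(mean_d4) ~ NA_character_,
    mean_d1 > mean_control & mean_d4 < mean_d1 ~ "early_up_then_down",
    mean_d4 > mean_control & mean_d4 >= mean_d1 ~ "late_up",
    mean_d1 < mean_control & mean_d4 < mean_control ~ "down",
    TRUE ~ "unclassified"
  )
}

# ---- the two-stage DRE caller ----------------------------------------------

#' Call differential RNA editing across groups
#'
#' The two-stage differential-editing procedure: per site, a binomial GLM
#' likelihood-ratio test of the group term gives `p_glm`; sites with
#' `p_glm < 0.05` additionally receive a Fisher exact test on the
#' group-pooled allele counts (`p_fisher`); `p_glm` is BH-adjusted across
#' tested sites. A site is called differentially edited when
#' `fdr < alpha_fdr` and `p_fisher < fisher_alpha`. With `fdr_mode = "off"`
#' (the cross-dataset comparison mode) the call is made at raw
#' `p_glm < alpha_fdr` instead, leaving multiple-testing to the set
#' comparison.
#'
#' Group means, the maximum pairwise group-mean difference (`max_delta`) and
#' its >= 5-percentage-point flag are reported for every tested site; for the
#' three-group temporal design the trend label (see [trend_cluster()]) is
#' assigned to significant sites.
#'
#' @param counts Long allele-count tibble restricted to the analysis catalog.
#' @param metadata Metadata with `sample_id`, `group` (factor, reference
#'   first) and any covariate columns.
#' @param threshold Subgroup-mean inclusion threshold (see
#'   [dre_inclusion_mask()]); `NULL` skips inclusion filtering.
#' @param min_coverage Coverage floor for editing levels and group means.
#' @param alpha_fdr FDR threshold for the GLM stage (raw-p threshold when
#'   `fdr_mode = "off"`).
#' @param fisher_alpha Threshold on the Fisher confirmation p.
#' @param fdr_mode `"bh"` (default) or `"off"`.
#' @param covariates Character subset of `c("age", "sex")` to adjust the GLM
#'   for, or `NULL`.
#' @param subgroup_by Explicit subgroup columns for the inclusion mask.
#' @param dispersion_correction Use the quasi-binomial F-test instead of the
#'   chi-square LRT at the GLM stage (default `FALSE`).
#' @param exact_total,mc_B Passed to [fisher_pooled()].
#' @param seed Optional seed for the Monte-Carlo Fisher fallback.
#' @return A tibble of class `dre_result`, one row per tested site:
#'   `site_id`, `p_glm`, `fdr`, `p_fisher`, `fisher_method`, one
#'   `mean_<group>` column per group, `max_delta`, `delta5_flag`, `is_dre`,
#'   `trend`, `glm_flag`, `n_samples`.
#' @export
call_dre <- function(counts, metadata, threshold = 0.05, min_coverage = 10,
                     alpha_fdr = 0.05, fisher_alpha = 0.05,
                     fdr_mode = c("bh", "off"), covariates = NULL,
                     subgroup_by = NULL, dispersion_correction = FALSE,
                     exact_total = 500, mc_B = 1e5,
                     seed = NULL) {
  fdr_mode <- match.arg(fdr_mode)
  if (!is.null(seed)) set.seed(seed)
  assert_columns(counts, c("site_id", "sample_id", "ref_count", "alt_count"),
                 "counts")
  assert_columns(metadata, c("sample_id", "group"), "metadata")
  meta <- metadata %>% mutate(group = factor(.data$group))
  groups <- levels(meta$group)
  if (length(groups) < 2) {
    abort("need at least two groups", class = "aied_config_error")
  }
  if (!is.null(covariates)) {
    covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
    assert_columns(meta, covariates, "metadata")
  }

  if (!is.null(threshold)) {
    keep_sites <- dre_inclusion_mask(counts, meta, threshold = threshold,
                                     min_coverage = min_coverage,
                                     subgroup_by = subgroup_by)
    counts <- counts %>% filter(.data$site_id %in% keep_sites)
  }
  if (nrow(counts) == 0) {
    abort("no sites pass the inclusion mask", class = "aied_validation_error")
  }

  # one shared design matrix over metadata rows; per site we subset its rows
  terms <- c("group", covariates)
  X_all <- model.matrix(stats::reformulate(terms), data = meta)
  group_cols <- which(attr(X_all, "assign") == 1)
  meta_row <- setNames(seq_len(nrow(meta)), meta$sample_id)

  per_site <- counts %>%
    mutate(.row = meta_row[.data$sample_id]) %>%
    group_by(.data$site_id)
  site_ids <- dplyr::group_keys(per_site)$site_id
  chunks <- dplyr::group_split(per_site)

  fit_one <- function(df) {
    keep <- (df$ref_count + df$alt_count) > 0 & !is.na(df$.row)
    df <- df[keep, , drop = FALSE]
    alt <- df$alt_count; ref <- df$ref_count
    rows <- df$.row
    grp <- droplevels(meta$group[rows])
    lev <- editing_level(ref, alt, min_coverage)
    gm <- tapply(lev, factor(meta$group[rows], levels = groups),
                 function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    gm <- as.numeric(gm[groups])
    p <- NA_real_; flag <- NA_character_
    rawlev <- alt / (alt + ref)
    if (nlevels(grp) < 2 || min(table(grp)) < 2) {
      flag <- "insufficient"
    } else if (sum(alt) == 0 || sum(ref) == 0 ||
               all(abs(rawlev - rawlev[1]) < 1e-12)) {
      p <- 1; flag <- "degenerate"
    } else {
      X <- X_all[rows, , drop = FALSE]
      res <- lrt_drop(X, group_cols, alt, ref)
      if (res$converged) {
        p <- if (dispersion_correction) res$p_quasi else res$p
      } else {
        flag <- "nonconverged"
      }
    }
    pooled_ref <- tapply(ref, factor(meta$group[rows], levels = groups), sum)
    pooled_alt <- tapply(alt, factor(meta$group[rows], levels = groups), sum)
    list(p_glm = p, flag = flag, group_means = gm, n_samples = nrow(df),
         pooled_ref = as.numeric(ifelse(is.na(pooled_ref), 0, pooled_ref)),
         pooled_alt = as.numeric(ifelse(is.na(pooled_alt), 0, pooled_alt)))
  }
  fits <- purrr::map(chunks, fit_one)

  p_glm <- purrr::map_dbl(fits, "p_glm")
  fdr <- bh_adjust(p_glm)
  needs_fisher <- !is.na(p_glm) & p_glm < 0.05
  fisher <- purrr::map(seq_along(fits), function(i) {
    if (!needs_fisher[i]) {
      return(list(p_value = NA_real_, method = NA_character_))
    }
    suppressWarnings(
      fisher_pooled(fits[[i]]$pooled_ref, fits[[i]]$pooled_alt,
                    exact_total = exact_total, B = mc_B)
    )
  })

  gm_mat <- do.call(rbind, purrr::map(fits, "group_means"))
  colnames(gm_mat) <- paste0("mean_", groups)
  max_delta <- apply(gm_mat, 1, function(m) {
    if (any(is.na(m))) return(NA_real_)
    max(stats::dist(m))
  })

  p_fisher <- purrr::map_dbl(fisher, "p_value")
  is_dre <- if (fdr_mode == "bh") {
    !is.na(fdr) & fdr < alpha_fdr & !is.na(p_fisher) & p_fisher < fisher_alpha
  } else {
    !is.na(p_glm) & p_glm < alpha_fdr
  }

  out <- tibble(site_id = site_ids, p_glm = p_glm, fdr = fdr,
                p_fisher = p_fisher,
                fisher_method = purrr::map_chr(fisher, "method"),
                as_tibble(gm_mat),
                max_delta = max_delta,
                delta5_flag = !is.na(max_delta) & max_delta >= 0.05,
                is_dre = is_dre,
                glm_flag = purrr::map_chr(fits, "flag"),
                n_samples = purrr::map_int(fits, "n_samples"))
  if (length(groups) == 3) {
    tr <- trend_cluster(gm_mat[, 1], gm_mat[, 2], gm_mat[, 3])
    out$trend <- ifelse(out$is_dre, tr, NA_character_)
  } else {
    out$trend <- NA_character_
  }
  structure(out, class = c("dre_result", class(out)),
            groups = groups, fdr_mode = fdr_mode, alpha_fdr = alpha_fdr)
}

# ---- covariate effects -----------------------------------------------------

#' Age and sex covariate effects at individual sites
#'
#' For each site, fits the full binomial GLM intercept + group + age + sex and
#' reports the 1-df likelihood-ratio p-value for dropping age (`p_age`) and
#' for dropping sex (`p_sex`). A covariate that is constant across samples is
#' inestimable and reported as missing with a note.
#'
#' @param counts Long allele-count tibble (typically restricted to sites of
#'   interest, e.g. the differential sites).
#' @param metadata Metadata with `sample_id`, `group`, `age`, `sex`.
#' @param sites Optional character vector restricting the sites tested.
#' @return A tibble with `site_id`, `p_age`, `p_sex`, `note`.
#' @export
covariate_effects <- function(counts, metadata, sites = NULL) {
  assert_columns(metadata, c("sample_id", "group", "age", "sex"), "metadata")
  if (!is.null(sites)) counts <- counts %>% filter(.data$site_id %in% sites)
  if (nrow(counts) == 0) {
    return(tibble(site_id = character(), p_age = numeric(),
                  p_sex = numeric(), note = character()))
  }
  meta <- metadata %>%
    mutate(group = factor(.data$group), age = factor(.data$age),
           sex = factor(.data$sex))
  age_ok <- nlevels(droplevels(meta$age)) >= 2
  sex_ok <- nlevels(droplevels(meta$sex)) >= 2
  terms <- c("group", if (age_ok) "age", if (sex_ok) "sex")
  X_all <- model.matrix(stats::reformulate(terms), data = meta)
  assign <- attr(X_all, "assign")
  age_cols <- which(assign == match("age", terms))
  sex_cols <- which(assign == match("sex", terms))
  meta_row <- setNames(seq_len(nrow(meta)), meta$sample_id)

  per_site <- counts %>%
    mutate(.row = meta_row[.data$sample_id]) %>%
    group_by(.data$site_id)
  site_ids <- dplyr::group_keys(per_site)$site_id
  chunks <- dplyr::group_split(per_site)

  one <- function(df) {
    keep <- (df$ref_count + df$alt_count) > 0 & !is.na(df$.row)
    df <- df[keep, , drop = FALSE]
    X <- X_all[df$.row, , drop = FALSE]
    rawlev <- df$alt_count / (df$alt_count + df$ref_count)
    degenerate <- sum(df$alt_count) == 0 || sum(df$ref_count) == 0 ||
      all(abs(rawlev - rawlev[1]) < 1e-12)
    p_for <- function(cols, ok) {
      if (!ok) return(NA_real_)
      if (degenerate) return(1)
      lrt_drop(X, cols, df$alt_count, df$ref_count)$p
    }
    note <- if (!age_ok && !sex_ok) "age and sex constant"
            else if (!age_ok) "age constant"
            else if (!sex_ok) "sex constant"
            else NA_character_
    tibble(p_age = p_for(age_cols, age_ok), p_sex = p_for(sex_cols, sex_ok),
           note = note)
  }
  bind_rows(purrr::map(chunks, one)) %>%
    mutate(site_id = site_ids) %>%
    select("site_id", "p_age", "p_sex", "note")
}
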