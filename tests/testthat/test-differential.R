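test_that("the group LRT is 1 for data with no group information", {
  g <- factor(rep(c("a", "b"), each = 4))
  fit <- glm_lrt_site(alt = rep(10, 8), ref = rep(90, 8), group = g)
  expect_equal(fit$p_glm, 1)
  expect_equal(fit$flag, "degenerate")
  # all-zero alternative counts likewise
  fit0 <- glm_lrt_site(alt = rep(0, 8), ref = rep(50, 8), group = g)
  expect_equal(fit0$p_glm, 1)
  # preconditions
  expect_error(glm_lrt_site(1:4, 5:8, factor(rep("a", 4))),
               class = "aied_validation_error")
  expect_error(glm_lrt_site(1:3, c(9, 9, 9), factor(c("a", "a", "b"))),
               class = "aied_validation_error")
})

test_that("the site GLM matches an independent IRLS oracle", {
  fit <- glm_lrt_site(alt = c(10, 10, 10, 10, 30, 30, 30, 30),
                      ref = c(90, 90, 90, 90, 70, 70, 70, 70),
                      group = factor(rep(c("a", "b"), each = 4)))
  orc <- oracle_glm_lrt(c(10, 10, 10, 10, 30, 30, 30, 30),
                        c(90, 90, 90, 90, 70, 70, 70, 70),
                        rep(c("a", "b"), each = 4))
  expect_equal(fit$p_glm, orc$p, tolerance = 1e-9)
  expect_lt(abs(fit$deviance_full - orc$deviance_full), 1e-6)
  expect_lt(abs(fit$deviance_null - orc$deviance_null), 1e-6)

  # random two- and three-group fixtures
  withr::with_seed(17, {
    for (i in 1:15) {
      k <- sample(2:3, 1)
      n_per <- sample(3:6, 1)
      g <- rep(letters[1:k], each = n_per)
      cov <- rpois(k * n_per, 60) + 10
      p_true <- runif(k, 0.05, 0.5)[match(g, letters[1:k])]
      alt <- rbinom(k * n_per, cov, p_true)
      alt <- pmin(pmax(alt, 1), cov - 1)   # avoid boundary fits in the check
      fit <- glm_lrt_site(alt, cov - alt, factor(g))
      orc <- oracle_glm_lrt(alt, cov - alt, g)
      expect_lt(abs(fit$deviance_full - orc$deviance_full), 1e-6)
      expect_equal(fit$p_glm, orc$p, tolerance = 1e-6)
    }
  })
})

test_that("tidy and glance expose the per-site fit", {
  fit <- glm_lrt_site(alt = c(10, 12, 28, 30), ref = c(90, 88, 72, 70),
                      group = factor(rep(c("a", "b"), each = 2)))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "groupb"))
  gl <- glance(fit)
  expect_equal(gl$p_glm, fit$p_glm)
  expect_true(gl$converged)
})

test_that("pooled Fisher test handles trivial and degenerate tables", {
  expect_equal(fisher_pooled(c(90, 90), c(10, 10))$p_value, 1)
  expect_warning(res <- fisher_pooled(c(90, 0), c(10, 0)), "zero total")
  expect_true(is.na(res$p_value))
  # identical 3-group table
  expect_equal(fisher_pooled(c(90, 90, 90), c(10, 10, 10))$p_value, 1)
})

test_that("pooled Fisher equals brute-force enumeration on random tables", {
  withr::with_seed(23, {
    for (i in 1:40) {
      k <- sample(2:3, 1)
      repeat {
        tab <- matrix(rpois(2 * k, sample(5:40, 1)), nrow = 2)
        if (all(colSums(tab) > 0) && all(rowSums(tab) > 0) &&
            sum(tab) <= 200) break
      }
      got <- fisher_pooled(tab[1, ], tab[2, ])
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, oracle_fisher_enum(tab), tolerance = 1e-7)
    }
  })
})

test_that("the Monte-Carlo Fisher fallback is seeded and close to exact", {
  tab <- matrix(c(900, 100, 850, 150, 820, 180), nrow = 2)
  set.seed(5)
  a <- fisher_pooled(tab[1, ], tab[2, ], exact_total = 100, B = 2e4)
  set.seed(5)
  b <- fisher_pooled(tab[1, ], tab[2, ], exact_total = 100, B = 2e4)
  expect_equal(a$method, "monte-carlo")
  expect_identical(a$p_value, b$p_value)
  exact <- fisher_pooled(tab[1, ], tab[2, ], exact_total = 1e5)
  expect_lt(abs(a$p_value - exact$p_value), 0.02)
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  p_na <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "aied_validation_error")

  withr::with_seed(3, {
    for (i in 1:10) {
      p <- runif(50)^2
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-12))          # adjusted >= raw
      expect_true(all(adj <= 1))
      expect_equal(order(adj[order(p)]), 1:50)    # ranking preserved
    }
  })
})

test_that("the inclusion mask keeps sites reaching 5% in some subgroup", {
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                         group = rep(c("a", "b"), each = 2))
  mk <- function(levs) {
    tibble::tibble(site_id = "x", sample_id = meta$sample_id,
                   alt_count = as.integer(levs * 100),
                   ref_count = as.integer(100 - levs * 100))
  }
  expect_length(dre_inclusion_mask(mk(rep(0.02, 4)), meta), 0)
  expect_equal(dre_inclusion_mask(mk(c(0.05, 0.05, 0.02, 0.02)), meta), "x")
  # matches levels recomputed from the generator truth on a null study
  cfg <- sim_config(n_sites = 150, frac_dre = 0, effect_size = 0,
                    frac_age_effect = 0, frac_sex_effect = 0,
                    dispersion = 0, seed = 13)
  study <- simulate_study(cfg)
  mask <- dre_inclusion_mask(study$counts, study$metadata)
  scheme <- subgroup_scheme(study$metadata)
  expected <- study$counts %>%
    dplyr::left_join(scheme, by = "sample_id") %>%
    dplyr::mutate(level = ifelse(ref_count + alt_count >= 10,
                                 alt_count / (ref_count + alt_count), NA_real_)) %>%
    dplyr::filter(!is.na(level)) %>%
    dplyr::group_by(site_id, subgroup) %>%
    dplyr::summarise(m = mean(level), .groups = "drop_last") %>%
    dplyr::summarise(inc = any(m >= 0.05), .groups = "drop")
  expect_setequal(mask, expected$site_id[expected$inc])
})

test_that("trend rules transcribe the three temporal patterns", {
  expect_equal(trend_cluster(0.10, 0.20, 0.12), "early_up_then_down")
  expect_equal(trend_cluster(0.10, 0.11, 0.25), "late_up")
  expect_equal(trend_cluster(0.20, 0.10, 0.08), "down")
  expect_equal(trend_cluster(0.10, 0.10, 0.10), "unclassified")
  expect_equal(trend_cluster(0.10, 0.05, 0.20), "late_up")
  expect_equal(trend_cluster(0.10, 0.10, 0.05), "unclassified")  # tie at D1
  expect_true(is.na(trend_cluster(NA, 0.2, 0.1)))
  # rule table is exhaustive: every finite triple gets exactly one label
  withr::with_seed(6, {
    m <- matrix(runif(300), ncol = 3)
    labs <- trend_cluster(m[, 1], m[, 2], m[, 3])
    expect_true(all(labs %in% c("early_up_then_down", "late_up", "down",
                                "unclassified")))
  })
})

test_that("call_dre never calls a site with identical data in all groups", {
  study <- small_study()
  meta <- study$metadata
  flat <- tibble::tibble(
    site_id = "flat:chr9:9", chrom = "chr9", pos = 9L, strand = "+",
    ref = "A", alt = "G", sample_id = meta$sample_id,
    ref_count = 80L, alt_count = 20L
  )
  res <- call_dre(flat, meta, threshold = NULL)
  expect_equal(res$p_glm, 1)
  expect_false(res$is_dre)
  expect_equal(res$glm_flag, "degenerate")
})

test_that("two-stage DRE calls recover simulated effects on a small study", {
  cfg <- sim_config(n_sites = 150, frac_dre = 0.25, effect_size = 0.12,
                    coverage_mean = 60, dispersion = 0,
                    frac_age_effect = 0, frac_sex_effect = 0, seed = 77)
  study <- simulate_study(cfg)
  res <- call_dre(study$counts, study$metadata, seed = 1)
  truth <- study$truth[match(res$site_id, study$truth$site_id), ]
  sens <- mean(res$is_dre[truth$is_dre])
  fdp <- if (sum(res$is_dre) > 0) mean(!truth$is_dre[res$is_dre]) else 0
  expect_gt(sens, 0.7)
  expect_lt(fdp, 0.2)
  # invariants of the result table
  expect_true(all(res$p_glm >= 0 & res$p_glm <= 1, na.rm = TRUE))
  expect_true(all(res$fdr >= res$p_glm - 1e-12, na.rm = TRUE))
  expect_true(all(is.na(res$trend) | res$is_dre))
  expect_equal(res$delta5_flag, !is.na(res$max_delta) & res$max_delta >= 0.05)
  # Fisher p present exactly where the GLM stage triggered it
  expect_equal(!is.na(res$p_fisher), !is.na(res$p_glm) & res$p_glm < 0.05)
})

test_that("fdr_mode = off calls at raw p and is a superset of the BH calls", {
  cfg <- sim_config(n_sites = 100, frac_dre = 0.2, coverage_mean = 60,
                    frac_age_effect = 0, frac_sex_effect = 0, seed = 15)
  study <- simulate_study(cfg)
  with_bh <- call_dre(study$counts, study$metadata, seed = 1)
  without <- call_dre(study$counts, study$metadata, fdr_mode = "off", seed = 1)
  expect_equal(without$is_dre, !is.na(without$p_glm) & without$p_glm < 0.05)
  expect_true(all(with_bh$site_id[with_bh$is_dre] %in%
                    without$site_id[without$is_dre]))
})

test_that("covariate effects are reported per site and flag inestimable ones", {
  study <- small_study()
  some_sites <- head(study$truth$site_id, 4)
  cov <- covariate_effects(study$counts, study$metadata, sites = some_sites)
  expect_equal(sort(cov$site_id), sort(some_sites))
  expect_true(all(cov$p_age >= 0 & cov$p_age <= 1))
  expect_true(all(cov$p_sex >= 0 & cov$p_sex <= 1))

  # all-female study: sex is inestimable
  meta_f <- dplyr::mutate(study$metadata, sex = "female")
  cov_f <- covariate_effects(study$counts, meta_f, sites = some_sites)
  expect_true(all(is.na(cov_f$p_sex)))
  expect_equal(unique(cov_f$note), "sex constant")
  expect_true(all(!is.na(cov_f$p_age)))
})

test_that("simulated age effects drive p_age but not p_sex", {
  cfg <- sim_config(n_sites = 60, frac_dre = 0, effect_size = 0,
                    frac_age_effect = 1, frac_sex_effect = 0,
                    age_effect_size = 0.15, dispersion = 0, seed = 19)
  study <- simulate_study(cfg)
  cov <- covariate_effects(study$counts, study$metadata)
  expect_gt(mean(cov$p_age < 0.05), 0.8)
  expect_lt(mean(cov$p_sex < 0.05), 0.2)
})

test_that("the quasi-binomial correction restores calibration under overdispersion", {
  cfg <- sim_config(n_sites = 300, frac_dre = 0, effect_size = 0,
                    frac_age_effect = 0, frac_sex_effect = 0,
                    coverage_mean = 50, dispersion = 0.01, seed = 909)
  study <- simulate_study(cfg)
  plain <- call_dre(study$counts, study$metadata, seed = 1)
  quasi <- call_dre(study$counts, study$metadata, seed = 1,
                    dispersion_correction = TRUE)
  rate_plain <- mean(plain$p_glm < 0.05, na.rm = TRUE)
  rate_quasi <- mean(quasi$p_glm < 0.05, na.rm = TRUE)
  expect_gt(rate_plain, 0.09)   # binomial LRT is anti-conservative here
  expect_lt(rate_quasi, 0.09)   # the F-test brings it back near nominal
})

test_that("permutation p-values agree with the obvious cases", {
  g <- factor(rep(c("a", "b"), each = 4))
  set.seed(2)
  strong <- glm_lrt_site(alt = c(5, 6, 5, 6, 60, 58, 61, 59),
                         ref = c(95, 94, 95, 94, 40, 42, 39, 41),
                         group = g, n_perm = 199)
  # with 4 + 4 samples the same 4v4 partition recurs with probability 2/70,
  # so the smallest attainable permutation p is about 0.03
  expect_lte(strong$p_perm, 0.05)
  flat <- glm_lrt_site(alt = rep(10, 8), ref = rep(90, 8), group = g,
                       n_perm = 99)
  expect_equal(flat$p_perm, 1)
})
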