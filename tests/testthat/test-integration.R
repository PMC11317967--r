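test_that("TPM normalisation follows the rate formula and its identities", {
  expr <- tibble::tibble(gene = "a", s1 = 123)
  lens <- tibble::tibble(gene = "a", length = 500)
  expect_equal(tpm_normalize(expr, lens)$s1, 1e6)

  expr2 <- tibble::tibble(gene = c("a", "b"), s1 = c(100, 100))
  lens2 <- tibble::tibble(gene = c("a", "b"), length = c(1000, 2000))
  tpm2 <- tpm_normalize(expr2, lens2)
  # equal counts, lengths 1000/2000 -> rates 2:1
  expect_equal(tpm2$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  withr::with_seed(12, {
    expr3 <- tibble::tibble(gene = sprintf("g%d", 1:40),
                            s1 = rpois(40, 200), s2 = rpois(40, 500))
    lens3 <- tibble::tibble(gene = expr3$gene,
                            length = sample(500:3000, 40))
  })
  tpm3 <- tpm_normalize(expr3, lens3)
  expect_equal(sum(tpm3$s1), 1e6, tolerance = 1e-3)
  expect_equal(sum(tpm3$s2), 1e6, tolerance = 1e-3)
  # invariant to rescaling all lengths by a constant
  lens3b <- dplyr::mutate(lens3, length = length * 7)
  expect_equal(tpm_normalize(expr3, lens3b), tpm3, tolerance = 1e-12)

  expr0 <- tibble::tibble(gene = c("a", "b"), s1 = c(0, 0))
  expect_warning(tpm0 <- tpm_normalize(expr0, lens2), "zero library")
  expect_equal(tpm0$s1, c(0, 0))
  expect_error(tpm_normalize(expr2, tibble::tibble(gene = "a", length = 100)),
               class = "aied_validation_error")
})

test_that("differential expression is null on identical columns and errors on n=1 groups", {
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                         group = rep(c("a", "b"), each = 2))
  expr <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         s1 = c(100, 50, 0), s2 = c(100, 50, 0),
                         s3 = c(100, 50, 0), s4 = c(100, 50, 0))
  de <- de_gene_test(expr, meta, family = "poisson")
  expect_true(all(de$p[de$status == "ok"] > 0.9))
  expect_equal(de$status[de$gene == "g3"], "all_zero")

  meta1 <- tibble::tibble(sample_id = c("s1", "s2"), group = c("a", "b"))
  expect_error(de_gene_test(expr[, 1:3], meta1),
               class = "aied_validation_error")
})

test_that("simulated expression shifts are detected with good sensitivity", {
  withr::with_seed(44, {
    n_g <- 120; n_s <- 16
    meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:n_s),
                           group = rep(c("a", "b"), each = n_s / 2))
    shifted <- seq_len(n_g) <= 12   # 10% of genes with a 2-fold shift
    base <- runif(n_g, log(50), log(500))
    mu <- outer(base, rep(1, n_s)) +
      outer(shifted * log(2), as.numeric(meta$group == "b")) +
      matrix(rnorm(n_g * n_s, sd = 0.15), n_g)
    counts <- matrix(rpois(n_g * n_s, exp(mu)), n_g)
    expr <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", 1:n_g)),
                             tibble::as_tibble(matrix(counts, n_g,
                                                      dimnames = list(NULL, meta$sample_id))))
  })
  de <- de_gene_test(expr, meta)
  calls <- !is.na(de$fdr) & de$fdr < 0.05
  expect_gt(mean(calls[shifted]), 0.8)        # sensitivity
  expect_lt(mean(calls[!shifted]), 0.1)       # false calls stay rare
  ov <- edited_expressed_overlap(de$gene[shifted], de)
  expect_equal(ov$n_edited, 12)
  expect_gte(ov$pct_edited_de, 80)
})

test_that("cis correlation reproduces exact monotone relationships", {
  meta_ids <- sprintf("s%d", 1:6)
  counts <- tibble::tibble(
    site_id = "gA:chr1:1", sample_id = meta_ids,
    alt_count = as.integer(seq(10, 35, 5)),
    ref_count = as.integer(100 - seq(10, 35, 5))
  )
  tpm_up <- dplyr::bind_cols(tibble::tibble(gene = "gA"),
                             tibble::as_tibble(as.list(setNames(exp(1:6), meta_ids))))
  res <- cis_correlation(counts, tpm_up)
  expect_equal(res$rho, 1)   # invariant under the monotone exp transform
  tpm_down <- dplyr::bind_cols(tibble::tibble(gene = "gA"),
                               tibble::as_tibble(as.list(setNames(6:1, meta_ids))))
  expect_equal(cis_correlation(counts, tpm_down)$rho, -1)

  # constant editing vector -> undefined, reported not errored
  counts_const <- dplyr::mutate(counts, alt_count = 20L, ref_count = 80L)
  res_c <- cis_correlation(counts_const, tpm_up)
  expect_true(is.na(res_c$rho))
  expect_equal(res_c$note, "constant vector")

  # too few paired observations
  res_few <- cis_correlation(counts[1:3, ], tpm_up)
  expect_equal(res_few$note, "too few observations")
})

test_that("simulated expression coupling is recovered as significant positive rho", {
  study <- small_study()
  tpm <- tpm_normalize(study$expression, study$gene_lengths)
  coupled <- study$truth$site_id[study$truth$coupling > 0]
  res <- cis_correlation(study$counts %>% dplyr::filter(site_id %in% coupled),
                         tpm, study$annotation, min_coverage = 1)
  expect_gt(mean(res$significant, na.rm = TRUE), 0.8)
  expect_gt(median(res$rho, na.rm = TRUE), 0.3)
})

test_that("overlap report implements exact set algebra", {
  rep1 <- overlap_dre_sets(list(a = c("s1", "s2"), b = c("s2", "s3"),
                                c = "s2"))
  expect_equal(rep1$in_all, "s2")
  expect_equal(rep1$n_union, 3)
  expect_equal(rep1$per_set$n_shared_any, c(1L, 1L, 1L))

  disjoint <- overlap_dre_sets(list(a = c("x", "y"), b = c("p", "q")))
  expect_length(disjoint$in_all, 0)
  expect_equal(disjoint$per_set$n_shared_any, c(0L, 0L))
  expect_equal(sum(disjoint$cells$n), disjoint$n_union)

  expect_warning(overlap_dre_sets(list(a = c("x", "x"), b = "x")), "duplicate")
  expect_error(overlap_dre_sets(list(c("x"), c("y"))), class = "aied_config_error")
})

test_that("overlap cells match a brute-force membership matrix on random sets", {
  withr::with_seed(31, {
    for (i in 1:10) {
      k <- sample(2:4, 1)
      universe <- sprintf("site%03d", 1:60)
      sets <- setNames(
        lapply(seq_len(k), function(j) sample(universe, sample(5:40, 1))),
        paste0("d", seq_len(k))
      )
      rep <- overlap_dre_sets(sets)
      # oracle: per-site membership pattern tabulation
      uni <- unique(unlist(sets))
      mem <- sapply(sets, function(s) uni %in% s)
      pat <- apply(mem, 1, paste, collapse = "/")
      oracle_cells <- table(pat)
      got <- rep$cells
      got_pat <- apply(as.matrix(got[, names(sets)]), 1, paste, collapse = "/")
      expect_equal(sort(as.integer(oracle_cells)), sort(got$n))
      expect_equal(setNames(got$n, got_pat)[names(oracle_cells)],
                   setNames(as.integer(oracle_cells), names(oracle_cells)))
      expect_equal(sum(got$n), length(uni))
      expect_equal(length(rep$in_all), sum(rowSums(mem) == k))
    }
  })
})

test_that("rescue rules require opposite significant shifts back toward control", {
  md <- treatment_design(n_per_group = 4)
  lv <- list(
    rescued_up = c(CON = 0.10, LPS = 0.30, FUL = 0.12),
    not_rescued = c(CON = 0.10, LPS = 0.30, FUL = 0.35),
    flat = c(CON = 0.20, LPS = 0.20, FUL = 0.20),
    rescued_down = c(CON = 0.30, LPS = 0.10, FUL = 0.28)
  )
  counts <- purrr::imap_dfr(lv, function(l, nm) {
    one_site_counts(l, md, coverage = 300, seed = match(nm, names(lv)),
                    site_id = nm)
  })
  res <- rescue_call(counts, md)
  res <- res[match(names(lv), res$site_id), ]
  expect_equal(res$rescued, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(rescue_call(counts, treatment_design(n_per_group = 1)),
               class = "aied_validation_error")
})

test_that("rescue calling recovers a seeded truth with high sensitivity and specificity", {
  md <- treatment_design(n_per_group = 3)
  withr::with_seed(55, {
    is_rescue <- rep(c(TRUE, FALSE), c(20, 80))
    counts <- purrr::map_dfr(seq_along(is_rescue), function(i) {
      base <- runif(1, 0.08, 0.3)
      lv <- if (is_rescue[i]) {
        c(CON = base, LPS = base + 0.18, FUL = base + 0.02)
      } else {
        c(CON = base, LPS = base, FUL = base)
      }
      one_site_counts(lv, md, coverage = 100, dispersion = 0,
                      seed = NULL, site_id = sprintf("site%03d", i))
    })
  })
  res <- rescue_call(counts, md)
  res <- res[match(sprintf("site%03d", seq_along(is_rescue)), res$site_id), ]
  expect_gte(mean(res$rescued[is_rescue]), 0.8)       # sensitivity
  expect_gte(mean(!res$rescued[!is_rescue]), 0.8)     # specificity
})
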