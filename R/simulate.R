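#' Fully crossed sepsis time-course design
#'
#' Builds the sample metadata for a three-group time-course study crossed with
#' age and sex, the layout of a CLP (caecal ligation and perforation) sepsis
#' experiment: controls plus two post-induction time points, each containing
#' young/old and male/female subgroups with a fixed number of replicates.
#'
#' @param groups Character vector of exactly three group labels; the first is
#'   the reference (control) level.
#' @param ages,sexes Two-level factors crossed with group.
#' @param n_per_cell Replicates per group x age x sex cell.
#' @param dataset Dataset identifier stored in the metadata.
#' @return A tibble with columns `sample_id`, `group`, `age`, `sex`, `dataset`.
#' @export
#' @examples
#' clp_design() # 3 groups x 2 ages x 2 sexes x 4 = 48 samples
clp_design <- function(groups = c("control", "D1", "D4"),
                       ages = c("young", "old"),
                       sexes = c("male", "female"),
                       n_per_cell = 4,
                       dataset = "CLP") {
  if (n_per_cell < 1) abort("n_per_cell must be >= 1", class = "aied_config_error")
  grid <- tidyr::expand_grid(
    group = factor(groups, levels = groups),
    age = factor(ages, levels = ages),
    sex = factor(sexes, levels = sexes),
    replicate = seq_len(n_per_cell)
  )
  grid %>%
    mutate(
      sample_id = sprintf("s%03d", row_number()),
      dataset = dataset
    ) %>%
    select("sample_id", "group", "age", "sex", "dataset")
}

#' Three-arm treatment design without covariates
#'
#' Metadata for a control / challenge / pre-treated-challenge comparison (the
#' layout of an LPS endotoxaemia study with a candidate rescue compound), with
#' no age or sex structure.
#'
#' @param groups Exactly three group labels, reference first.
#' @param n_per_group Replicates per group.
#' @param dataset Dataset identifier.
#' @return A tibble with columns `sample_id`, `group`, `age`, `sex`, `dataset`
#'   (`age` and `sex` are `NA`).
#' @export
treatment_design <- function(groups = c("CON", "LPS", "FUL"),
                             n_per_group = 3,
                             dataset = "LPS") {
  if (n_per_group < 1) abort("n_per_group must be >= 1", class = "aied_config_error")
  tibble(
    group = factor(rep(groups, each = n_per_group), levels = groups),
    replicate = rep(seq_len(n_per_group), times = length(groups))
  ) %>%
    mutate(
      sample_id = sprintf("s%03d", row_number()),
      age = NA_character_, sex = NA_character_, dataset = dataset
    ) %>%
    select("sample_id", "group", "age", "sex", "dataset")
}

#' Configuration for the synthetic-study generator
#'
#' Collects and validates every parameter of [simulate_study()]. Defaults are
#' the study conditions emulated throughout the package: a fully crossed
#' 3 x 2 x 2 x 4 design, mean per-site coverage of 50 reads, mild beta-binomial
#' overdispersion (rho = 0.01), baseline editing levels in \[0.02, 0.40\] and a
#' +0.10 group shift (on the proportion scale) at true differential sites.
#'
#' @param n_sites Number of editing sites to simulate.
#' @param frac_known Proportion of sites present in the known-site table.
#' @param frac_dre Proportion of sites with a true group effect.
#' @param frac_age_effect,frac_sex_effect Proportions of sites with additive
#'   age (old vs young) and sex (male vs female) shifts.
#' @param baseline_level_range Length-2 interval in \[0,1\] from which baseline
#'   editing levels are drawn uniformly.
#' @param effect_size Additive group shift on the proportion scale.
#' @param age_effect_size,sex_effect_size Additive covariate shifts.
#' @param coverage_mean Mean reads per site per sample (Poisson, floored at 1).
#' @param dispersion Beta-binomial intra-class correlation rho in \[0, 1).
#' @param frac_coupled Proportion of sites whose host gene's expression is
#'   coupled to the site's observed editing level.
#' @param coupling Log-scale expression slope per unit editing level at
#'   coupled sites.
#' @param design Sample metadata tibble, e.g. [clp_design()] or
#'   [treatment_design()]; must contain exactly three group levels (reference
#'   first).
#' @param seed Integer seed; the same seed always yields an identical study.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 50, seed = 1)
#' study <- simulate_study(cfg)
sim_config <- function(n_sites = 500,
                       frac_known = 0.3,
                       frac_dre = 0.2,
                       frac_age_effect = 0.1,
                       frac_sex_effect = 0.1,
                       baseline_level_range = c(0.02, 0.40),
                       effect_size = 0.10,
                       age_effect_size = 0.15,
                       sex_effect_size = 0.15,
                       coverage_mean = 50,
                       dispersion = 0.01,
                       frac_coupled = 0.3,
                       coupling = 4,
                       design = clp_design(),
                       seed = 1) {
  if (!is.numeric(n_sites) || n_sites < 0 || n_sites != round(n_sites)) {
    abort("n_sites must be a non-negative integer", class = "aied_config_error")
  }
  for (nm in c("frac_known", "frac_dre", "frac_age_effect", "frac_sex_effect",
               "frac_coupled")) {
    assert_proportion(get(nm), nm)
  }
  if (length(baseline_level_range) != 2 ||
      any(baseline_level_range < 0) || any(baseline_level_range > 1) ||
      baseline_level_range[1] > baseline_level_range[2]) {
    abort("baseline_level_range must be an ordered interval within [0, 1]",
          class = "aied_config_error")
  }
  if (coverage_mean <= 0) {
    abort("coverage_mean must be positive", class = "aied_config_error")
  }
  if (dispersion < 0 || dispersion >= 1) {
    abort("dispersion (rho) must lie in [0, 1)", class = "aied_config_error")
  }
  assert_columns(design, c("sample_id", "group"), "design")
  if (nrow(design) == 0) {
    abort("design must contain at least one sample", class = "aied_config_error")
  }
  groups <- levels(factor(design$group))
  if (dplyr::n_distinct(design$group) != 3) {
    abort("design must contain exactly three groups (reference first)",
          class = "aied_config_error")
  }
  covars_wanted <- frac_age_effect > 0 || frac_sex_effect > 0
  if (covars_wanted) {
    cells <- subgroup_scheme(design)
    if (min(table(cells$subgroup)) < 2) {
      abort("covariate effects require >= 2 samples per design cell",
            class = "aied_config_error")
    }
  }
  structure(list(
    n_sites = as.integer(n_sites), frac_known = frac_known, frac_dre = frac_dre,
    frac_age_effect = frac_age_effect, frac_sex_effect = frac_sex_effect,
    baseline_level_range = baseline_level_range, effect_size = effect_size,
    age_effect_size = age_effect_size, sex_effect_size = sex_effect_size,
    coverage_mean = coverage_mean, dispersion = dispersion,
    frac_coupled = frac_coupled, coupling = coupling,
    design = as_tibble(design), seed = as.integer(seed)
  ), class = "sim_config")
}

# beta-binomial draws parameterised by mean p and intra-class correlation rho;
# rho = 0 degenerates to binomial, p in {0, 1} is deterministic
rbetabinom_icc <- function(n, size, prob, rho) {
  if (rho >= 1) abort("dispersion (rho) must be < 1", class = "aied_config_error")
  prob <- rep_len(prob, n)
  size <- rep_len(size, n)
  if (rho == 0) return(rbinom(n, size, prob))
  out <- integer(n)
  interior <- prob > 0 & prob < 1
  if (any(interior)) {
    a <- prob[interior] * (1 - rho) / rho
    b <- (1 - prob[interior]) * (1 - rho) / rho
    p_i <- rbeta(sum(interior), a, b)
    out[interior] <- rbinom(sum(interior), size[interior], p_i)
  }
  out[!interior] <- rbinom(sum(!interior), size[!interior], prob[!interior])
  out
}

#' Simulate allele counts for one site across samples
#'
#' Draws per-sample coverage from a Poisson law (floored at one read) and
#' edited-read counts from a beta-binomial with the given per-sample true
#' levels and overdispersion. `dispersion = 0` is exactly binomial.
#'
#' @param true_levels Numeric vector of per-sample true editing levels in
#'   \[0, 1\].
#' @param coverage_mean Mean coverage per sample.
#' @param dispersion Beta-binomial intra-class correlation rho in \[0, 1).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A tibble with columns `coverage`, `alt_count`, `ref_count`.
#' @export
#' @examples
#' simulate_site_counts(rep(0.3, 8), coverage_mean = 50, seed = 1)
simulate_site_counts <- function(true_levels, coverage_mean = 50,
                                 dispersion = 0, seed = NULL) {
  if (any(is.na(true_levels)) || any(true_levels < 0) || any(true_levels > 1)) {
    abort("true_levels must lie in [0, 1]", class = "aied_config_error")
  }
  if (dispersion < 0 || dispersion >= 1) {
    abort("dispersion (rho) must lie in [0, 1)", class = "aied_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_levels)
  coverage <- pmax(rpois(n, coverage_mean), 1L)
  alt <- rbetabinom_icc(n, coverage, true_levels, dispersion)
  tibble(coverage = as.integer(coverage),
         alt_count = as.integer(alt),
         ref_count = as.integer(coverage - alt))
}

# draw the per-site truth table for a config; shift columns d1_shift/d4_shift
# apply to the 2nd/3rd group level of the design
simulate_truth <- function(config) {
  n <- config$n_sites
  if (n == 0) {
    return(tibble(
      site_id = character(), gene = character(), chrom = character(),
      pos = integer(), strand = character(), baseline = numeric(),
      d1_shift = numeric(), d4_shift = numeric(), age_shift = numeric(),
      sex_shift = numeric(), rho = numeric(), coupling = numeric(),
      is_dre = logical(), is_known = logical()
    ))
  }
  n_genes <- max(1L, ceiling(n / 1.7))
  gene_pool <- sprintf("Gene%04d", seq_len(n_genes))
  gene <- sample(gene_pool, n, replace = TRUE)
  chrom <- sample(paste0("chr", c(1:19, "X")), n, replace = TRUE)
  pos <- sample.int(2e8, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  baseline <- runif(n, config$baseline_level_range[1], config$baseline_level_range[2])

  is_dre <- runif(n) < config$frac_dre
  # true-effect pattern: shift the 2nd group, the 3rd, or both (upward)
  pattern <- sample(c("g2", "g3", "both"), n, replace = TRUE)
  d1_shift <- ifelse(is_dre & pattern %in% c("g2", "both"), config$effect_size, 0)
  d4_shift <- ifelse(is_dre & pattern %in% c("g3", "both"), config$effect_size, 0)
  age_shift <- ifelse(runif(n) < config$frac_age_effect, config$age_effect_size, 0)
  sex_shift <- ifelse(runif(n) < config$frac_sex_effect, config$sex_effect_size, 0)
  is_known <- runif(n) < config$frac_known
  coupled <- runif(n) < config$frac_coupled
  # one coupled site per gene at most: keep the first in table order
  coupled <- coupled & !duplicated(gene)

  tibble(
    site_id = paste(gene, chrom, pos, sep = ":"),
    gene = gene, chrom = chrom, pos = as.integer(pos), strand = strand,
    baseline = baseline, d1_shift = d1_shift, d4_shift = d4_shift,
    age_shift = age_shift, sex_shift = sex_shift,
    rho = config$dispersion,
    coupling = ifelse(coupled, config$coupling, 0),
    is_dre = is_dre, is_known = is_known
  )
}

# realized true level for each site x sample; additive effects are clamped
# into [0.001, 0.999], untouched baselines are left exact
realized_levels <- function(truth, metadata) {
  groups <- levels(factor(metadata$group))
  grid <- tidyr::expand_grid(site_id = truth$site_id,
                             sample_id = metadata$sample_id) %>%
    left_join(truth %>% select("site_id", "baseline", "d1_shift", "d4_shift",
                               "age_shift", "sex_shift"),
              by = "site_id") %>%
    left_join(metadata %>% select("sample_id", "group", "age", "sex"),
              by = "sample_id") %>%
    mutate(
      shift = .data$d1_shift * (.data$group == groups[2]) +
        .data$d4_shift * (.data$group == groups[3]) +
        .data$age_shift * (!is.na(.data$age) & .data$age == "old") +
        .data$sex_shift * (!is.na(.data$sex) & .data$sex == "male"),
      true_level = ifelse(.data$shift == 0, .data$baseline,
                          clamp_level(.data$baseline + .data$shift))
    )
  grid %>% select("site_id", "sample_id", "true_level")
}

consequence_categories <- function() {
  c("3'UTR", "intronic", "missense", "synonymous", "noncoding_exonic",
    "5'UTR", "noncoding_intronic", "stop_loss")
}

# category frequencies of a typical mouse hippocampal editing catalog
consequence_weights <- function() {
  c(0.553, 0.189, 0.174, 0.040, 0.026, 0.009, 0.007, 0.002)
}

#' Generate a complete synthetic editing study
#'
#' Produces every input table the pipeline consumes — a long allele-count
#' table (with strand-of-genome base representation: A>G on "+", T>C on "-"),
#' sample metadata, a site annotation table, a known-site table, a repeat BED
#' and an editing-coupled gene-expression matrix — together with the per-site
#' ground truth used by recovery tests. Identical seeds give identical output.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_study`: a named list of tibbles
#'   `counts`, `metadata`, `annotation`, `known_sites`, `repeats`,
#'   `expression`, `gene_lengths`, `truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_sites = 20, seed = 7))
#' names(study)
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be created with sim_config()", class = "aied_config_error")
  }
  set.seed(config$seed)
  metadata <- config$design
  truth <- simulate_truth(config)

  levels_long <- realized_levels(truth, metadata)
  draws <- simulate_site_counts(levels_long$true_level,
                                coverage_mean = config$coverage_mean,
                                dispersion = config$dispersion)
  counts <- dplyr::bind_cols(levels_long %>% select("site_id", "sample_id"),
                             draws) %>%
    left_join(truth %>% select("site_id", "chrom", "pos", "strand"),
              by = "site_id") %>%
    mutate(
      ref = ifelse(.data$strand == "-", "T", "A"),
      alt = ifelse(.data$strand == "-", "C", "G")
    ) %>%
    select("site_id", "chrom", "pos", "strand", "ref", "alt", "sample_id",
           "ref_count", "alt_count")

  annotation <- simulate_annotation(truth)
  known_sites <- truth %>%
    filter(.data$is_known) %>%
    mutate(Region = .data$chrom, Position = .data$pos,
           Ref = "A", Ed = "G", Strand = .data$strand) %>%
    select("Region", "Position", "Ref", "Ed", "Strand")
  repeats <- simulate_repeats(truth)
  expr <- simulate_expression(truth, counts, metadata)

  structure(list(
    counts = counts, metadata = as_tibble(metadata), annotation = annotation,
    known_sites = known_sites, repeats = repeats,
    expression = expr$counts, gene_lengths = expr$lengths,
    truth = truth %>% select(-"is_known")
  ), class = "synthetic_study")
}

simulate_annotation <- function(truth) {
  n <- nrow(truth)
  consequence <- sample(consequence_categories(), n, replace = TRUE,
                        prob = consequence_weights())
  tibble(
    site_id = truth$site_id,
    gene = truth$gene,
    gene_biotype = sample(c("protein_coding", "lincRNA"), n, replace = TRUE,
                          prob = c(0.92, 0.08)),
    consequence = consequence,
    cdna_change = sprintf("c.%dA>G", sample.int(5000, n, replace = TRUE)),
    protein_change = ifelse(consequence == "missense",
                            sprintf("p.M%dV", sample.int(900, n, replace = TRUE)),
                            NA_character_)
  )
}

# ~60% of sites fall inside a SINE-like repeat; B1 dominates as in the murine
# genome; plus decoy intervals that overlap no site
simulate_repeats <- function(truth) {
  n <- nrow(truth)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  family = character()))
  }
  in_repeat <- runif(n) < 0.6
  fam <- sample(c("B1", "B2", "B3", "ID"), n, replace = TRUE,
                prob = c(0.55, 0.22, 0.13, 0.10))
  lead <- sample.int(150, n, replace = TRUE)
  len <- 150 + sample.int(150, n, replace = TRUE)
  covering <- tibble(
    chrom = truth$chrom,
    start = pmax(truth$pos - 1L - lead, 0L),       # BED 0-based start
    end = pmax(truth$pos - 1L - lead, 0L) + len,   # half-open end
    family = fam
  )[in_repeat, ]
  n_decoy <- max(2L, ceiling(n / 5))
  decoys <- tibble(
    chrom = sample(paste0("chr", c(1:19, "X")), n_decoy, replace = TRUE),
    start = sample.int(2e8, n_decoy) + 2e8L,        # beyond any simulated site
    family = sample(c("B1", "B2", "B4", "L1"), n_decoy, replace = TRUE)
  ) %>%
    mutate(end = .data$start + 150L + sample.int(200, n_decoy, replace = TRUE)) %>%
    select("chrom", "start", "end", "family")
  bind_rows(covering, decoys) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

# gene expression with log-scale coupling to the observed editing level of the
# gene's coupled site, enabling Spearman cis-correlation recovery
simulate_expression <- function(truth, counts, metadata) {
  genes <- unique(truth$gene)
  n_extra <- ceiling(length(genes) * 0.3)
  extra <- if (n_extra > 0) sprintf("Bkg%04d", seq_len(n_extra)) else character()
  all_genes <- c(genes, extra)
  n_g <- length(all_genes)
  if (n_g == 0) {
    empty <- as_tibble(setNames(
      c(list(character()), rep(list(numeric()), nrow(metadata))),
      c("gene", metadata$sample_id)
    ))
    return(list(counts = empty,
                lengths = tibble(gene = character(), length = integer())))
  }
  lengths <- tibble(gene = all_genes,
                    length = as.integer(sample(600:4000, n_g, replace = TRUE)))
  log_base <- runif(n_g, log(20), log(2000))
  names(log_base) <- all_genes

  coupled <- truth %>% filter(.data$coupling != 0)
  obs_level <- counts %>%
    semi_join(coupled, by = "site_id") %>%
    mutate(level = .data$alt_count / (.data$ref_count + .data$alt_count)) %>%
    left_join(coupled %>% select("site_id", "gene", "coupling"), by = "site_id") %>%
    group_by(.data$gene) %>%
    mutate(level_c = .data$level - mean(.data$level)) %>%
    ungroup()

  samples <- metadata$sample_id
  base_mat <- matrix(rep(log_base, times = length(samples)),
                     nrow = n_g, dimnames = list(all_genes, samples))
  if (nrow(obs_level) > 0) {
    idx <- cbind(match(obs_level$gene, all_genes),
                 match(obs_level$sample_id, samples))
    base_mat[idx] <- base_mat[idx] + obs_level$coupling * obs_level$level_c
  }
  noise <- matrix(rnorm(n_g * length(samples), sd = 0.25), nrow = n_g)
  counts_mat <- matrix(rpois(n_g * length(samples), exp(base_mat + noise)),
                       nrow = n_g, dimnames = dimnames(base_mat))
  expr <- as_tibble(counts_mat, rownames = "gene")
  list(counts = expr, lengths = lengths)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits every table of a [simulate_study()] result in the external interface
#' formats consumed by the readers ([read_allele_counts()] and friends), plus
#' the ground-truth table. Files round-trip losslessly.
#'
#' @param study A `synthetic_study` object.
#' @param dir Target directory (created if absent).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study")) {
    abort("study must come from simulate_study()", class = "aied_config_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create directory '%s'", dir), class = "aied_io_error")
  }
  paths <- c(
    counts = file.path(dir, "allele_counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    known_sites = file.path(dir, "known_sites.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    expression = file.path(dir, "expression.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(study$counts, paths[["counts"]])
  readr::write_tsv(study$metadata, paths[["metadata"]])
  readr::write_tsv(study$annotation, paths[["annotation"]])
  readr::write_tsv(study$known_sites, paths[["known_sites"]])
  readr::write_tsv(study$repeats, paths[["repeats"]], col_names = FALSE)
  readr::write_tsv(study$expression, paths[["expression"]])
  readr::write_tsv(study$gene_lengths, paths[["gene_lengths"]])
  readr::write_tsv(study$truth, paths[["truth"]])
  invisible(paths)
}
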