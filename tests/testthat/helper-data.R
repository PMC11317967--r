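# Shared fixtures, generated in code. The small CLP-design study is memoised
# because several test files reuse it.

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(n_sites = 120, seed = 42))
    }
    cache
  }
})

# long count table for a single site under an arbitrary per-sample level map
one_site_counts <- function(levels_by_sample, metadata, coverage = 100,
                            dispersion = 0, seed = 1, site_id = "g:chr1:100") {
  lev <- levels_by_sample[as.character(metadata$group)]
  d <- simulate_site_counts(lev, coverage_mean = coverage,
                            dispersion = dispersion, seed = seed)
  tibble::tibble(
    site_id = site_id, chrom = "chr1", pos = 100L, strand = "+",
    ref = "A", alt = "G",
    sample_id = metadata$sample_id,
    ref_count = d$ref_count, alt_count = d$alt_count
  )
}
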