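#' Read a per-sample per-site allele-count table
#'
#' Reads the long-format TSV that is the pipeline's primary input: one row per
#' (site, sample) with reference and alternative (edited) read counts. The
#' required columns are validated by name; extra columns are preserved.
#'
#' @param path Path to a TSV with columns `site_id`, `chrom`, `pos`, `strand`,
#'   `ref`, `alt`, `sample_id`, `ref_count`, `alt_count`.
#' @return A tibble of validated records.
#' @export
read_allele_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("site_id", "chrom", "pos", "strand", "ref", "alt",
                "sample_id", "ref_count", "alt_count")
  assert_columns(tbl, required, "allele-count table")
  tbl <- tbl %>%
    mutate(across(all_of(c("pos", "ref_count", "alt_count")), as.integer),
           across(all_of(c("site_id", "chrom", "strand", "ref", "alt",
                           "sample_id")), as.character))
  bad <- which(tbl$ref_count < 0 | tbl$alt_count < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative read count at row %s of the allele-count table",
                  paste(head(bad, 5), collapse = ", ")),
          class = "aied_validation_error")
  }
  if (any(tbl$pos < 1, na.rm = TRUE)) {
    abort("positions must be 1-based (>= 1)", class = "aied_validation_error")
  }
  tbl
}

#' Read a known editing-site table
#'
#' Accepts the REDIportal-style header (`Region`, `Position`, `Ref`, `Ed`,
#' `Strand`) and returns a normalised known-site index.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `ed`, `strand`.
#' @export
read_known_sites <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tbl, c("Region", "Position"), "known-site table")
  tibble(
    chrom = as.character(tbl$Region),
    pos = as.integer(tbl$Position),
    ref = if ("Ref" %in% names(tbl)) as.character(tbl$Ref) else "A",
    ed = if ("Ed" %in% names(tbl)) as.character(tbl$Ed) else "G",
    strand = if ("Strand" %in% names(tbl)) as.character(tbl$Strand) else NA_character_
  )
}

#' Read the site annotation table
#'
#' Consequence classes, gene symbols and biotypes are consumed as pre-computed
#' input (VEP-style), one row per site.
#'
#' @param path Path to a TSV with columns `site_id`, `gene`, `gene_biotype`,
#'   `consequence` (and optionally `cdna_change`, `protein_change`).
#' @return A tibble.
#' @export
read_site_annotation <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tbl, c("site_id", "gene", "gene_biotype", "consequence"),
                 "annotation table")
  if (anyDuplicated(tbl$site_id)) {
    dup <- unique(tbl$site_id[duplicated(tbl$site_id)])
    abort(sprintf("annotation has duplicate site_id(s): %s",
                  paste(head(dup, 3), collapse = ", ")),
          class = "aied_validation_error")
  }
  tbl
}

#' Read a repeat BED file
#'
#' Standard 0-based half-open BED with a repeat-family name in the fourth
#' column (e.g. the murine SINE families B1, B2, B3, ID).
#'
#' @param path Path to the BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `family`.
#' @export
read_repeat_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "family"),
                         show_col_types = FALSE, progress = FALSE)
  bad <- which(is.na(tbl$chrom) | is.na(tbl$start) | is.na(tbl$end) |
                 tbl$start < 0 | tbl$end < tbl$start)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED row at line %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "aied_validation_error")
  }
  tbl %>% mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Read the sample metadata table
#'
#' @param path Path to a TSV with columns `sample_id`, `group` and optionally
#'   `age`, `sex`, `dataset`.
#' @param group_levels Optional explicit group level order (reference first);
#'   defaults to order of first appearance in the file.
#' @return A tibble; `group` is a factor.
#' @export
read_sample_metadata <- function(path, group_levels = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tbl, c("sample_id", "group"), "metadata table")
  if (anyDuplicated(tbl$sample_id)) {
    abort("metadata sample_ids must be unique", class = "aied_validation_error")
  }
  lev <- group_levels %||% unique(as.character(tbl$group))
  tbl %>% mutate(group = factor(as.character(.data$group), levels = lev))
}

#' Orient candidate calls to the sense strand and keep A-to-G only
#'
#' Canonical A-to-I editing appears as A>G on the "+" strand and T>C on the
#' "-" strand of the genome. Records on "-" with a T>C call are rewritten to
#' their sense-strand A>G representation; A>G on "+" is kept as is; every
#' other substitution is rejected (dropped).
#'
#' @param counts A tibble with at least `strand`, `ref`, `alt`.
#' @param quiet Suppress the message reporting how many records were dropped.
#' @return The tibble restricted to A-to-G editing candidates, all represented
#'   as `ref = "A"`, `alt = "G"` on the sense strand.
#' @export
orient_to_sense <- function(counts, quiet = FALSE) {
  assert_columns(counts, c("strand", "ref", "alt"), "counts")
  ref <- toupper(counts$ref)
  alt <- toupper(counts$alt)
  strand <- counts$strand
  plus_ag <- strand == "+" & ref == "A" & alt == "G"
  minus_tc <- strand == "-" & ref == "T" & alt == "C"
  ambiguous <- (!strand %in% c("+", "-")) & ref == "T" & alt == "C"
  if (any(ambiguous, na.rm = TRUE)) {
    abort("T>C call with unknown strand cannot be oriented",
          class = "aied_validation_error")
  }
  keep <- !is.na(plus_ag) & (plus_ag | minus_tc)
  out <- counts[keep, , drop = FALSE] %>%
    mutate(ref = "A", alt = "G")
  n_drop <- nrow(counts) - nrow(out)
  if (n_drop > 0 && !quiet) {
    inform(sprintf("orient_to_sense: dropped %d non A-to-G record(s)", n_drop))
  }
  out
}

#' Flag sites present in a known-site index
#'
#' Exact-match lookup on chromosome and 1-based position; strand is not part
#' of the key (known-site catalogues are sense-oriented and candidates are
#' already canonicalised).
#'
#' @param sites A tibble with `chrom` and `pos` columns.
#' @param known_sites A known-site tibble as from [read_known_sites()] (or any
#'   table with `chrom` and `pos`), or `NULL` for no index.
#' @return `sites` with a logical `known` column.
#' @export
flag_known <- function(sites, known_sites = NULL) {
  assert_columns(sites, c("chrom", "pos"), "sites")
  if (is.null(known_sites) || nrow(known_sites) == 0) {
    return(sites %>% mutate(known = FALSE))
  }
  if (!all(c("chrom", "pos") %in% names(known_sites)) &&
      all(c("Region", "Position") %in% names(known_sites))) {
    known_sites <- known_sites %>%
      rename(chrom = "Region", pos = "Position")
  }
  assert_columns(known_sites, c("chrom", "pos"), "known_sites")
  key <- paste(known_sites$chrom, known_sites$pos)
  sites %>% mutate(known = paste(.data$chrom, .data$pos) %in% key)
}

#' Annotate sites with the repeat family they fall in
#'
#' A site at 1-based position p overlaps a 0-based half-open BED interval
#' \[start, end) iff start <= p - 1 < end. When repeats overlap each other,
#' the first interval in file order wins. Sites outside all repeats get
#' `NA`.
#'
#' @param sites A tibble with `chrom` and `pos`.
#' @param repeats A repeat tibble as from [read_repeat_bed()].
#' @return `sites` with a `repeat_family` character column.
#' @export
overlap_repeats <- function(sites, repeats) {
  assert_columns(sites, c("chrom", "pos"), "sites")
  assert_columns(repeats, c("chrom", "start", "end", "family"), "repeats")
  out <- sites %>% mutate(repeat_family = NA_character_)
  if (nrow(sites) == 0 || nrow(repeats) == 0) return(out)
  for (chr in unique(sites$chrom)) {
    qi <- which(sites$chrom == chr)
    sj <- which(repeats$chrom == chr)   # preserves file order
    if (length(sj) == 0) next
    q <- IRanges::IRanges(start = sites$pos[qi], width = 1L)
    s <- IRanges::IRanges(start = repeats$start[sj] + 1L, end = repeats$end[sj])
    hit <- IRanges::findOverlaps(q, s, select = "first")
    found <- !is.na(hit)
    out$repeat_family[qi[found]] <- repeats$family[sj[hit[found]]]
  }
  out
}

#' Summarise a catalog by functional consequence
#'
#' Counts sites per consequence category and reports the percentage of the
#' catalog each represents, rounded to one decimal.
#'
#' @param catalog A tibble with a `consequence` column (one row per site).
#' @return A tibble with columns `consequence`, `n`, `pct`, sorted by
#'   decreasing count. The catalog size is `sum(n)`.
#' @export
#' @examples
#' cat <- tibble::tibble(consequence = c("3'UTR", "3'UTR", "missense"))
#' summarize_consequences(cat)
summarize_consequences <- function(catalog) {
  assert_columns(catalog, "consequence", "catalog")
  if (nrow(catalog) == 0) {
    return(tibble(consequence = character(), n = integer(), pct = numeric()))
  }
  catalog %>%
    count(.data$consequence, name = "n") %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    arrange(dplyr::desc(.data$n))
}

#' Summarise a catalog by overlapping repeat family
#'
#' @param catalog A tibble with a `repeat_family` column (as produced by
#'   [overlap_repeats()]); `NA` means no repeat overlap.
#' @return A tibble `repeat_family`, `n`, `pct` over sites inside repeats,
#'   sorted by decreasing count.
#' @export
summarize_repeats <- function(catalog) {
  assert_columns(catalog, "repeat_family", "catalog")
  inside <- catalog %>% filter(!is.na(.data$repeat_family))
  if (nrow(inside) == 0) {
    return(tibble(repeat_family = character(), n = integer(), pct = numeric()))
  }
  inside %>%
    count(.data$repeat_family, name = "n") %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    arrange(dplyr::desc(.data$n))
}
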