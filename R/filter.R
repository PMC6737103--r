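#' Filtering and discovery configuration
#'
#' Bundles the thresholds used by shared-locus filtering and diagnostic
#' discovery.
#'
#' @param presence_threshold Minimum fraction of samples (and, during
#'   discovery, of each taxon) with a non-missing call, in (0, 1]. The
#'   comparison is `>=` on the exact fraction: 3 of 4 samples passes 0.75.
#' @param max_snps_per_locus Cap on SNPs per locus. In [filter_shared_loci()]
#'   it counts all retained SNPs on a locus; in [find_diagnostic_markers()]
#'   it counts the species-specific SNPs on a locus (an "up to k" cap). Loci
#'   over the cap are dropped whole, never thinned.
#' @param require_biallelic Drop a locus if any of its sites shows more than
#'   two alleles across the analysed samples.
#' @param min_edge_distance_bp Minimum distance (bp) of an assayable SNP from
#'   either end of its RAD-tag, used by [filter_assay_candidates()].
#' @param taxon_level Grouping level diagnostic analyses operate at.
#' @return A `filter_config` list.
#' @export
filter_config <- function(presence_threshold = 0.75,
                          max_snps_per_locus = 2L,
                          require_biallelic = TRUE,
                          min_edge_distance_bp = 20L,
                          taxon_level = c("species", "subspecies", "population")) {
  taxon_level <- match.arg(taxon_level)
  if (!is_prob(presence_threshold) || presence_threshold <= 0) {
    stopf("presence_threshold must be in (0, 1]")
  }
  if (!(is.infinite(max_snps_per_locus) || is_count(max_snps_per_locus))) {
    stopf("max_snps_per_locus must be an integer >= 1 (or Inf)")
  }
  if (!is_count(min_edge_distance_bp, min = 0L)) {
    stopf("min_edge_distance_bp must be a non-negative integer")
  }
  structure(list(presence_threshold = presence_threshold,
                 max_snps_per_locus = max_snps_per_locus,
                 require_biallelic = isTRUE(require_biallelic),
                 min_edge_distance_bp = as.integer(min_edge_distance_bp),
                 taxon_level = taxon_level),
            class = "filter_config")
}

#' Fraction of non-missing calls at a site within a sample group
#'
#' @param x A [geno_matrix].
#' @param site A site key.
#' @param group Sample ids forming the group (defaults to all samples).
#' @return Fraction in \[0, 1\]: non-missing calls / group size.
#' @export
presence_fraction <- function(x, site, group = sample_ids(x)) {
  if (length(group) == 0L) stopf("presence_fraction: empty sample group")
  j <- match(site, x$sites$site_key)
  if (is.na(j)) stopf("unknown site key '%s'", site)
  k <- match(group, sample_ids(x))
  if (anyNA(k)) stopf("unknown sample id(s) in group")
  mean(!is.na(x$a1[j, k]))
}

# per-site summary used by the filters: presence over `samples`,
# number of distinct observed alleles
site_stats <- function(x, samples = sample_ids(x)) {
  k <- match(samples, sample_ids(x))
  a1 <- x$a1[, k, drop = FALSE]
  ac <- allele_counts(x, samples)
  data.frame(site_key = x$sites$site_key,
             locus_id = x$sites$locus_id,
             presence = rowSums(!is.na(a1)) / length(k),
             n_alleles = rowSums(ac > 0L),
             stringsAsFactors = FALSE)
}

#' Filter a genotype matrix down to shared loci
#'
#' Implements locus-level selection for downstream analyses. Polymorphic
#' loci are RAD-tags with at least one SNP (a site showing >= 2 alleles);
#' shared loci are polymorphic loci genotyped in at least
#' `presence_threshold` of all samples. A locus is retained when (a) it is
#' polymorphic, (b) every one of its polymorphic sites reaches the presence
#' threshold over all samples, (c) no site shows more than two alleles (when
#' `require_biallelic`), and (d) its number of polymorphic sites does not
#' exceed `max_snps_per_locus` — loci over the cap are dropped whole. The
#' retained sites of a retained locus are its polymorphic sites (markers).
#'
#' @param x A [geno_matrix].
#' @param cfg A [filter_config].
#' @return A `shared_locus_set`: list with `matrix` (the filtered
#'   [geno_matrix]), `cfg`, `n_input_loci`, `n_shared_loci` and `n_markers`.
#' @export
filter_shared_loci <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "geno_matrix"), inherits(cfg, "filter_config"))
  if (n_sites(x) == 0L) stopf("empty genotype matrix")
  st <- site_stats(x)
  poly <- st$n_alleles >= 2L
  pres_ok <- st$presence >= cfg$presence_threshold
  over_bi <- st$n_alleles > 2L

  by_locus <- split(seq_len(nrow(st)), st$locus_id)
  keep_locus <- vapply(by_locus, function(i) {
    p <- poly[i]
    any(p) &&
      all(pres_ok[i][p]) &&
      (!cfg$require_biallelic || !any(over_bi[i])) &&
      sum(p) <= cfg$max_snps_per_locus
  }, logical(1L))
  kept <- unlist(by_locus[keep_locus], use.names = FALSE)
  kept <- kept[poly[kept]]
  kept <- sort(kept)
  keys <- st$site_key[kept]
  filtered <- if (length(keys)) subset_sites(x, keys) else {
    stopf("no loci pass the shared-locus filter")
  }
  structure(list(matrix = filtered, cfg = cfg,
                 n_input_loci = n_loci(x),
                 n_shared_loci = n_loci(filtered),
                 n_markers = n_sites(filtered)),
            class = "shared_locus_set")
}

#' @export
print.shared_locus_set <- function(x, ...) {
  cat(sprintf(
    "shared_locus_set: %d / %d loci retained (%d markers) at presence >= %.2f, cap %s SNPs/locus\n",
    x$n_shared_loci, x$n_input_loci, x$n_markers,
    x$cfg$presence_threshold, format(x$cfg$max_snps_per_locus)))
  invisible(x)
}

#' Cumulative SNPs-per-locus marker count table
#'
#' Builds the per-taxon table of species-specific marker counts by
#' SNPs-per-locus cap: row `k` counts, per focal taxon, the markers lying on
#' loci that carry at most `k` species-specific SNPs, so rows are cumulative
#' ("up to k SNPs per locus"). A `total` column sums each row across taxa.
#'
#' @param counts Numeric matrix of cumulative counts, rows = caps `1..K`
#'   (rownames optional), columns = taxa. Checked for row-monotonicity.
#' @return A `snps_per_locus_table`: the count matrix with a `total` column.
#' @seealso [tabulate_snps_per_locus()] to build one from a catalog.
#' @export
snps_per_locus_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stopf("counts needs taxon column names")
  if (nrow(counts) > 1L && any(diff(counts) < 0)) {
    stopf("rows must be cumulative: counts at cap k cannot exceed cap k+1")
  }
  out <- cbind(counts, total = rowSums(counts))
  rownames(out) <- rownames(counts) %||% paste0("1-", seq_len(nrow(counts)))
  structure(out, class = c("snps_per_locus_table", class(out)))
}

#' Tabulate diagnostic markers by species-specific SNPs per locus
#'
#' @param catalog A `diagnostic_catalog` from [find_diagnostic_markers()],
#'   built with a cap of at least `max_k` so that loci up to `max_k`
#'   species-specific SNPs are represented.
#' @param max_k Largest SNPs-per-locus cap to tabulate (rows `1..max_k`).
#' @return A [snps_per_locus_table] with one column per analysed taxon.
#' @export
tabulate_snps_per_locus <- function(catalog, max_k = 5L) {
  stopifnot(inherits(catalog, "diagnostic_catalog"), is_count(max_k))
  taxa <- attr(catalog, "taxa")
  counts <- vapply(seq_len(max_k), function(k) {
    sub <- catalog[catalog$snps_on_locus <= k, , drop = FALSE]
    as.integer(table(factor(sub$focal_taxon, levels = taxa)))
  }, integer(length(taxa)))
  counts <- t(counts)
  dimnames(counts) <- list(paste0("1-", seq_len(max_k)), taxa)
  snps_per_locus_table(counts)
}

#' Read a published-style marker count table
#'
#' Reads a TSV with columns `max_snps_per_locus`, `analysis` and one column
#' per taxon, holding cumulative species-specific marker counts (the layout
#' in which such tables are printed), and returns one
#' [snps_per_locus_table] per analysis.
#'
#' @param path Path to the TSV.
#' @return Named list of [snps_per_locus_table] objects, one per analysis.
#' @export
read_marker_count_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("max_snps_per_locus", "analysis")
  if (!all(need %in% colnames(tab))) {
    stopf("marker count table needs columns: %s", paste(need, collapse = ", "))
  }
  taxa <- setdiff(colnames(tab), need)
  lapply(split(tab, tab$analysis), function(d) {
    d <- d[order(d$max_snps_per_locus), , drop = FALSE]
    m <- as.matrix(d[, taxa, drop = FALSE])
    rownames(m) <- paste0("1-", d$max_snps_per_locus)
    snps_per_locus_table(m)
  })
}
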