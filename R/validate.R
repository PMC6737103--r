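#' Construct a diagnostic-allele frequency table
#'
#' @param freq Numeric matrix of diagnostic-allele frequencies in percent,
#'   markers x taxa (`NA` where no individual of the taxon was genotyped).
#' @param focal_taxon Character vector, one focal taxon per marker (must be
#'   a column of `freq`).
#' @param diagnostic_allele Optional character vector of diagnostic alleles.
#' @param n Optional named integer vector of per-taxon sample sizes.
#' @param excluded_taxon Optional character vector: for markers designed to
#'   discriminate only a subset of the taxa, the taxon excluded from the
#'   discrimination set (`NA` for full designs).
#' @return A `freq_table`.
#' @seealso [allele_frequency_table()], [classify_markers()]
#' @export
freq_table <- function(freq, focal_taxon, diagnostic_allele = NULL,
                       n = NULL, excluded_taxon = NULL) {
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) stopf("freq needs taxon column names")
  if (length(focal_taxon) != nrow(freq)) {
    stopf("focal_taxon must have one entry per marker row")
  }
  if (!all(focal_taxon %in% colnames(freq))) {
    stopf("focal taxa must be columns of the frequency matrix")
  }
  rng <- range(freq, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 100) stopf("frequencies must lie in [0, 100]")
  structure(freq, class = c("freq_table", class(freq)),
            focal_taxon = focal_taxon,
            diagnostic_allele = diagnostic_allele,
            n = n,
            excluded_taxon = excluded_taxon %||%
              rep(NA_character_, nrow(freq)))
}

#' Per-taxon diagnostic-allele frequencies for a marker catalog
#'
#' For every marker and taxon, the frequency of the diagnostic allele among
#' the non-missing alleles of the taxon (two per genotyped individual),
#' expressed in percent. Individuals with missing calls are excluded from
#' the denominator; a taxon with no genotyped individual yields `NA` (not
#' 0). Exact values are stored; the print method rounds to whole percent.
#'
#' @param x A [geno_matrix] containing every catalog marker.
#' @param catalog A `diagnostic_catalog`.
#' @return A [freq_table], markers x taxa, with per-taxon `n` attribute.
#' @export
allele_frequency_table <- function(x, catalog) {
  stopifnot(inherits(x, "geno_matrix"), inherits(catalog, "diagnostic_catalog"))
  miss <- setdiff(catalog$site_key, x$sites$site_key)
  if (length(miss)) stopf("marker(s) absent from the genotype matrix: %s",
                          paste(miss, collapse = ", "))
  g <- taxa_of(x$samples)
  taxa <- unique(g)
  j <- match(catalog$site_key, x$sites$site_key)
  freq <- matrix(NA_real_, nrow(catalog), length(taxa),
                 dimnames = list(catalog$site_key, taxa))
  for (t in taxa) {
    k <- which(g == t)
    a1 <- x$a1[j, k, drop = FALSE]; a2 <- x$a2[j, k, drop = FALSE]
    n_alleles <- 2L * rowSums(!is.na(a1))
    hits <- rowSums(a1 == catalog$diagnostic_allele, na.rm = TRUE) +
      rowSums(a2 == catalog$diagnostic_allele, na.rm = TRUE)
    freq[, t] <- ifelse(n_alleles > 0L, 100 * hits / n_alleles, NA_real_)
  }
  freq_table(freq, catalog$focal_taxon,
             diagnostic_allele = catalog$diagnostic_allele,
             n = group_sizes(x$samples)[taxa],
             excluded_taxon = catalog$excluded_taxon)
}

#' Read a diagnostic-allele frequency table from TSV
#'
#' Layout: columns `marker`, `focal_taxon`, `diagnostic_allele`,
#' `excluded_taxon`, then one column per taxon with percent frequencies. An
#' optional comment line `# taxon_n: A=30,B=22,...` carries per-taxon sample
#' sizes.
#'
#' @param path Path to the TSV.
#' @return A [freq_table].
#' @export
read_freq_table <- function(path) {
  first <- readLines(path, n = 1L)
  n <- NULL
  if (grepl("^#\\s*taxon_n:", first)) {
    spec <- sub("^#\\s*taxon_n:\\s*", "", first)
    parts <- strsplit(strsplit(spec, ",")[[1L]], "=")
    n <- stats::setNames(as.integer(vapply(parts, `[`, "", 2L)),
                         trimws(vapply(parts, `[`, "", 1L)))
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  meta <- c("marker", "focal_taxon", "diagnostic_allele", "excluded_taxon")
  if (!all(meta %in% colnames(tab))) {
    stopf("frequency table needs columns: %s", paste(meta, collapse = ", "))
  }
  taxa <- setdiff(colnames(tab), meta)
  freq <- as.matrix(tab[, taxa, drop = FALSE])
  rownames(freq) <- tab$marker
  excl <- as.character(tab$excluded_taxon)
  excl[excl %in% c("", "NA")] <- NA_character_
  freq_table(freq, tab$focal_taxon,
             diagnostic_allele = tab$diagnostic_allele,
             n = n, excluded_taxon = excl)
}

#' Classify markers by diagnostic specificity
#'
#' Each marker is judged on its *discrimination set*: all table taxa except
#' the marker's designated excluded taxon (for designs meant to separate
#' only a subset of the taxa). Tiers, with `f` the diagnostic-allele percent
#' in the focal taxon and `o` the maximum percent in the other taxa of the
#' set:
#'
#' * `fully_diagnostic` — `f == 100` and `o == 0`;
#' * `near_diagnostic_target_leak` — `o == 0` but `f < 100` (the target
#'   shows some alternate allele);
#' * `near_diagnostic_offtarget_leak` — `f == 100` but `0 < o <=
#'   leak_cutoff_pct`;
#' * `failed` — everything else (off-target leak above the cutoff, or leaks
#'   on both sides).
#'
#' Raising `leak_cutoff_pct` can only move markers out of `failed`, never
#' into it.
#'
#' @param table A [freq_table].
#' @param leak_cutoff_pct Maximum tolerated off-target frequency (percent).
#' @return `data.frame` with `marker`, `focal_taxon`, `tier`,
#'   `target_leak_pct` (alternate-allele percent in the target) and
#'   `max_offtarget_pct`.
#' @export
classify_markers <- function(table, leak_cutoff_pct = 5) {
  stopifnot(inherits(table, "freq_table"))
  focal <- attr(table, "focal_taxon")
  excl <- attr(table, "excluded_taxon")
  taxa <- colnames(table)
  out <- lapply(seq_len(nrow(table)), function(i) {
    set <- setdiff(taxa, excl[i])
    f <- table[i, focal[i]]
    o <- suppressWarnings(max(table[i, setdiff(set, focal[i])], na.rm = TRUE))
    if (!is.finite(o)) o <- NA_real_
    tier <- if (is.na(f) || is.na(o)) {
      "failed"
    } else if (f == 100 && o == 0) {
      "fully_diagnostic"
    } else if (o == 0 && f < 100) {
      "near_diagnostic_target_leak"
    } else if (f == 100 && o <= leak_cutoff_pct) {
      "near_diagnostic_offtarget_leak"
    } else {
      "failed"
    }
    data.frame(marker = rownames(table)[i] %||% as.character(i),
               focal_taxon = focal[i], tier = tier,
               target_leak_pct = 100 - f, max_offtarget_pct = o,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d marker(s) x %d taxa (%% diagnostic allele)\n",
              nrow(x), ncol(x)))
  m <- round(unclass(x))
  print(m)
  invisible(x)
}

#' Cross-platform genotype concordance with mismatch typing
#'
#' Compares two genotype matrices (e.g. ddRAD-derived calls against KASP
#' assay results) over their shared markers (matched by site key) and shared
#' samples. A cell missing in either platform is excluded from the
#' comparable count; matching is on unordered allele pairs. Mismatches are
#' typed as heterozygote-vs-homozygote, discordant homozygotes, or
#' discordant heterozygotes. The match percentage is stored exactly and
#' rounded only for display.
#'
#' @param matrix_a,matrix_b Two [geno_matrix] objects sharing at least one
#'   sample and one marker.
#' @return A `concordance_report` list: `n_sites`, `n_samples`, `n_cells`,
#'   `n_missing_a`, `n_missing_b`, `n_comparable`, `n_match`, `n_mismatch`,
#'   `mismatch_types` (named counts) and `percent_match`.
#' @export
genotype_concordance <- function(matrix_a, matrix_b) {
  stopifnot(inherits(matrix_a, "geno_matrix"), inherits(matrix_b, "geno_matrix"))
  sites <- intersect(matrix_a$sites$site_key, matrix_b$sites$site_key)
  samples <- intersect(sample_ids(matrix_a), sample_ids(matrix_b))
  if (length(sites) == 0L || length(samples) == 0L) {
    stopf("matrices share %d marker(s) and %d sample(s); need >= 1 of each",
          length(sites), length(samples))
  }
  ia <- match(sites, matrix_a$sites$site_key)
  ib <- match(sites, matrix_b$sites$site_key)
  ja <- match(samples, sample_ids(matrix_a))
  jb <- match(samples, sample_ids(matrix_b))
  a1 <- matrix_a$a1[ia, ja, drop = FALSE]; a2 <- matrix_a$a2[ia, ja, drop = FALSE]
  b1 <- matrix_b$a1[ib, jb, drop = FALSE]; b2 <- matrix_b$a2[ib, jb, drop = FALSE]
  miss_a <- is.na(a1); miss_b <- is.na(b1)
  comparable <- !miss_a & !miss_b
  same <- comparable & a1 == b1 & a2 == b2
  het_a <- a1 != a2; het_b <- b1 != b2
  mm <- comparable & !same
  types <- c(
    het_vs_hom = sum(mm & xor(het_a, het_b), na.rm = TRUE),
    hom_vs_hom_discordant = sum(mm & !het_a & !het_b, na.rm = TRUE),
    het_vs_het_discordant = sum(mm & het_a & het_b, na.rm = TRUE))
  n_comp <- sum(comparable)
  structure(list(
    n_sites = length(sites), n_samples = length(samples),
    n_cells = length(sites) * length(samples),
    n_missing_a = sum(miss_a), n_missing_b = sum(miss_b),
    n_comparable = n_comp,
    n_match = sum(same), n_mismatch = sum(mm),
    mismatch_types = types,
    percent_match = if (n_comp > 0L) 100 * sum(same) / n_comp else NA_real_),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance_report: %d marker(s) x %d sample(s) = %d cells\n",
    x$n_sites, x$n_samples, x$n_cells))
  cat(sprintf("  missing: %d (a), %d (b); comparable: %d\n",
              x$n_missing_a, x$n_missing_b, x$n_comparable))
  cat(sprintf("  match: %d/%d (%.1f%%)\n",
              x$n_match, x$n_comparable, x$percent_match))
  if (x$n_mismatch > 0L) {
    cat("  mismatches: ",
        paste(names(x$mismatch_types), x$mismatch_types,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
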