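#' Diploid genotype matrix
#'
#' The substrate of every analysis stage: unphased diploid calls at SNP sites
#' (rows) for samples (columns). Genotypes are unordered allele pairs over
#' A/C/G/T; a missing call has both alleles absent. Sites belong to loci
#' (RAD-tags) and may carry a 0-based offset within the tag and/or a 1-based
#' reference coordinate.
#'
#' @param gt Character matrix of genotypes, sites x samples. Accepted cell
#'   formats: `"AG"`, `"A/G"`, `"A|G"`, and `NA` or `"NA"` for missing. Pairs
#'   are stored unordered (`"AG"` and `"GA"` are the same call).
#' @param samples A [species_map]; its sample ids must equal `colnames(gt)`
#'   as a set (columns are reordered to map order).
#' @param sites Optional `data.frame` with any of the columns `site_key`,
#'   `locus_id`, `site_index`, `offset_bp`, `chrom`, `pos`, `ref`, `alt`
#'   (rows parallel to `gt`). By default each row of `gt` is its own
#'   single-site locus named by its rowname.
#' @param tag_length Default RAD-tag length (bp) recorded for loci without an
#'   explicit length.
#' @return A `geno_matrix` object.
#' @examples
#' sm <- species_map(c("a1", "a2", "b1"), c("A", "A", "B"))
#' gt <- rbind(s1 = c("AA", "AA", "GG"), s2 = c("AG", NA, "CC"))
#' colnames(gt) <- sm$sample_id
#' gm <- geno_matrix(gt, sm)
#' dim(gm)
#' @export
geno_matrix <- function(gt, samples, sites = NULL, tag_length = 148L) {
  stopifnot(inherits(samples, "species_map"), is.matrix(gt))
  if (is.null(colnames(gt))) stopf("gt needs sample ids as colnames")
  if (!setequal(colnames(gt), samples$sample_id)) {
    stopf("gt columns and species map samples differ: %s",
          paste(union(setdiff(colnames(gt), samples$sample_id),
                      setdiff(samples$sample_id, colnames(gt))),
                collapse = ", "))
  }
  gt <- gt[, samples$sample_id, drop = FALSE]
  if (is.null(rownames(gt))) rownames(gt) <- paste0("site", seq_len(nrow(gt)))
  g <- gsub("[/|]", "", as.character(gt))
  g[g %in% c("NA", "")] <- NA_character_
  bad <- !is.na(g) & !grepl("^[ACGT]{2}$", g)
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf("malformed genotype '%s' at site '%s', sample '%s'",
          gt[i], rownames(gt)[(i - 1L) %% nrow(gt) + 1L],
          colnames(gt)[(i - 1L) %/% nrow(gt) + 1L])
  }
  x1 <- substr(g, 1L, 1L)
  x2 <- substr(g, 2L, 2L)
  a1 <- matrix(pmin(x1, x2), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  a2 <- matrix(pmax(x1, x2), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  sites <- complete_site_info(sites, rownames(gt))
  rownames(a1) <- rownames(a2) <- sites$site_key
  loci <- data.frame(locus_id = unique(sites$locus_id),
                     tag_length = as.integer(tag_length),
                     stringsAsFactors = FALSE)
  new_geno_matrix(a1, a2, sites, samples, loci)
}

complete_site_info <- function(sites, keys) {
  n <- length(keys)
  if (is.null(sites)) sites <- data.frame(row.names = seq_len(n))
  if (nrow(sites) != n) stopf("sites has %d rows for %d sites", nrow(sites), n)
  defaults <- list(site_key = keys, locus_id = keys,
                   site_index = rep.int(0L, n),
                   offset_bp = rep.int(NA_integer_, n),
                   chrom = rep.int(NA_character_, n),
                   pos = rep.int(NA_integer_, n),
                   ref = rep.int(NA_character_, n),
                   alt = rep.int(NA_character_, n))
  for (nm in names(defaults)) {
    if (is.null(sites[[nm]])) sites[[nm]] <- defaults[[nm]]
  }
  sites$site_index <- as.integer(sites$site_index)
  sites$offset_bp <- as.integer(sites$offset_bp)
  sites$pos <- as.integer(sites$pos)
  if (anyDuplicated(sites$site_key)) stopf("duplicate site keys")
  rownames(sites) <- NULL
  sites[c("site_key", "locus_id", "site_index", "offset_bp",
          "chrom", "pos", "ref", "alt")]
}

new_geno_matrix <- function(a1, a2, sites, samples, loci) {
  x <- structure(list(a1 = a1, a2 = a2, sites = sites,
                      samples = samples, loci = loci),
                 class = "geno_matrix")
  validate_geno_matrix(x)
}

validate_geno_matrix <- function(x) {
  stopifnot(identical(dim(x$a1), dim(x$a2)),
            nrow(x$a1) == nrow(x$sites),
            ncol(x$a1) == nrow(x$samples))
  miss1 <- is.na(x$a1); miss2 <- is.na(x$a2)
  if (!identical(miss1, miss2)) {
    stopf("half-calls are not supported: both alleles must be present or absent")
  }
  if (!all(x$sites$locus_id %in% x$loci$locus_id)) stopf("orphan locus ids")
  x
}

#' @export
dim.geno_matrix <- function(x) dim(x$a1)

#' Number of sites / loci / samples in a genotype matrix
#' @param x A `geno_matrix`.
#' @return Integer scalar.
#' @export
n_sites <- function(x) nrow(x$a1)

#' @rdname n_sites
#' @export
n_loci <- function(x) nrow(x$loci)

#' @rdname n_sites
#' @export
n_samples <- function(x) ncol(x$a1)

#' @rdname n_sites
#' @export
sample_ids <- function(x) x$samples$sample_id

#' Site and locus metadata of a genotype matrix
#' @param x A `geno_matrix`.
#' @return `data.frame` of per-site (or per-locus) metadata.
#' @export
site_info <- function(x) x$sites

#' @rdname site_info
#' @export
locus_info <- function(x) x$loci

#' Genotype calls as an unordered-pair character matrix
#'
#' @param x A `geno_matrix`.
#' @param sep Separator between the two alleles.
#' @return Character matrix sites x samples, `NA` for missing calls.
#' @export
genotype_calls <- function(x, sep = "/") {
  m <- matrix(paste(x$a1, x$a2, sep = sep), nrow(x$a1), ncol(x$a1),
              dimnames = dimnames(x$a1))
  m[is.na(x$a1)] <- NA_character_
  m
}

#' Per-site allele copy counts
#'
#' @param x A `geno_matrix`.
#' @param samples Optional sample ids to restrict the count to.
#' @return Integer matrix sites x 4 (columns A, C, G, T) of observed allele
#'   copies among non-missing calls.
#' @export
allele_counts <- function(x, samples = NULL) {
  a1 <- x$a1; a2 <- x$a2
  if (!is.null(samples)) {
    a1 <- a1[, samples, drop = FALSE]
    a2 <- a2[, samples, drop = FALSE]
  }
  out <- vapply(BASES, function(b) {
    rowSums(a1 == b, na.rm = TRUE) + rowSums(a2 == b, na.rm = TRUE)
  }, numeric(nrow(a1)))
  out <- matrix(as.integer(out), nrow(a1), 4L,
                dimnames = list(rownames(a1), BASES))
  out
}

#' Observed alleles at each site
#'
#' The allele set of a site is the union of alleles over its non-missing
#' calls (restricted to `samples` when given).
#'
#' @inheritParams allele_counts
#' @return Named list of character vectors, one per site.
#' @export
site_alleles <- function(x, samples = NULL) {
  ac <- allele_counts(x, samples)
  apply(ac > 0L, 1L, function(r) BASES[r], simplify = FALSE)
}

#' Subset a genotype matrix
#'
#' `subset_sites()` keeps the given sites (by site key); `subset_samples()`
#' keeps the given samples; `subset_taxa()` keeps all samples whose taxon (at
#' the active level) is in `taxa`. Locus metadata is trimmed to the loci that
#' retain at least one site.
#'
#' @param x A `geno_matrix`.
#' @param keys Site keys to keep (order preserved as given).
#' @return A `geno_matrix`.
#' @export
subset_sites <- function(x, keys) {
  idx <- match(keys, x$sites$site_key)
  if (anyNA(idx)) stopf("unknown site key(s): %s",
                        paste(keys[is.na(idx)], collapse = ", "))
  sites <- x$sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  loci <- x$loci[x$loci$locus_id %in% sites$locus_id, , drop = FALSE]
  rownames(loci) <- NULL
  new_geno_matrix(x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE],
                  sites, x$samples, loci)
}

#' @rdname subset_sites
#' @param ids Sample ids to keep.
#' @export
subset_samples <- function(x, ids) {
  idx <- match(ids, x$samples$sample_id)
  if (anyNA(idx)) stopf("unknown sample id(s): %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  sm <- x$samples[idx, , drop = FALSE]
  rownames(sm) <- NULL
  class(sm) <- c("species_map", "data.frame")
  attr(sm, "taxon_level") <- taxon_level(x$samples)
  new_geno_matrix(x$a1[, idx, drop = FALSE], x$a2[, idx, drop = FALSE],
                  x$sites, sm, x$loci)
}

#' @rdname subset_sites
#' @param taxa Taxon labels (at the active taxon level) to keep.
#' @export
subset_taxa <- function(x, taxa) {
  g <- taxa_of(x$samples)
  absent <- setdiff(taxa, g)
  if (length(absent)) stopf("taxa with zero samples: %s",
                            paste(absent, collapse = ", "))
  subset_samples(x, x$samples$sample_id[g %in% taxa])
}

#' @export
print.geno_matrix <- function(x, ...) {
  gs <- group_sizes(x$samples)
  cat(sprintf("geno_matrix: %d sites on %d loci x %d samples (%d %s groups)\n",
              n_sites(x), n_loci(x), n_samples(x), length(gs),
              taxon_level(x$samples)))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}
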