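# IUPAC codes for unordered diploid genotypes (hom -> base, het -> 2-fold
# ambiguity, missing -> N); inverse used by alignment round-trips
IUPAC_OF_PAIR <- c(AA = "A", CC = "C", GG = "G", TT = "T",
                   AC = "M", AG = "R", AT = "W",
                   CG = "S", CT = "Y", GT = "K")
PAIR_OF_IUPAC <- stats::setNames(names(IUPAC_OF_PAIR), IUPAC_OF_PAIR)

#' Composite genotypes as IUPAC sequences
#'
#' Concatenates each sample's SNP calls into one sequence (the composite
#' genotype used as a phylogenetic character matrix): homozygotes map to the
#' base, heterozygotes to the two-fold IUPAC ambiguity code, missing calls
#' to `N`. Column order is deterministic: (chrom, pos, locus, site index),
#' unknown coordinates last.
#'
#' @param x A [geno_matrix] with >= 1 site.
#' @return Named character vector, one sequence per sample; the ordered site
#'   keys are attached as attribute `site_keys`.
#' @export
composite_genotypes <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  if (n_sites(x) == 0L) stopf("empty genotype matrix")
  ord <- site_order(x$sites)
  code <- IUPAC_OF_PAIR[paste0(x$a1[ord, , drop = FALSE],
                               x$a2[ord, , drop = FALSE])]
  code[is.na(code)] <- "N"
  m <- matrix(code, length(ord), n_samples(x))
  seqs <- apply(m, 2L, paste, collapse = "")
  names(seqs) <- sample_ids(x)
  attr(seqs, "site_keys") <- x$sites$site_key[ord]
  seqs
}

#' Export a composite-genotype alignment
#'
#' Writes the [composite_genotypes()] of a matrix as FASTA or relaxed
#' (sequential) PHYLIP, suitable as input for external tree builders such as
#' RAxML.
#'
#' @param x A [geno_matrix] with >= 2 samples and >= 1 site.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
export_composite_alignment <- function(x, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (n_samples(x) < 2L) stopf("alignment export needs >= 2 samples")
  seqs <- composite_genotypes(x)
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", names(seqs)), seqs))
  } else {
    c(sprintf("%d %d", length(seqs), nchar(seqs[[1L]])),
      paste(names(seqs), seqs, sep = "  "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Allele-sharing distance between samples
#'
#' For each pair of samples, `d = 1 - shared / (2 * m)` where `m` is the
#' number of sites called in both and `shared` is the number of alleles the
#' two unordered genotypes have in common at those sites (0, 1 or 2 per
#' site, counting multiplicity). Identical genotypes give 0; fully
#' discordant homozygotes give 1. The result is symmetric with a zero
#' diagonal; the triangle inequality is not guaranteed.
#'
#' @param x A [geno_matrix] with >= 2 samples.
#' @return Symmetric numeric matrix, samples x samples.
#' @export
allele_sharing_distance <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  n <- n_samples(x)
  if (n < 2L) stopf("distance needs >= 2 samples")
  ids <- sample_ids(x)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    xi1 <- x$a1[, i]; xi2 <- x$a2[, i]
    for (j in (i + 1L):n) {
      yj1 <- x$a1[, j]; yj2 <- x$a2[, j]
      both <- !is.na(xi1) & !is.na(yj1)
      m <- sum(both)
      if (m == 0L) stopf("samples '%s' and '%s' share no genotyped site",
                         ids[i], ids[j])
      a1 <- xi1[both]; a2 <- xi2[both]; b1 <- yj1[both]; b2 <- yj2[both]
      identical_pair <- a1 == b1 & a2 == b2
      overlap <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
      shared <- sum(2L * identical_pair + (!identical_pair & overlap))
      d[i, j] <- d[j, i] <- 1 - shared / (2 * m)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via [ape::nj()]) on a symmetric distance
#' matrix, returned as a Newick string with branch lengths. Used as an
#' internal species-discrimination check: with species-level fixed
#' differences planted in the data, samples of each species should form a
#' clade.
#'
#' @param dm Symmetric numeric distance matrix with >= 3 samples.
#' @return Newick string (single tree, terminated by `;`).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stopf("neighbor-joining needs >= 3 samples")
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stopf("distance matrix must be symmetric")
  }
  phy <- ape::nj(stats::as.dist(dm))
  ape::write.tree(phy)
}

#' Export catalog markers as BED intervals
#'
#' One 0-based half-open single-base interval per marker with a known
#' reference position (`chrom` + 1-based `pos`), named by site key and
#' sorted by (chrom, start). Markers without coordinates are skipped with a
#' reported counter.
#'
#' @param catalog A `diagnostic_catalog`.
#' @param path Output path.
#' @return `path` invisibly, with attribute `n_skipped`.
#' @export
export_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "diagnostic_catalog"))
  known <- !is.na(catalog$chrom) & !is.na(catalog$pos)
  if (any(known & catalog$pos <= 0L)) stopf("positions must be 1-based (> 0)")
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    message(sprintf("export_bed: skipped %d marker(s) without coordinates",
                    n_skipped))
  }
  d <- catalog[known, , drop = FALSE]
  d <- d[order(d$chrom, d$pos, d$site_key, method = "radix"), , drop = FALSE]
  writeLines(paste(d$chrom, d$pos - 1L, d$pos, d$site_key, sep = "\t"), path)
  out <- invisible(path)
  attr(out, "n_skipped") <- n_skipped
  invisible(out)
}
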