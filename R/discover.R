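#' Classify one site's allele pattern per taxon
#'
#' For each analysed taxon a site is `fixed(allele)` when every non-missing
#' call in the taxon is homozygous for that one allele, `polymorphic` when
#' the taxon shows a heterozygote or more than one allele (strict: a single
#' heterozygote disqualifies), and `insufficient` when fewer than the
#' presence threshold of the taxon's samples are genotyped.
#'
#' @param x A [geno_matrix].
#' @param site A site key.
#' @param cfg A [filter_config] (presence threshold and taxon level).
#' @param taxa Taxa to classify (default: all taxa in the matrix).
#' @return A `site_partition`: data.frame with one row per taxon (`taxon`,
#'   `status`, `allele`, `presence`) plus the site's observed allele count as
#'   attribute `n_alleles`.
#' @export
partition_site <- function(x, site, cfg = filter_config(), taxa = NULL) {
  taxon_level(x) <- cfg$taxon_level
  g <- taxa_of(x$samples)
  if (is.null(taxa)) taxa <- unique(g)
  absent <- setdiff(taxa, g)
  if (length(absent)) stopf("taxa with zero samples: %s",
                            paste(absent, collapse = ", "))
  j <- match(site, x$sites$site_key)
  if (is.na(j)) stopf("unknown site key '%s'", site)
  rows <- lapply(taxa, function(t) {
    k <- which(g == t)
    a1 <- x$a1[j, k]; a2 <- x$a2[j, k]
    called <- !is.na(a1)
    pres <- mean(called)
    if (pres < cfg$presence_threshold) {
      status <- "insufficient"; allele <- NA_character_
    } else {
      obs <- unique(c(a1[called], a2[called]))
      if (any(a1[called] != a2[called]) || length(obs) > 1L) {
        status <- "polymorphic"; allele <- NA_character_
      } else {
        status <- "fixed"; allele <- obs
      }
    }
    data.frame(taxon = t, status = status, allele = allele,
               presence = pres, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_alleles") <- sum(allele_counts(x)[j, ] > 0L)
  class(out) <- c("site_partition", "data.frame")
  out
}

# vectorised per-taxon fixation over all sites; returns list of matrices
taxon_fixation <- function(x, taxa, grp, thr) {
  nS <- n_sites(x)
  pres <- matrix(0, nS, length(taxa), dimnames = list(NULL, taxa))
  fixed <- matrix(FALSE, nS, length(taxa), dimnames = list(NULL, taxa))
  allele <- matrix(NA_character_, nS, length(taxa), dimnames = list(NULL, taxa))
  for (t in taxa) {
    k <- which(grp == t)
    a1 <- x$a1[, k, drop = FALSE]; a2 <- x$a2[, k, drop = FALSE]
    ncall <- rowSums(!is.na(a1))
    pres[, t] <- ncall / length(k)
    has_het <- rowSums(a1 != a2, na.rm = TRUE) > 0L
    ind <- vapply(BASES, function(b) {
      rowSums(a1 == b, na.rm = TRUE) + rowSums(a2 == b, na.rm = TRUE) > 0L
    }, logical(nS))
    if (nS == 1L) ind <- matrix(ind, 1L, 4L)
    n_all <- rowSums(ind)
    f <- pres[, t] >= thr & ncall > 0L & !has_het & n_all == 1L
    fixed[, t] <- f
    if (any(f)) allele[f, t] <- BASES[max.col(ind[f, , drop = FALSE])]
  }
  list(presence = pres, fixed = fixed, allele = allele)
}

#' Find species-specific (one-vs-rest fixed-difference) markers
#'
#' The core discovery stage. A biallelic SNP site is diagnostic for a focal
#' taxon when every analysed taxon is fixed (no intraspecific polymorphism,
#' presence at least the threshold in each taxon), the focal taxon is fixed
#' for one allele and all other taxa are fixed for the other. With exactly
#' two analysed taxa every fixed difference separates both; one marker per
#' site is then reported, with the first taxon as focal.
#'
#' Unless `prefilter = FALSE`, the matrix is first restricted to the analysed
#' taxa and passed through [filter_shared_loci()] with the SNPs-per-locus cap
#' disabled — at this stage the cap instead applies to the number of
#' species-specific SNPs found on a locus (`snps_on_locus`), and loci over
#' the cap are dropped whole. Fixation is always recomputed on the analysed
#' subset, since segregation depends on which samples are included.
#'
#' @param x A [geno_matrix].
#' @param cfg A [filter_config].
#' @param taxa Taxa to analyse (>= 2; default all taxa at the configured
#'   level).
#' @param prefilter Apply the shared-locus filter internally first.
#' @return A `diagnostic_catalog`: data.frame with one row per marker
#'   (`site_key`, `locus_id`, `site_index`, `offset_bp`, `chrom`, `pos`,
#'   `focal_taxon`, `diagnostic_allele`, `alternate_allele`,
#'   `snps_on_locus`, `excluded_taxon`, and `presence.<taxon>` columns),
#'   ordered by (chrom, pos, locus, site); attributes `taxa`, `cfg` and
#'   `per_taxon_counts`.
#' @export
find_diagnostic_markers <- function(x, cfg = filter_config(), taxa = NULL,
                                    prefilter = TRUE) {
  stopifnot(inherits(x, "geno_matrix"), inherits(cfg, "filter_config"))
  taxon_level(x) <- cfg$taxon_level
  g <- taxa_of(x$samples)
  if (is.null(taxa)) taxa <- unique(g)
  if (length(taxa) < 2L) stopf("diagnostic discovery needs >= 2 taxa")
  absent <- setdiff(taxa, g)
  if (length(absent)) stopf("taxa with zero samples: %s",
                            paste(absent, collapse = ", "))
  x <- subset_taxa(x, taxa)
  n_per <- group_sizes(x$samples)[taxa]
  if (any(n_per == 1L)) {
    message(sprintf(
      "find_diagnostic_markers: taxa with a single sample (fixation unverifiable at n = 1): %s",
      paste(names(n_per)[n_per == 1L], collapse = ", ")))
  }
  if (prefilter) {
    cfg0 <- cfg
    cfg0$max_snps_per_locus <- Inf
    x <- filter_shared_loci(x, cfg0)$matrix
  }
  grp <- taxa_of(x$samples)
  fx <- taxon_fixation(x, taxa, grp, cfg$presence_threshold)
  all_fixed <- rowSums(fx$fixed) == length(taxa)

  hits <- list()
  for (j in which(all_fixed)) {
    al <- fx$allele[j, ]
    tab <- table(al)
    if (length(tab) != 2L) next  # needs exactly two alleles across taxa
    if (length(taxa) == 2L) {
      focal <- taxa[1L]
    } else {
      singles <- names(tab)[tab == 1L]
      if (length(singles) != 1L) next  # not a one-vs-rest partition
      focal <- taxa[al == singles]
    }
    diag_allele <- al[[focal]]
    alt_allele <- setdiff(names(tab), diag_allele)
    hits[[length(hits) + 1L]] <- data.frame(
      site_key = x$sites$site_key[j], focal_taxon = focal,
      diagnostic_allele = diag_allele, alternate_allele = alt_allele,
      stringsAsFactors = FALSE)
  }
  mk <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(site_key = character(), focal_taxon = character(),
               diagnostic_allele = character(), alternate_allele = character(),
               stringsAsFactors = FALSE)
  }
  idx <- match(mk$site_key, x$sites$site_key)
  mk <- cbind(mk[, "site_key", drop = FALSE],
              x$sites[idx, c("locus_id", "site_index", "offset_bp",
                             "chrom", "pos"), drop = FALSE],
              mk[, c("focal_taxon", "diagnostic_allele", "alternate_allele"),
                 drop = FALSE])
  rownames(mk) <- NULL
  ss_per_locus <- table(mk$locus_id)
  mk$snps_on_locus <- as.integer(ss_per_locus[mk$locus_id])
  mk$excluded_taxon <- rep(NA_character_, nrow(mk))
  pres <- fx$presence[idx, , drop = FALSE]
  colnames(pres) <- paste0("presence.", taxa)
  mk <- cbind(mk, as.data.frame(pres))
  mk <- mk[mk$snps_on_locus <= cfg$max_snps_per_locus, , drop = FALSE]
  mk <- mk[site_order(mk), , drop = FALSE]
  rownames(mk) <- NULL
  new_diagnostic_catalog(mk, taxa, cfg)
}

new_diagnostic_catalog <- function(mk, taxa, cfg) {
  counts <- table(factor(mk$focal_taxon, levels = taxa))
  structure(mk, class = c("diagnostic_catalog", "data.frame"),
            taxa = taxa, cfg = cfg,
            per_taxon_counts = stats::setNames(as.integer(counts), taxa))
}

#' @export
print.diagnostic_catalog <- function(x, ...) {
  cat(sprintf("diagnostic_catalog: %d marker(s) on %d locus/loci across %d taxa\n",
              nrow(x), length(unique(x$locus_id)), length(attr(x, "taxa"))))
  print(attr(x, "per_taxon_counts"))
  invisible(x)
}

#' Find markers diagnostic between one pair of taxa
#'
#' Equivalent to [find_diagnostic_markers()] restricted to `{taxon_a,
#' taxon_b}`: every fixed difference between the pair is diagnostic for
#' both; one marker per site is reported with `taxon_a` as focal. The number
#' of distinct loci carrying markers is attached as attribute `n_loci`.
#'
#' @param x A [geno_matrix].
#' @param taxon_a,taxon_b The two taxa (distinct).
#' @param cfg A [filter_config].
#' @return A `diagnostic_catalog` (see [find_diagnostic_markers()]).
#' @export
find_pairwise_diagnostics <- function(x, taxon_a, taxon_b,
                                      cfg = filter_config()) {
  if (identical(taxon_a, taxon_b)) stopf("taxon_a and taxon_b must differ")
  cat <- find_diagnostic_markers(x, cfg, taxa = c(taxon_a, taxon_b))
  attr(cat, "n_loci") <- length(unique(cat$locus_id))
  cat
}

#' Filter a catalog down to assay-designable candidates
#'
#' Retains markers for which a single-SNP PCR assay (e.g. KASP) can be
#' designed: the SNP must lie at least `cfg$min_edge_distance_bp` from both
#' ends of its RAD-tag (so flanking primers fit), and its locus must carry at
#' most two species-specific SNPs. Markers with unknown tag offset or tag
#' length are excluded and counted (attribute `n_unknown_offset`), not
#' silently dropped.
#'
#' @param catalog A `diagnostic_catalog`.
#' @param loci Locus metadata with `locus_id` and `tag_length` (default: the
#'   matrix locus table stored positions came from must be supplied here,
#'   e.g. `locus_info(x)`).
#' @param cfg A [filter_config].
#' @return The filtered `diagnostic_catalog`.
#' @export
filter_assay_candidates <- function(catalog, loci, cfg = filter_config()) {
  stopifnot(inherits(catalog, "diagnostic_catalog"))
  tl <- loci$tag_length[match(catalog$locus_id, loci$locus_id)]
  off <- catalog$offset_bp
  unknown <- is.na(off) | is.na(tl)
  if (any(unknown)) {
    message(sprintf(
      "filter_assay_candidates: excluded %d marker(s) with unknown offset or tag length",
      sum(unknown)))
  }
  d <- cfg$min_edge_distance_bp
  keep <- !unknown & off >= d & (tl - 1L - off) >= d & catalog$snps_on_locus <= 2L
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_diagnostic_catalog(out, attr(catalog, "taxa"), cfg)
  attr(out, "n_unknown_offset") <- sum(unknown)
  out
}

#' Select a balanced, genome-spread marker panel
#'
#' Greedy selection of `size` markers from a catalog, maximising first
#' balanced representation of focal taxa, then spread across linkage groups
#' (fewest selected markers per LG), with remaining ties broken by catalog
#' order — fully deterministic for identical inputs. When perfect taxon
#' balance is infeasible (a taxon runs out of markers) the best-effort panel
#' is returned with a warning.
#'
#' @param catalog A `diagnostic_catalog`.
#' @param size Panel size (<= number of markers in the catalog).
#' @param lg_of Optional named character vector mapping site keys to linkage
#'   groups; defaults to the catalog's `chrom` column (sites without an LG
#'   share the pseudo-group `"?"`).
#' @return A `panel`: list with `markers` (a `diagnostic_catalog`),
#'   `per_taxon` and `per_lg` counts.
#' @export
select_panel <- function(catalog, size, lg_of = NULL) {
  stopifnot(inherits(catalog, "diagnostic_catalog"))
  if (!is_count(size) || size > nrow(catalog)) {
    stopf("panel size must be an integer between 1 and the catalog size (%d)",
          nrow(catalog))
  }
  lg <- if (is.null(lg_of)) catalog$chrom else unname(lg_of[catalog$site_key])
  lg[is.na(lg)] <- "?"
  taxa <- attr(catalog, "taxa")
  taxa <- taxa[taxa %in% catalog$focal_taxon]
  chosen <- logical(nrow(catalog))
  taxon_count <- stats::setNames(integer(length(taxa)), taxa)
  lg_count <- stats::setNames(integer(length(unique(lg))), unique(lg))
  short <- FALSE
  for (step in seq_len(size)) {
    open <- vapply(taxa, function(t) any(!chosen & catalog$focal_taxon == t),
                   logical(1L))
    if (!any(open)) break
    if (!all(open)) short <- TRUE
    cand_taxa <- taxa[open]
    focal <- cand_taxa[which.min(taxon_count[cand_taxa])]
    cand <- which(!chosen & catalog$focal_taxon == focal)
    best <- cand[which.min(lg_count[lg[cand]])]
    chosen[best] <- TRUE
    taxon_count[focal] <- taxon_count[focal] + 1L
    lg_count[lg[best]] <- lg_count[lg[best]] + 1L
  }
  if (short && max(taxon_count) - min(taxon_count) > 1L) {
    warnf("select_panel: perfect taxon balance infeasible; best-effort panel returned")
  }
  mk <- catalog[chosen, , drop = FALSE]
  rownames(mk) <- NULL
  mk <- new_diagnostic_catalog(mk, attr(catalog, "taxa"), attr(catalog, "cfg"))
  structure(list(markers = mk,
                 per_taxon = taxon_count,
                 per_lg = lg_count[lg_count > 0L]),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("panel: %d marker(s)\n", nrow(x$markers)))
  cat("  per taxon: ")
  cat(paste(names(x$per_taxon), x$per_taxon, sep = "=", collapse = ", "), "\n")
  cat("  per LG:    ")
  cat(paste(names(x$per_lg), x$per_lg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
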