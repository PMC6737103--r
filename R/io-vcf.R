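#' Read diploid genotypes from a VCF file
#'
#' Each VCF record becomes one SNP site. Records are grouped into loci
#' (RAD-tags) through the ID column dialect `locus_offset` (e.g. `57_103` =
#' locus 57, 0-based offset 103 within the tag); when no ID follows the
#' dialect each record becomes its own single-site locus and a warning is
#' issued once, since per-locus SNP counts then degenerate to one SNP per
#' locus. Indels and symbolic alleles are skipped with a reported counter;
#' `./.` is missing; phased separators are accepted and unphased. Half-calls
#' (`A/.`) and non-diploid GT fields are rejected.
#'
#' @param path Path to a VCF 4.x file with per-sample GT fields.
#' @param species_map A [species_map] covering every VCF sample. Samples in
#'   the map but absent from the VCF are allowed and reported.
#' @param tag_length RAD-tag length (bp) assumed for all loci.
#' @return A [geno_matrix] restricted to the VCF samples, with VCF 1-based
#'   coordinates in `chrom`/`pos` and tag offsets 0-based in `offset_bp`.
#' @export
read_vcf <- function(path, species_map, tag_length = 148L) {
  stopifnot(inherits(species_map, "species_map"))
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  vcf_samples <- colnames(gt_raw)[-1L]
  unknown <- setdiff(vcf_samples, species_map$sample_id)
  if (length(unknown)) {
    stopf("VCF sample(s) missing from the species map: %s",
          paste(unknown, collapse = ", "))
  }
  extra <- setdiff(species_map$sample_id, vcf_samples)
  if (length(extra)) {
    message(sprintf("read_vcf: %d species-map sample(s) absent from the VCF: %s",
                    length(extra), paste(extra, collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  allele_list <- mapply(function(r, a) c(r, a[nzchar(a) & a != "."]),
                        ref, alt_list, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  snp_ok <- vapply(allele_list, function(a) all(a %in% BASES), logical(1L))
  n_skipped <- sum(!snp_ok)
  if (n_skipped > 0L) {
    message(sprintf(
      "read_vcf: skipped %d record(s) with indel or symbolic alleles", n_skipped))
  }
  keep <- which(snp_ok)
  if (length(keep) == 0L) stopf("VCF '%s' contains no usable SNP records", path)

  n <- length(keep)
  ns <- length(vcf_samples)
  a1 <- matrix(NA_character_, n, ns, dimnames = list(NULL, vcf_samples))
  a2 <- a1
  for (j in seq_len(n)) {
    r <- keep[j]
    g <- gt[r, ]
    g <- gsub("|", "/", g, fixed = TRUE)
    miss <- is.na(g) | g == "." | g == "./."
    gg <- g[!miss]
    if (length(gg)) {
      if (any(grepl(".", gg, fixed = TRUE))) {
        stopf("half-call genotype in record %s:%s (%s)",
              fix[r, "CHROM"], fix[r, "POS"], gg[grepl(".", gg, fixed = TRUE)][1L])
      }
      ok <- grepl("^[0-9]+/[0-9]+$", gg)
      if (!all(ok)) {
        stopf("non-diploid or malformed GT '%s' in record %s:%s",
              gg[!ok][1L], fix[r, "CHROM"], fix[r, "POS"])
      }
      codes <- allele_list[[r]]
      i1 <- as.integer(sub("/.*$", "", gg)) + 1L
      i2 <- as.integer(sub("^.*/", "", gg)) + 1L
      if (max(i1, i2) > length(codes)) {
        stopf("GT allele index out of range in record %s:%s",
              fix[r, "CHROM"], fix[r, "POS"])
      }
      a1[j, !miss] <- codes[i1]
      a2[j, !miss] <- codes[i2]
    }
  }
  sw <- a1 > a2
  sw[is.na(sw)] <- FALSE
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp

  id <- fix[keep, "ID"]
  dialect <- !is.na(id) & grepl("^.+_[0-9]+$", id)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  if (all(dialect)) {
    locus_id <- sub("_[0-9]+$", "", id)
    offset <- as.integer(sub("^.*_", "", id))
    site_key <- id
  } else {
    warnf(paste0("VCF IDs do not follow the 'locus_offset' dialect; ",
                 "treating each record as its own single-site locus"))
    site_key <- ifelse(!is.na(id) & id != ".", id, paste(chrom, pos, sep = "_"))
    site_key <- make.unique(site_key, sep = ".")
    locus_id <- site_key
    offset <- rep.int(NA_integer_, length(site_key))
  }
  site_index <- stats::ave(seq_along(locus_id), locus_id,
                           FUN = function(i) order(order(offset[i])) - 1L)
  sites <- data.frame(site_key = site_key, locus_id = locus_id,
                      site_index = as.integer(site_index),
                      offset_bp = offset, chrom = chrom, pos = pos,
                      ref = ref[keep],
                      alt = vapply(allele_list[keep], function(a) {
                        if (length(a) > 1L) paste(a[-1L], collapse = ",") else NA_character_
                      }, character(1L)),
                      stringsAsFactors = FALSE)

  sm <- species_map(vcf_samples,
                    species_map$species[match(vcf_samples, species_map$sample_id)],
                    subspecies = species_map$subspecies[match(vcf_samples, species_map$sample_id)],
                    population = species_map$population[match(vcf_samples, species_map$sample_id)],
                    platform = species_map$platform[match(vcf_samples, species_map$sample_id)],
                    taxon_level = taxon_level(species_map))
  rownames(a1) <- rownames(a2) <- sites$site_key
  loci <- data.frame(locus_id = unique(sites$locus_id),
                     tag_length = as.integer(tag_length),
                     stringsAsFactors = FALSE)
  new_geno_matrix(a1, a2, sites, sm, loci)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one record per site with GT-only FORMAT. Coordinates are 1-based
#' (VCF convention); when a site lacks a reference coordinate its 0-based tag
#' offset + 1 (or site index + 1) is used as POS and the locus id as CHROM.
#' The ID column uses the `locus_offset` dialect so that [read_vcf()]
#' round-trips locus grouping.
#'
#' @param x A [geno_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  s <- x$sites
  ac <- allele_counts(x)
  ref <- s$ref
  alt <- s$alt
  for (j in which(is.na(ref))) {
    obs <- BASES[ac[j, ] > 0L]
    ref[j] <- if (length(obs)) obs[1L] else "A"
    alt[j] <- if (length(obs) > 1L) paste(obs[-1L], collapse = ",") else NA_character_
  }
  # alleles observed in calls but absent from REF/ALT are appended to ALT
  for (j in seq_len(nrow(s))) {
    known <- c(ref[j], if (!is.na(alt[j])) strsplit(alt[j], ",")[[1L]])
    obs <- BASES[ac[j, ] > 0L]
    miss <- setdiff(obs, known)
    if (length(miss)) {
      alt[j] <- paste(c(known[-1L], miss), collapse = ",")
    }
  }
  chrom <- ifelse(is.na(s$chrom), s$locus_id, s$chrom)
  pos <- ifelse(!is.na(s$pos), s$pos,
                ifelse(!is.na(s$offset_bp), s$offset_bp + 1L, s$site_index + 1L))
  id <- ifelse(!is.na(s$offset_bp),
               paste(s$locus_id, s$offset_bp, sep = "_"), s$site_key)
  gt_codes <- matrix(".", n_sites(x), n_samples(x))
  for (j in seq_len(nrow(s))) {
    codes <- c(ref[j], if (!is.na(alt[j])) strsplit(alt[j], ",")[[1L]])
    i1 <- match(x$a1[j, ], codes) - 1L
    i2 <- match(x$a2[j, ], codes) - 1L
    gt_codes[j, ] <- ifelse(is.na(i1), "./.", paste0(i1, "/", i2))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=diagsnp",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(x)), collapse = "\t"))
  body <- paste(chrom, pos, id, ref, ifelse(is.na(alt), ".", alt),
                ".", "PASS", ".", "GT",
                apply(gt_codes, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
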