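# literal brute-force re-implementations of the definitions, used as
# independent oracles; every computation is a per-cell loop over
# genotype_calls() output, deliberately sharing no code with the package

oracle_site_summary <- function(gm) {
  gt <- genotype_calls(gm, sep = "")
  t(vapply(seq_len(nrow(gt)), function(i) {
    cells <- gt[i, ]
    called <- sum(!is.na(cells))
    alleles <- unique(unlist(strsplit(cells[!is.na(cells)], "")))
    c(presence = called / length(cells), n_alleles = length(alleles))
  }, c(presence = 0, n_alleles = 0)))
}

# shared-locus filter: literal application of the three definitions
oracle_shared_keys <- function(gm, thr = 0.75, cap = 2L, biallelic = TRUE) {
  ss <- oracle_site_summary(gm)
  info <- site_info(gm)
  keep <- character()
  for (l in unique(info$locus_id)) {
    rows <- which(info$locus_id == l)
    poly <- rows[ss[rows, "n_alleles"] >= 2]
    if (length(poly) == 0) next                      # not polymorphic
    if (any(ss[poly, "presence"] < thr)) next        # not shared
    if (biallelic && any(ss[rows, "n_alleles"] > 2)) next
    if (length(poly) > cap) next                     # over the SNP cap
    keep <- c(keep, info$site_key[poly])
  }
  keep
}

# per-taxon status at one site: fixed(allele) / polymorphic / insufficient
oracle_status <- function(gm, key, taxon, thr = 0.75) {
  gt <- genotype_calls(gm, sep = "")
  i <- which(site_info(gm)$site_key == key)
  cells <- gt[i, taxa_of(gm$samples) == taxon]
  called <- cells[!is.na(cells)]
  if (length(called) / length(cells) < thr) {
    return(list(status = "insufficient", allele = NA))
  }
  alleles <- unique(unlist(strsplit(called, "")))
  any_het <- any(substr(called, 1, 1) != substr(called, 2, 2))
  if (any_het || length(alleles) > 1) {
    return(list(status = "polymorphic", allele = NA))
  }
  list(status = "fixed", allele = alleles)
}

# one-vs-rest diagnostic classification at every site of a (pre-filtered)
# matrix; returns data.frame(site_key, focal)
oracle_diagnostics <- function(gm, taxa, thr = 0.75) {
  out <- NULL
  for (key in site_info(gm)$site_key) {
    st <- lapply(taxa, function(t) oracle_status(gm, key, t, thr))
    if (!all(vapply(st, function(s) s$status == "fixed", TRUE))) next
    alleles <- vapply(st, function(s) s$allele, "")
    if (length(unique(alleles)) != 2) next
    if (length(taxa) == 2) {
      out <- rbind(out, data.frame(site_key = key, focal = taxa[1]))
    } else {
      counts <- table(alleles)
      if (!any(counts == 1)) next
      rare <- names(counts)[counts == 1]
      if (length(rare) != 1) next
      out <- rbind(out, data.frame(site_key = key,
                                   focal = taxa[alleles == rare]))
    }
  }
  out
}

# full brute-force discovery incl. shared filter and the species-specific
# SNPs-per-locus cap (loci over the cap dropped whole)
oracle_catalog <- function(gm, taxa, thr = 0.75, cap = 2L) {
  gm <- subset_taxa(gm, taxa)
  keys <- oracle_shared_keys(gm, thr = thr, cap = Inf)
  if (length(keys) == 0) return(NULL)
  d <- oracle_diagnostics(subset_sites(gm, keys), taxa, thr)
  if (is.null(d)) return(NULL)
  info <- site_info(gm)
  d$locus <- info$locus_id[match(d$site_key, info$site_key)]
  per_locus <- table(d$locus)
  d[per_locus[d$locus] <= cap, c("site_key", "focal")]
}

# allele-count frequency of one allele in one taxon, per-cell loop
oracle_freq <- function(gm, key, taxon, allele) {
  gt <- genotype_calls(gm, sep = "")
  i <- which(site_info(gm)$site_key == key)
  cells <- gt[i, taxa_of(gm$samples) == taxon]
  called <- cells[!is.na(cells)]
  if (length(called) == 0) return(NA_real_)
  100 * sum(unlist(strsplit(called, "")) == allele) / (2 * length(called))
}

# concordance counts by looping over shared cells
oracle_concordance <- function(ga, gb) {
  sites <- intersect(site_info(ga)$site_key, site_info(gb)$site_key)
  samples <- intersect(sample_ids(ga), sample_ids(gb))
  gta <- genotype_calls(ga, sep = "")
  gtb <- genotype_calls(gb, sep = "")
  res <- c(comparable = 0, match = 0, het_vs_hom = 0)
  for (s in sites) {
    ia <- which(site_info(ga)$site_key == s)
    ib <- which(site_info(gb)$site_key == s)
    for (id in samples) {
      ca <- gta[ia, id]; cb <- gtb[ib, id]
      if (is.na(ca) || is.na(cb)) next
      res["comparable"] <- res["comparable"] + 1
      if (ca == cb) res["match"] <- res["match"] + 1 else {
        ha <- substr(ca, 1, 1) != substr(ca, 2, 2)
        hb <- substr(cb, 1, 1) != substr(cb, 2, 2)
        if (xor(ha, hb)) res["het_vs_hom"] <- res["het_vs_hom"] + 1
      }
    }
  }
  res
}
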