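#' Configuration for the synthetic genotype generator
#'
#' Describes a multi-species diploid genotype study with the statistical
#' structure the diagnostic-marker analysis assumes: a minority of RAD loci
#' carry planted one-vs-rest fixed differences, the rest segregate shared
#' background polymorphism drawn from a common allele-frequency prior
#' (Hardy–Weinberg within every taxon, no species tree), and calls are
#' degraded by RAD-style heterozygote dropout and per-call missingness. The
#' defaults mirror a ten-species ddRAD study design: 132 samples with
#' uneven group sizes (the largest species split into two subspecies),
#' 148 bp tags, 1–5 SNPs per locus, moderate missingness and heterozygote
#' under-calling.
#'
#' @param taxa Named integer vector: samples per taxon.
#' @param n_loci Number of RAD loci to simulate.
#' @param snps_per_locus_weights Sampling weights for 1–5 SNPs per locus.
#' @param planted_diagnostic_fraction Fraction of loci planted as diagnostic
#'   for each taxon; scalar (recycled) or named per taxon. Fractions must
#'   sum to <= 1.
#' @param background_maf_prior `c(shape1, shape2)` of the Beta prior the
#'   shared background alternate-allele frequency is drawn from.
#' @param missing_rate Per-call missingness probability.
#' @param het_dropout_rate Probability that a true heterozygote is recorded
#'   as a homozygote for one of its alleles (allelic dropout).
#' @param platform_error_rate Per-cell rate at which [platform_replicate()]
#'   perturbs the replicate platform.
#' @param tag_length RAD-tag length in bp; SNP offsets are uniform on
#'   `[0, tag_length)`.
#' @param n_chrom Number of linkage groups loci are spread over.
#' @param seed Mandatory RNG seed; every stage derives its own substream
#'   from it, so adding a later noise stage never perturbs earlier draws.
#' @param subspecies Optional named list: per taxon, a named integer vector
#'   of subspecies sizes summing to the taxon size. By default the `Oni`
#'   group of the default design is split 30/33 into two subspecies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(taxa = c(Oni = 63, Omo = 15, Oau = 15, Oho = 5,
                                Oka = 5, Tzi = 10, Sga = 5, Oan = 6,
                                Oma = 4, Sme = 4),
                       n_loci = 500L,
                       snps_per_locus_weights = c(0.55, 0.25, 0.10, 0.06, 0.04),
                       planted_diagnostic_fraction = 0.005,
                       background_maf_prior = c(0.8, 0.8),
                       missing_rate = 0.05,
                       het_dropout_rate = 0.10,
                       platform_error_rate = 0.01,
                       tag_length = 148L,
                       n_chrom = 22L,
                       seed,
                       subspecies = NULL) {
  if (missing(seed) || !is_count(seed, min = 0L)) {
    stopf("sim_config: an integer seed is mandatory")
  }
  if (is.null(names(taxa)) || any(!nzchar(names(taxa)))) {
    stopf("taxa must be a named vector of group sizes")
  }
  if (any(taxa < 1L)) stopf("every taxon needs >= 1 sample")
  if (!is_count(n_loci)) stopf("n_loci must be a positive integer")
  if (length(snps_per_locus_weights) != 5L || any(snps_per_locus_weights < 0)) {
    stopf("snps_per_locus_weights must be 5 non-negative weights")
  }
  frac <- planted_diagnostic_fraction
  if (is.null(names(frac))) {
    frac <- stats::setNames(rep_len(frac, length(taxa)), names(taxa))
  } else if (!all(names(frac) %in% names(taxa))) {
    stopf("planted_diagnostic_fraction names must be taxa")
  } else {
    full <- stats::setNames(numeric(length(taxa)), names(taxa))
    full[names(frac)] <- frac
    frac <- full
  }
  if (any(frac < 0) || sum(frac) > 1) {
    stopf("planted fractions must be >= 0 and sum to <= 1")
  }
  for (p in c(missing_rate, het_dropout_rate, platform_error_rate)) {
    if (!is_prob(p)) stopf("rates must be probabilities in [0, 1]")
  }
  if (!is_count(tag_length)) stopf("tag_length must be a positive integer")
  if (is.null(subspecies) &&
      identical(names(taxa)[1L], "Oni") && taxa[[1L]] == 63L) {
    subspecies <- list(Oni = c(niloticus = 30L, cancellatus = 33L))
  }
  if (!is.null(subspecies)) {
    for (t in names(subspecies)) {
      if (!t %in% names(taxa) || sum(subspecies[[t]]) != taxa[[t]]) {
        stopf("subspecies sizes for '%s' must sum to its taxon size", t)
      }
    }
  }
  structure(list(taxa = taxa, n_loci = as.integer(n_loci),
                 snps_per_locus_weights = snps_per_locus_weights,
                 planted_diagnostic_fraction = frac,
                 background_maf_prior = background_maf_prior,
                 missing_rate = missing_rate,
                 het_dropout_rate = het_dropout_rate,
                 platform_error_rate = platform_error_rate,
                 tag_length = as.integer(tag_length),
                 n_chrom = as.integer(n_chrom),
                 seed = as.integer(seed),
                 subspecies = subspecies),
            class = "sim_config")
}

# one derived seed per simulation stage, all below 2^31
stage_seeds <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  sample.int(2147483646L, 8L)
}

sim_species_map <- function(cfg) {
  taxa <- cfg$taxa
  ids <- unlist(lapply(names(taxa), function(t) {
    sprintf("%s_%02d", t, seq_len(taxa[[t]]))
  }), use.names = FALSE)
  species <- rep(names(taxa), taxa)
  subsp <- rep(NA_character_, length(ids))
  for (t in names(cfg$subspecies %||% list())) {
    sizes <- cfg$subspecies[[t]]
    subsp[species == t] <- rep(names(sizes), sizes)
  }
  species_map(ids, species, subspecies = subsp)
}

#' Simulate a genotype matrix with planted diagnostic markers
#'
#' Planted sites are homozygous for the diagnostic allele in the focal taxon
#' and homozygous for the alternate allele in every other taxon (before
#' noise); every site of a planted locus is diagnostic for the same taxon,
#' so SNPs-per-locus bookkeeping can be exercised. Background sites draw a
#' shared alternate-allele frequency from the Beta prior and sample
#' genotypes under Hardy–Weinberg identically in all taxa. Noise is applied
#' in order heterozygote-dropout then missingness, each from its own seeded
#' substream. The same configuration always yields a bit-identical result.
#'
#' @param cfg A [sim_config].
#' @return A `sim_result` list: `matrix` (a [geno_matrix], with the true
#'   genotypes of dropped heterozygotes recorded in attribute
#'   `het_dropout`), `truth` (the truth table: one row per planted site with
#'   `site_key`, `locus_id`, `offset_bp`, `focal_taxon`,
#'   `diagnostic_allele`, `alternate_allele`, `snps_on_locus`) and `config`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- stage_seeds(cfg)
  sm <- sim_species_map(cfg)
  N <- nrow(sm)
  grp <- sm$species
  taxa <- names(cfg$taxa)

  ## stage 1: locus structure
  set.seed(seeds[1L])
  nL <- cfg$n_loci
  k_per_locus <- sample.int(5L, nL, replace = TRUE,
                            prob = cfg$snps_per_locus_weights)
  n_planted <- round(cfg$planted_diagnostic_fraction * nL)
  if (sum(n_planted) > nL) stopf("more planted loci requested than n_loci")
  perm <- sample.int(nL)
  focal_of_locus <- rep(NA_character_, nL)
  used <- 0L
  for (t in taxa) {
    if (n_planted[[t]] > 0L) {
      focal_of_locus[perm[(used + 1L):(used + n_planted[[t]])]] <- t
      used <- used + n_planted[[t]]
    }
  }
  locus_id <- sprintf("L%04d", seq_len(nL))
  chrom <- sprintf("LG%02d", sample.int(cfg$n_chrom, nL, replace = TRUE))
  offsets <- lapply(k_per_locus, function(k) {
    sort(sample.int(cfg$tag_length, k) - 1L)
  })
  sites <- data.frame(
    locus_id = rep(locus_id, k_per_locus),
    site_index = unlist(lapply(k_per_locus, seq_len), use.names = FALSE) - 1L,
    offset_bp = unlist(offsets, use.names = FALSE),
    chrom = rep(chrom, k_per_locus),
    stringsAsFactors = FALSE)
  sites$site_key <- paste(sites$locus_id, sites$offset_bp, sep = "_")
  sites$pos <- 1000L * as.integer(sub("^L", "", sites$locus_id)) +
    sites$offset_bp
  sites$focal <- rep(focal_of_locus, k_per_locus)
  nS <- nrow(sites)
  pair <- vapply(seq_len(nS), function(i) sample(BASES, 2L), character(2L))
  allele1 <- pair[1L, ]  # diagnostic (planted) or reference (background)
  allele2 <- pair[2L, ]  # alternate

  ## stage 2: genotypes
  set.seed(seeds[2L])
  a1 <- matrix(NA_character_, nS, N,
               dimnames = list(sites$site_key, sm$sample_id))
  a2 <- a1
  planted <- !is.na(sites$focal)
  prior <- cfg$background_maf_prior
  p_alt <- numeric(nS)
  p_alt[!planted] <- stats::rbeta(sum(!planted), prior[1L], prior[2L])
  for (i in seq_len(nS)) {
    if (planted[i]) {
      focal_cols <- grp == sites$focal[i]
      a1[i, focal_cols] <- a2[i, focal_cols] <- allele1[i]
      a1[i, !focal_cols] <- a2[i, !focal_cols] <- allele2[i]
    } else {
      x1 <- ifelse(stats::runif(N) < p_alt[i], allele2[i], allele1[i])
      x2 <- ifelse(stats::runif(N) < p_alt[i], allele2[i], allele1[i])
      a1[i, ] <- pmin(x1, x2)
      a2[i, ] <- pmax(x1, x2)
    }
  }

  ## stage 3: heterozygote dropout (het -> hom for one allele)
  set.seed(seeds[3L])
  het_cells <- which(a1 != a2)
  dropped <- het_cells[stats::runif(length(het_cells)) < cfg$het_dropout_rate]
  het_dropout <- data.frame(site = (dropped - 1L) %% nS + 1L,
                            sample = (dropped - 1L) %/% nS + 1L,
                            true_a1 = a1[dropped], true_a2 = a2[dropped],
                            stringsAsFactors = FALSE)
  if (length(dropped)) {
    keep_first <- stats::runif(length(dropped)) < 0.5
    kept <- ifelse(keep_first, a1[dropped], a2[dropped])
    a1[dropped] <- kept
    a2[dropped] <- kept
  }

  ## stage 4: missingness
  set.seed(seeds[4L])
  gone <- stats::runif(nS * N) < cfg$missing_rate
  a1[gone] <- NA_character_
  a2[gone] <- NA_character_

  site_df <- data.frame(site_key = sites$site_key, locus_id = sites$locus_id,
                        site_index = sites$site_index,
                        offset_bp = sites$offset_bp,
                        chrom = sites$chrom, pos = sites$pos,
                        ref = allele1, alt = allele2,
                        stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = locus_id, tag_length = cfg$tag_length,
                     stringsAsFactors = FALSE)
  gm <- new_geno_matrix(a1, a2, site_df, sm, loci)
  het_dropout$site_key <- sites$site_key[het_dropout$site]
  het_dropout$sample_id <- sm$sample_id[het_dropout$sample]
  attr(gm, "het_dropout") <- het_dropout

  truth <- data.frame(site_key = sites$site_key[planted],
                      locus_id = sites$locus_id[planted],
                      offset_bp = sites$offset_bp[planted],
                      focal_taxon = sites$focal[planted],
                      diagnostic_allele = allele1[planted],
                      alternate_allele = allele2[planted],
                      snps_on_locus = rep(k_per_locus,
                                          k_per_locus)[planted],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(matrix = gm, truth = truth, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d sites on %d loci x %d samples; %d planted diagnostic site(s)\n",
              n_sites(x$matrix), n_loci(x$matrix), n_samples(x$matrix),
              nrow(x$truth)))
  invisible(x)
}

#' Emulate a second genotyping platform
#'
#' Produces a replicate of a simulated matrix as a second platform (e.g.
#' single-SNP PCR assays re-typing ddRAD calls) for concordance analysis.
#' In stochastic mode, each heterozygote that the first platform dropped to
#' a homozygote is restored to the true heterozygote with probability
#' `platform_error_rate` (assay platforms typically resolve heterozygotes
#' better), and every other cell is independently set missing with the same
#' probability. In exact mode (`n_het_discordances` / `n_missing` given),
#' precisely that many het-vs-hom discordances and missing cells are planted
#' in the replicate, on disjoint cells, for arithmetic fixtures.
#'
#' @param x A [geno_matrix] from [simulate_genotypes()].
#' @param cfg The [sim_config] (for rates and seed substreams).
#' @param n_het_discordances,n_missing Exact-mode counts (both optional).
#' @return A [geno_matrix] with attribute `planted` =
#'   `list(n_het_vs_hom, n_missing)`.
#' @export
platform_replicate <- function(x, cfg, n_het_discordances = NULL,
                               n_missing = NULL) {
  stopifnot(inherits(x, "geno_matrix"), inherits(cfg, "sim_config"))
  seeds <- stage_seeds(cfg)
  a1 <- x$a1; a2 <- x$a2
  exact <- !is.null(n_het_discordances) || !is.null(n_missing)
  if (exact) {
    set.seed(seeds[6L])
    n_het <- n_het_discordances %||% 0L
    n_miss <- n_missing %||% 0L
    hom_cells <- which(!is.na(a1) & a1 == a2)
    if (n_het > length(hom_cells)) {
      stopf("cannot plant %d het-vs-hom discordances: only %d homozygous cells",
            n_het, length(hom_cells))
    }
    disc <- if (n_het > 0L) sample(hom_cells, n_het) else integer()
    for (cell in disc) {
      i <- (cell - 1L) %% nrow(a1) + 1L
      cur <- a1[cell]
      alt <- c(x$sites$ref[i],
               if (!is.na(x$sites$alt[i])) strsplit(x$sites$alt[i], ",")[[1L]])
      other <- setdiff(alt, cur)
      if (length(other) == 0L) other <- setdiff(BASES, cur)
      other <- other[1L]
      a1[cell] <- min(cur, other)
      a2[cell] <- max(cur, other)
    }
    pool <- setdiff(which(!is.na(x$a1)), disc)
    if (n_miss > length(pool)) stopf("cannot plant %d missing cells", n_miss)
    gone <- if (n_miss > 0L) sample(pool, n_miss) else integer()
    a1[gone] <- NA_character_
    a2[gone] <- NA_character_
    planted <- list(n_het_vs_hom = length(disc), n_missing = length(gone))
  } else {
    set.seed(seeds[5L])
    hd <- attr(x, "het_dropout")
    restored <- integer()
    if (!is.null(hd) && nrow(hd)) {
      cells <- (hd$sample - 1L) * nrow(a1) + hd$site
      hit <- stats::runif(nrow(hd)) < cfg$platform_error_rate
      restored <- cells[hit]
      a1[restored] <- pmin(hd$true_a1[hit], hd$true_a2[hit])
      a2[restored] <- pmax(hd$true_a1[hit], hd$true_a2[hit])
    }
    other <- setdiff(seq_along(a1), restored)
    gone <- other[stats::runif(length(other)) < cfg$platform_error_rate]
    a1[gone] <- NA_character_
    a2[gone] <- NA_character_
    planted <- list(n_het_vs_hom = length(restored), n_missing = length(gone))
  }
  out <- new_geno_matrix(a1, a2, x$sites, x$samples, x$loci)
  attr(out, "planted") <- planted
  out
}

#' Write a simulation to disk
#'
#' Emits the study bundle a real pipeline would consume: a VCF of the
#' genotypes, a popmap, a KASP-shaped genotype TSV and the truth table.
#'
#' @param sim A `sim_result` from [simulate_genotypes()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             table = file.path(dir, "genotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$matrix, paths[["vcf"]])
  write_popmap(sim$matrix$samples, paths[["popmap"]])
  write_genotype_table(sim$matrix, paths[["table"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
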