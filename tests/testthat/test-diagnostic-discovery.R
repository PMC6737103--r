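test_that("site partition classifies fixed / polymorphic / insufficient", {
  sm <- make_sm(A = 2, B = 2)
  gm <- toy_matrix(list(fixed = c("AA", "AA", "GG", "GG"),
                        het   = c("AA", "AG", "GG", "GG"),
                        thin  = c("AA", NA, "GG", "GG")), sm)
  p <- partition_site(gm, "fixed")
  expect_equal(p$status, c("fixed", "fixed"))
  expect_equal(p$allele, c("A", "G"))
  expect_equal(partition_site(gm, "het")$status[1], "polymorphic")
  p3 <- partition_site(gm, "thin")
  expect_equal(p3$status[1], "insufficient")  # presence 0.5 in taxon A
  expect_equal(p3$presence, c(0.5, 1))
  expect_error(partition_site(gm, "fixed", taxa = c("A", "Z")), "zero samples")
})

test_that("partition statuses equal the brute-force classifier", {
  for (seed in 1:10) {
    set.seed(seed)
    gm <- rand_matrix(n_loci = 6, miss = 0.25)
    taxa <- unique(taxa_of(gm$samples))
    for (key in sample(site_info(gm)$site_key, 4)) {
      p <- partition_site(gm, key)
      for (i in seq_along(taxa)) {
        o <- oracle_status(gm, key, taxa[i])
        expect_equal(p$status[p$taxon == taxa[i]], o$status,
                     info = paste(seed, key, taxa[i]))
      }
    }
  }
})

test_that("one-vs-rest discovery on a hand-enumerated toy matrix", {
  sm <- make_sm(A = 2, B = 2, C = 2)
  gm <- toy_matrix(list(
    L1_5  = c("AA", "AA", "GG", "GG", "GG", "GG"),  # diagnostic for A
    L2_5  = c("AA", "AG", "GG", "GG", "GG", "GG"),  # het in A: disqualified
    L3_5  = c("TT", "TT", "TT", "TT", "CC", "CC"),  # diagnostic for C
    L4_5  = c("AA", "AA", "GG", "GG", "AA", "AA")), # A,C share: diagnostic for B
    sm,
    sites = data.frame(site_key = c("L1_5", "L2_5", "L3_5", "L4_5"),
                       locus_id = c("L1", "L2", "L3", "L4"),
                       site_index = 0L, offset_bp = 5L))
  cat <- find_diagnostic_markers(gm, filter_config())
  expect_equal(cat$site_key, c("L1_5", "L3_5", "L4_5"))
  expect_equal(cat$focal_taxon, c("A", "C", "B"))
  expect_equal(cat$diagnostic_allele, c("A", "C", "G"))
  expect_equal(cat$alternate_allele, c("G", "T", "A"))
  expect_equal(attr(cat, "per_taxon_counts"), c(A = 1L, B = 1L, C = 1L))
  expect_error(find_diagnostic_markers(gm, taxa = "A"), ">= 2 taxa")
})

test_that("pairwise discovery is discovery restricted to the pair", {
  cfg <- zero_noise_cfg(seed = 902, taxa = c(A = 4, B = 4, C = 4, D = 4),
                        n_loci = 80, planted_diagnostic_fraction = 0.1)
  sim <- simulate_genotypes(cfg)
  fc <- filter_config(max_snps_per_locus = 5)
  full <- find_diagnostic_markers(sim$matrix, fc)
  pw <- find_pairwise_diagnostics(sim$matrix, "A", "B", fc)
  expect_error(find_pairwise_diagnostics(sim$matrix, "A", "A"), "differ")
  # subset monotonicity: every A-diagnostic over {A,B,C,D} persists in {A,B}
  a_full <- full$site_key[full$focal_taxon == "A"]
  expect_true(all(a_full %in% pw$site_key))
  # pairwise finds at least the one-vs-rest markers of both taxa
  expect_gte(nrow(pw), length(a_full))
  expect_equal(attr(pw, "n_loci"), length(unique(pw$locus_id)))
})

test_that("discovery agrees with the literal brute-force classifier", {
  for (seed in 1:25) {
    set.seed(seed)
    gm <- rand_matrix(n_loci = sample(5:15, 1), miss = stats::runif(1, 0, 0.3))
    taxa <- unique(taxa_of(gm$samples))
    want <- oracle_catalog(gm, taxa)
    got <- tryCatch(
      find_diagnostic_markers(gm, filter_config()),
      error = function(e) NULL)
    got_keys <- if (is.null(got)) character() else
      paste(got$site_key, got$focal_taxon)
    want_keys <- if (is.null(want)) character() else
      paste(want$site_key, want$focal)
    expect_identical(sort(got_keys), sort(want_keys),
                     info = paste("seed", seed))
  }
})

test_that("catalog content is invariant under sample and taxon order", {
  cfg <- zero_noise_cfg(seed = 903, taxa = c(A = 3, B = 3, C = 3),
                        n_loci = 50, planted_diagnostic_fraction = 0.1)
  sim <- simulate_genotypes(cfg)
  fc <- filter_config(max_snps_per_locus = 5)
  base <- find_diagnostic_markers(sim$matrix, fc)
  set.seed(1)
  shuf <- subset_samples(sim$matrix, sample(sample_ids(sim$matrix)))
  perm <- find_diagnostic_markers(shuf, fc, taxa = c("C", "A", "B"))
  cols <- c("site_key", "focal_taxon", "diagnostic_allele",
            "alternate_allele", "snps_on_locus")
  expect_identical(base[, cols], perm[, cols])
})

test_that("assay-candidate filter enforces tag-edge distance and SNP cap", {
  sm <- make_sm(A = 2, B = 2)
  mk_site <- function(key, locus, off) {
    data.frame(site_key = key, locus_id = locus, site_index = 0L,
               offset_bp = off)
  }
  gm <- toy_matrix(list(e19 = c("AA", "AA", "GG", "GG"),
                        e20 = c("CC", "CC", "TT", "TT"),
                        e130 = c("AA", "AA", "TT", "TT"),
                        e127 = c("GG", "GG", "CC", "CC"),
                        nooff = c("AA", "AA", "CC", "CC")),
                   sm,
                   sites = rbind(mk_site("e19", "La", 19L),
                                 mk_site("e20", "Lb", 20L),
                                 mk_site("e130", "Lc", 130L),
                                 mk_site("e127", "Ld", 127L),
                                 data.frame(site_key = "nooff",
                                            locus_id = "Le", site_index = 0L,
                                            offset_bp = NA_integer_)))
  cat <- find_diagnostic_markers(gm, filter_config())
  expect_message(
    cand <- filter_assay_candidates(cat, locus_info(gm), filter_config()),
    "excluded 1 marker")
  # 148 bp tag: offset must be in [20, 127]; 19 and 130 fail, 20 and 127 pass
  expect_setequal(cand$site_key, c("e20", "e127"))
  expect_equal(attr(cand, "n_unknown_offset"), 1L)
})

test_that("assay-candidate filter equals direct predicate application", {
  cfg <- zero_noise_cfg(seed = 904, taxa = c(A = 4, B = 4),
                        n_loci = 120, planted_diagnostic_fraction = 0.3)
  sim <- simulate_genotypes(cfg)
  cat <- find_diagnostic_markers(sim$matrix, filter_config(max_snps_per_locus = 5))
  cand <- filter_assay_candidates(cat, locus_info(sim$matrix), filter_config())
  keep <- cat$offset_bp >= 20 & (148 - 1 - cat$offset_bp) >= 20 &
    cat$snps_on_locus <= 2
  expect_setequal(cand$site_key, cat$site_key[keep])
})

test_that("panel selection balances taxa, spreads LGs, deterministically", {
  cfg <- zero_noise_cfg(seed = 905, taxa = c(A = 3, B = 3, C = 3, D = 3),
                        n_loci = 120, planted_diagnostic_fraction = 0.15)
  sim <- simulate_genotypes(cfg)
  cat <- find_diagnostic_markers(sim$matrix, filter_config(max_snps_per_locus = 5))
  pan <- select_panel(cat, 8)
  expect_equal(nrow(pan$markers), 8L)
  expect_true(max(pan$per_taxon) - min(pan$per_taxon) <= 1)
  expect_false(anyDuplicated(pan$markers$site_key) > 0)
  pan2 <- select_panel(cat, 8)
  expect_identical(pan$markers$site_key, pan2$markers$site_key)
  expect_error(select_panel(cat, nrow(cat) + 1), "between 1 and")

  # catalog of 4 markers, one per taxon: size-4 panel takes all
  four <- cat[!duplicated(cat$focal_taxon), , drop = FALSE]
  attr(four, "taxa") <- attr(cat, "taxa"); class(four) <- class(cat)
  p4 <- select_panel(four, 4)
  expect_setequal(p4$markers$site_key, four$site_key)

  # 10 markers on one LG plus 2 on another: a size-3 panel uses both LGs
  sm <- make_sm(A = 2, B = 2)
  calls <- stats::setNames(
    rep(list(c("AA", "AA", "GG", "GG")), 12),
    sprintf("M%02d_5", 1:12))
  sites <- data.frame(site_key = names(calls),
                      locus_id = sprintf("M%02d", 1:12),
                      site_index = 0L, offset_bp = 5L,
                      chrom = c(rep("LG1", 10), rep("LG2", 2)),
                      pos = 1:12)
  gm <- toy_matrix(calls, sm, sites = sites)
  cat2 <- find_diagnostic_markers(gm, filter_config(max_snps_per_locus = 12))
  p3 <- select_panel(cat2, 3)
  expect_setequal(names(p3$per_lg), c("LG1", "LG2"))
})
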