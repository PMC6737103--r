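test_that("composite genotypes use IUPAC codes with N for missing", {
  sm <- make_sm(A = 1, B = 1)
  gm <- toy_matrix(list(s1 = c("AA", "GG"), s2 = c("AG", "CC"),
                        s3 = c(NA, "TT")), sm)
  seqs <- composite_genotypes(gm)
  expect_equal(unname(seqs["A1"]), "ARN")
  expect_equal(unname(seqs["B1"]), "GCT")
})

test_that("alignment export round-trips genotypes up to het phase", {
  cfg <- sim_config(taxa = c(A = 4, B = 4), n_loci = 30, seed = 501,
                    missing_rate = 0.1)
  sim <- simulate_genotypes(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  export_composite_alignment(sim$matrix, fa, "fasta")
  back <- toupper(vapply(as.character(ape::read.FASTA(fa)),
                         paste, "", collapse = ""))
  seqs <- composite_genotypes(sim$matrix)
  expect_equal(unname(back), as.vector(seqs))
  # decode each column back to an unordered pair and compare with the calls
  pair_of <- c(A = "AA", C = "CC", G = "GG", T = "TT", M = "AC", R = "AG",
               W = "AT", S = "CG", Y = "CT", K = "GT")
  keys <- attr(seqs, "site_keys")
  gt <- genotype_calls(sim$matrix, sep = "")
  decoded <- vapply(strsplit(back, ""), function(ch) {
    unname(pair_of[ch])
  }, character(length(keys)))
  want <- gt[keys, names(seqs)]
  want[is.na(want)] <- NA_character_
  expect_equal(unname(decoded), unname(want))
})

test_that("phylip export writes the dimension header", {
  cfg <- sim_config(taxa = c(A = 3, B = 3), n_loci = 10, seed = 502)
  sim <- simulate_genotypes(cfg)
  ph <- withr::local_tempfile(fileext = ".phy")
  export_composite_alignment(sim$matrix, ph, "phylip")
  header <- readLines(ph, n = 1)
  expect_equal(header, sprintf("%d %d", 6, n_sites(sim$matrix)))
  sm1 <- make_sm(A = 1)
  expect_error(export_composite_alignment(
    toy_matrix(list(s = "AA"), sm1), ph), ">= 2 samples")
})

test_that("allele-sharing distance matches hand enumeration", {
  sm <- make_sm(A = 1, B = 1, C = 1)
  # samples: A1 = (AA, AA, GG), B1 = (AA, AG, CC), C1 = (AA, AA, GG)
  gm <- toy_matrix(list(m1 = c("AA", "AA", "AA"),
                        m2 = c("AA", "AG", "AA"),
                        m3 = c("GG", "CC", "GG")), sm)
  d <- allele_sharing_distance(gm)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["A1", "C1"], 0)                      # identical
  # A1 vs B1: site1 2 shared, site2 1 shared (AA vs AG), site3 0 -> 1 - 3/6
  expect_equal(d["A1", "B1"], 0.5)
  expect_true(isSymmetric(d))
  # single-site checks: identical -> 0; opposite homs -> 1; AA vs AG -> 0.5
  g2 <- toy_matrix(list(s = c("AA", "GG", "AG")),
                   make_sm(A = 1, B = 1, C = 1))
  d2 <- allele_sharing_distance(g2)
  expect_equal(d2["A1", "B1"], 1)
  expect_equal(d2["A1", "C1"], 0.5)
  # zero overlap is an error naming the pair
  g3 <- toy_matrix(list(m1 = c("AA", NA), m2 = c(NA, "GG")), make_sm(A = 2))
  expect_error(allele_sharing_distance(g3), "A1.*A2|share no")
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  # distances generated from ((a:1,b:2):1,(c:3,d:4)) with internal edge 1
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 3
  dm["a", "c"] <- dm["c", "a"] <- 5
  dm["a", "d"] <- dm["d", "a"] <- 6
  dm["b", "c"] <- dm["c", "b"] <- 6
  dm["b", "d"] <- dm["d", "b"] <- 7
  dm["c", "d"] <- dm["d", "c"] <- 7
  nw <- nj_tree(dm)
  phy <- ape::read.tree(text = nw)
  # the split ab|cd must be present, and recovered edge lengths additive
  expect_true(ape::is.monophyletic(phy, c("a", "b")) ||
              ape::is.monophyletic(phy, c("c", "d")))
  pd <- ape::cophenetic.phylo(phy)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)

  # 3 taxa: unique topology, branch lengths solve the three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  phy3 <- ape::read.tree(text = nj_tree(d3))
  pd3 <- ape::cophenetic.phylo(phy3)
  expect_equal(pd3[rownames(d3), colnames(d3)], d3, tolerance = 1e-8)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
  asym <- dm; asym["a", "b"] <- 10
  expect_error(nj_tree(asym), "symmetric")
})

test_that("species are monophyletic on zero-noise planted simulations", {
  cfg <- zero_noise_cfg(seed = 503, n_loci = 300,
                        planted_diagnostic_fraction = 0.03)
  sim <- simulate_genotypes(cfg)
  phy <- ape::read.tree(text = nj_tree(allele_sharing_distance(sim$matrix)))
  sm <- sim$matrix$samples
  for (sp in unique(sm$species)) {
    expect_true(ape::is.monophyletic(phy, sm$sample_id[sm$species == sp]),
                info = sp)
  }
})

test_that("PCA separates two clusters and matches the eigen oracle", {
  sm <- make_sm(A = 3, B = 3)
  gm <- toy_matrix(list(s1 = c(rep("AA", 3), rep("GG", 3)),
                        s2 = c(rep("CC", 3), rep("TT", 3)),
                        s3 = c(rep("GG", 3), rep("AA", 3))), sm)
  p <- compute_pca(gm, 2)
  expect_gt(min(abs(outer(p$coordinates[1:3, 1],
                          p$coordinates[4:6, 1], "-"))), 0.1)
  expect_equal(p$variance_explained[1], 100)
  expect_equal(p$variance_explained[2], 0)

  cfg <- sim_config(taxa = c(A = 5, B = 5, C = 5), n_loci = 25, seed = 504,
                    missing_rate = 0.1)
  sim <- simulate_genotypes(cfg)
  k <- 4
  p2 <- compute_pca(sim$matrix, k)
  # independent oracle: covariance eigendecomposition of the imputed dosages
  G <- dosage_matrix(sim$matrix)
  for (j in seq_len(ncol(G))) {
    na <- is.na(G[, j])
    if (any(na)) G[na, j] <- mean(G[, j], na.rm = TRUE)
  }
  Gc <- scale(G, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(Gc), symmetric = TRUE)
  coords <- Gc %*% eig$vectors[, 1:k]
  expect_equal(abs(unname(p2$coordinates)), abs(unname(coords)),
               tolerance = 1e-6)
  total <- sum(eig$values[eig$values > 0])
  expect_equal(p2$variance_explained, 100 * eig$values[1:k] / total,
               tolerance = 1e-8)
  expect_true(all(diff(p2$variance_explained) <= 1e-9))
  expect_lte(p2$cumulative[k], 100 + 1e-9)
})

test_that("PCA coordinates are invariant under sample reordering", {
  cfg <- sim_config(taxa = c(A = 4, B = 4), n_loci = 20, seed = 505)
  sim <- simulate_genotypes(cfg)
  p1 <- compute_pca(sim$matrix, 2)
  set.seed(2)
  shuf <- subset_samples(sim$matrix, sample(sample_ids(sim$matrix)))
  p2 <- compute_pca(shuf, 2)
  ids <- sample_ids(sim$matrix)
  expect_equal(p2$coordinates[ids, ], p1$coordinates[ids, ],
               tolerance = 1e-8)
  expect_equal(p1$variance_explained, p2$variance_explained,
               tolerance = 1e-10)
  expect_error(compute_pca(sim$matrix, 100), "min")
})

test_that("BED export writes sorted 0-based single-base intervals", {
  sm <- make_sm(A = 2, B = 2)
  gm <- toy_matrix(list(m1 = c("AA", "AA", "GG", "GG"),
                        m2 = c("CC", "CC", "TT", "TT"),
                        m3 = c("AA", "AA", "TT", "TT")), sm,
                   sites = data.frame(
                     site_key = c("m1", "m2", "m3"),
                     locus_id = c("m1", "m2", "m3"), site_index = 0L,
                     offset_bp = 5L,
                     chrom = c("LG2", "LG1", NA),
                     pos = c(1000L, 64L, NA)))
  cat <- find_diagnostic_markers(gm, filter_config())
  bed <- withr::local_tempfile(fileext = ".bed")
  expect_message(export_bed(cat, bed), "skipped 1")
  lines <- readLines(bed)
  expect_equal(lines, c("LG1\t63\t64\tm2", "LG2\t999\t1000\tm1"))
  # round trip: start + 1 reproduces the 1-based input positions
  parts <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.integer(parts[, 2]) + 1L, as.integer(parts[, 3]))
  expect_equal(as.integer(parts[, 3]), c(64L, 1000L))
})
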