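# fixtures are built in code; no binary files

# species map with n samples per taxon, ids <taxon><i>
make_sm <- function(...) {
  sizes <- c(...)
  species_map(
    unlist(lapply(names(sizes), function(t) paste0(t, seq_len(sizes[[t]])))),
    rep(names(sizes), sizes))
}

# genotype matrix from a list of per-site call vectors ("AA", "AG", NA),
# named by site key; optional sites data.frame columns passed through
toy_matrix <- function(calls, sm, sites = NULL, tag_length = 148L) {
  gt <- do.call(rbind, calls)
  colnames(gt) <- sm$sample_id
  if (is.null(rownames(gt))) rownames(gt) <- names(calls)
  geno_matrix(gt, sm, sites = sites, tag_length = tag_length)
}

# random instance generator for property tests, independent of the
# package's synthetic module: loci of 1-3 sites, genotypes drawn from the
# site's two (sometimes three) alleles, random missingness
rand_matrix <- function(n_loci = 10L, sm = make_sm(A = 3, B = 3, C = 3, D = 3),
                        miss = 0.15, p_triallelic = 0.05) {
  n <- nrow(sm)
  calls <- list()
  sites <- NULL
  for (l in seq_len(n_loci)) {
    k <- sample(1:3, 1L)
    offs <- sort(sample(0:147, k))
    for (s in seq_len(k)) {
      alleles <- sample(BASES_TEST, if (stats::runif(1) < p_triallelic) 3L else 2L)
      p <- stats::runif(1, 0.1, 0.9)
      g <- replicate(n, {
        if (stats::runif(1) < miss) return(NA_character_)
        a <- sample(alleles, 2L, replace = TRUE,
                    prob = c(p, rep((1 - p) / (length(alleles) - 1),
                                    length(alleles) - 1)))
        paste(sort(a), collapse = "")
      })
      key <- sprintf("L%02d_%d", l, offs[s])
      calls[[key]] <- g
      sites <- rbind(sites, data.frame(
        site_key = key, locus_id = sprintf("L%02d", l),
        site_index = s - 1L, offset_bp = offs[s], stringsAsFactors = FALSE))
    }
  }
  toy_matrix(calls, sm, sites = sites)
}

BASES_TEST <- c("A", "C", "G", "T")

# config used for zero-noise end-to-end checks
zero_noise_cfg <- function(seed, ...) {
  sim_config(missing_rate = 0, het_dropout_rate = 0, seed = seed, ...)
}
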