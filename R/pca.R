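#' Minor-allele dosage matrix
#'
#' Codes each genotype as the number of copies (0/1/2) of the site's minor
#' allele, the allele with the lowest copy count over all analysed samples
#' (ties broken alphabetically). Missing calls are `NA`.
#'
#' @param x A [geno_matrix].
#' @return Numeric matrix, samples x sites.
#' @export
dosage_matrix <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  ac <- allele_counts(x)
  present <- ac > 0L
  cnt <- ac
  cnt[!present] <- NA_integer_
  minor_idx <- apply(cnt, 1L, function(r) {
    if (all(is.na(r))) return(NA_integer_)
    which(!is.na(r) & r == min(r, na.rm = TRUE))[1L]  # BASES order = alphabetic
  })
  minor <- BASES[minor_idx]
  dos <- (x$a1 == minor) + (x$a2 == minor)
  t(dos)
}

#' Principal component analysis of genotype dosages
#'
#' PCA of the samples-x-sites minor-allele dosage matrix: missing dosages
#' are imputed with the per-site mean, columns are centred (no
#' allele-frequency scaling), and the sample covariance is
#' eigendecomposed (via SVD). Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making results
#' deterministic and invariant (up to nothing) under sample reordering.
#'
#' @param x A [geno_matrix] with >= 2 samples.
#' @param k Number of components to return; must satisfy
#'   `1 <= k < min(n_samples, n_sites)`.
#' @return A `pca_result`: list with `coordinates` (samples x k),
#'   `variance_explained` (percent per returned component, non-increasing),
#'   `cumulative` (running sum, <= 100) and `loadings` (sites x k).
#' @export
compute_pca <- function(x, k = 2L) {
  stopifnot(inherits(x, "geno_matrix"))
  n <- n_samples(x); p <- n_sites(x)
  if (n < 2L) stopf("PCA needs >= 2 samples")
  if (!is_count(k) || k >= min(n, p)) {
    stopf("k must be an integer in [1, min(samples, sites) - 1]")
  }
  G <- dosage_matrix(x)
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(p)) {
    na <- is.na(G[, j])
    if (any(na)) G[na, j] <- mu[j]
  }
  Gc <- sweep(G, 2L, colMeans(G))
  pc <- stats::prcomp(Gc, center = FALSE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  kk <- seq_len(k)
  coords <- pc$x[, kk, drop = FALSE]
  load <- pc$rotation[, kk, drop = FALSE]
  for (j in kk) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ve <- if (total_var > 0) 100 * pc$sdev[kk]^2 / total_var else rep(0, k)
  structure(list(coordinates = coords,
                 variance_explained = ve,
                 cumulative = cumsum(ve),
                 loadings = load),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$variance_explained)
  cat(sprintf("pca_result: %d samples, %d component(s)\n",
              nrow(x$coordinates), k))
  cat(sprintf("  variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", x$variance_explained), collapse = ", "),
              x$cumulative[k]))
  invisible(x)
}
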