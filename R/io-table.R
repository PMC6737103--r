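#' Read a genotype table (KASP-style TSV)
#'
#' Expects a tab-separated table with marker names in the first column, one
#' column per sample, and two-letter genotypes (`"AG"`, order-insensitive) or
#' `"NA"` in the cells — the shape in which plate-based assay results such as
#' KASP genotypes are commonly exported. Each row becomes a single-site
#' locus named after the marker.
#'
#' @param path Path to the TSV file.
#' @param species_map A [species_map] covering every table sample.
#' @return A [geno_matrix] with one single-site locus per row.
#' @export
read_genotype_table <- function(path, species_map) {
  stopifnot(inherits(species_map, "species_map"))
  if (!file.exists(path)) stopf("genotype table not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(tab) < 2L) stopf("genotype table needs a marker column and >= 1 sample")
  markers <- tab[[1L]]
  if (anyDuplicated(markers)) stopf("duplicate marker name(s) in genotype table")
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  ok <- grepl("^([ACGT]{2}|NA)$", cells)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stopf("malformed genotype cell '%s' at row '%s', column '%s'",
          cells[i], markers[(i - 1L) %% nrow(cells) + 1L],
          colnames(cells)[(i - 1L) %/% nrow(cells) + 1L])
  }
  rownames(cells) <- markers
  unknown <- setdiff(colnames(cells), species_map$sample_id)
  if (length(unknown)) {
    stopf("genotype table sample(s) missing from the species map: %s",
          paste(unknown, collapse = ", "))
  }
  ids <- colnames(cells)
  m <- match(ids, species_map$sample_id)
  sm <- species_map(ids, species_map$species[m],
                    subspecies = species_map$subspecies[m],
                    population = species_map$population[m],
                    platform = species_map$platform[m],
                    taxon_level = taxon_level(species_map))
  geno_matrix(cells, sm, tag_length = NA_integer_)
}

#' Write a genotype matrix as a genotype table
#'
#' Inverse of [read_genotype_table()]: markers (site keys) as rows, samples
#' as columns, two-letter genotypes with `"NA"` for missing.
#'
#' @param x A [geno_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  cells <- matrix(paste0(x$a1, x$a2), n_sites(x), n_samples(x))
  cells[is.na(x$a1)] <- "NA"
  lines <- c(paste(c("marker", sample_ids(x)), collapse = "\t"),
             paste(x$sites$site_key,
                   apply(cells, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
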