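#' Build a sample-to-taxon map
#'
#' A species map assigns every sample to a species and, optionally, a
#' subspecies and population of origin. It drives all per-taxon statistics in
#' the package: the *active taxon level* (`"species"`, `"subspecies"` or
#' `"population"`) determines how samples are grouped by [taxa_of()] and hence
#' which groups a diagnostic analysis compares. At levels below species,
#' samples lacking the finer label fall back to their species, so e.g. two
#' subspecies of one species can be compared against intact species groups.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param species Character vector of species labels (non-empty), recycled
#'   against `sample_id` only if scalar.
#' @param subspecies,population,platform Optional character vectors (`NA`
#'   where unknown).
#' @param taxon_level Grouping level used by downstream analyses.
#' @return A `species_map`, a `data.frame` with one row per sample and an
#'   active taxon level attribute.
#' @seealso [read_popmap()], [taxa_of()], [group_sizes()]
#' @examples
#' sm <- species_map(c("s1", "s2", "s3"), c("Oni", "Oni", "Omo"))
#' group_sizes(sm)
#' @export
species_map <- function(sample_id, species,
                        subspecies = NA_character_,
                        population = NA_character_,
                        platform = NA_character_,
                        taxon_level = c("species", "subspecies", "population")) {
  taxon_level <- match.arg(taxon_level)
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0L) stopf("species map contains no samples")
  species <- rep_len(as.character(species), length(sample_id))
  if (anyDuplicated(sample_id)) {
    stopf("duplicate sample id(s): %s",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (any(is.na(species) | !nzchar(species))) {
    stopf("every sample needs a non-empty species label")
  }
  df <- data.frame(
    sample_id  = sample_id,
    species    = species,
    subspecies = rep_len(as.character(subspecies), length(sample_id)),
    population = rep_len(as.character(population), length(sample_id)),
    platform   = rep_len(as.character(platform), length(sample_id)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  structure(df, class = c("species_map", "data.frame"),
            taxon_level = taxon_level)
}

#' Active taxon level of a species map
#'
#' @param x A `species_map` (or a `geno_matrix`, whose sample map is used).
#' @return The active level, one of `"species"`, `"subspecies"`,
#'   `"population"`.
#' @export
taxon_level <- function(x) {
  if (inherits(x, "geno_matrix")) x <- x$samples
  attr(x, "taxon_level") %||% "species"
}

#' @rdname taxon_level
#' @param value New level.
#' @export
`taxon_level<-` <- function(x, value) {
  value <- match.arg(value, c("species", "subspecies", "population"))
  if (inherits(x, "geno_matrix")) {
    attr(x$samples, "taxon_level") <- value
  } else {
    attr(x, "taxon_level") <- value
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Taxon label of each sample at the active level
#'
#' At `"subspecies"` (or `"population"`) level, samples without that label
#' keep their species label, so mixed-resolution maps remain analysable.
#'
#' @param x A `species_map` or `geno_matrix`.
#' @return Character vector, one taxon label per sample, in map order.
#' @export
taxa_of <- function(x) {
  if (inherits(x, "geno_matrix")) x <- x$samples
  lvl <- taxon_level(x)
  g <- x$species
  if (lvl %in% c("subspecies", "population")) {
    finer <- x[[lvl]]
    ok <- !is.na(finer) & nzchar(finer)
    g[ok] <- finer[ok]
  }
  g
}

#' Group sizes at the active taxon level
#'
#' @inheritParams taxa_of
#' @return Named integer vector in order of first appearance.
#' @export
group_sizes <- function(x) {
  g <- taxa_of(x)
  tab <- table(factor(g, levels = unique(g)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a population map (Stacks popmap dialect)
#'
#' Tab-separated, one sample per line: `sample<TAB>species[<TAB>subspecies
#' [<TAB>population]]`. Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the popmap file.
#' @param taxon_level Active grouping level for the returned map.
#' @return A [species_map].
#' @export
read_popmap <- function(path, taxon_level = "species") {
  if (!file.exists(path)) stopf("popmap file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stopf("popmap '%s' contains no samples", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols < 2L)
  if (length(bad)) {
    stopf("popmap '%s': line %d has %d tab-separated field(s), expected >= 2",
          path, keep[bad[1L]], ncols[bad[1L]])
  }
  field <- function(i) {
    vapply(parts, function(p) if (length(p) >= i && nzchar(p[i])) p[i]
           else NA_character_, character(1L))
  }
  species_map(field(1L), field(2L), subspecies = field(3L),
              population = field(4L), taxon_level = taxon_level)
}

#' Write a population map
#'
#' Inverse of [read_popmap()]; optional columns are emitted only when any
#' sample carries them.
#'
#' @param x A [species_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(x, path) {
  stopifnot(inherits(x, "species_map"))
  cols <- list(x$sample_id, x$species)
  for (opt in list(x$subspecies, x$population)) {
    if (any(!is.na(opt))) cols <- c(cols, list(ifelse(is.na(opt), "", opt)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' @export
print.species_map <- function(x, ...) {
  gs <- group_sizes(x)
  cat(sprintf("species_map: %d samples, %d %s group(s)\n",
              nrow(x), length(gs), taxon_level(x)))
  print(gs)
  invisible(x)
}
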