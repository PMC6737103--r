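# internal helpers shared across the package

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
BASES <- c("A", "C", "G", "T")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# deterministic ordering used for catalogs and exports:
# chrom, pos, locus_id, site_index with unknown chrom/pos last
site_order <- function(df) {
  order(is.na(df$chrom), df$chrom, is.na(df$pos), df$pos,
        df$locus_id, df$site_index, method = "radix")
}
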