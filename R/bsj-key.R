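#' Canonical backsplice-junction keys
#'
#' A backsplice junction (BSJ) is identified by the genomic interval it
#' closes and the strand it is transcribed from. The canonical rendering is
#' `"chrom|start|end|strand"` with BED-convention coordinates (0-based
#' start, exclusive end), e.g. `"chr12|108652271|108654410|-"`. All grouping
#' of circRNA isoforms into splice-variant families keys on this string.
#'
#' @param chrom Chromosome name.
#' @param start Genomic start, 0-based inclusive.
#' @param end Genomic end, exclusive; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#'
#' @return `bsj_key()` returns a character vector of canonical keys;
#'   `parse_bsj_key()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `strand`.
#'
#' @examples
#' bsj_key("chr12", 108652271, 108654410, "-")
#' parse_bsj_key("chr8|61680967|61684188|-")
#' @export
bsj_key <- function(chrom, start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")), all(start < end), all(start >= 0))
  sprintf("%s|%d|%d|%s", chrom, as.integer(start), as.integer(end), strand)
}

#' @rdname bsj_key
#' @param key Character vector of canonical `"chrom|start|end|strand"` keys.
#' @export
parse_bsj_key <- function(key) {
  parts <- stringr::str_split_fixed(key, stringr::fixed("|"), 4)
  if (any(parts == "") || !all(parts[, 4] %in% c("+", "-"))) {
    abort("malformed BSJ key; expected 'chrom|start|end|strand'")
  }
  out <- tibble(
    chrom = parts[, 1],
    start = as.integer(parts[, 2]),
    end = as.integer(parts[, 3]),
    strand = parts[, 4]
  )
  if (anyNA(out$start) || anyNA(out$end) || any(out$start >= out$end)) {
    abort("malformed BSJ key: non-integer or inverted coordinates")
  }
  out
}

# column set every circRNA variant tibble must carry
.variant_cols <- c(
  "chrom", "start", "end", "name", "read_count", "strand", "exon_count",
  "exon_sizes", "exon_offsets", "circ_type", "gene", "isoform",
  "mature_length"
)

# validate one variant row worth of fields; returns NULL or an error message
.variant_row_problem <- function(chrom, start, end, strand, exon_count,
                                 exon_sizes, exon_offsets, read_count,
                                 circ_type) {
  if (is.na(start) || is.na(end)) return("non-integer coordinates")
  if (start >= end) return("start must be < end")
  if (!strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (anyNA(exon_sizes) || anyNA(exon_offsets)) {
    return("non-integer exon block fields")
  }
  if (length(exon_sizes) != exon_count || length(exon_offsets) != exon_count) {
    return("exon block lists do not match exon_count")
  }
  if (exon_offsets[1] != 0) return("first exon offset must be 0")
  if (exon_count > 1 && any(diff(exon_offsets) <= 0)) {
    return("exon offsets must be strictly increasing")
  }
  if (any(exon_sizes < 1)) return("exon sizes must be positive")
  if (exon_count > 1 &&
      any(exon_offsets[-1] < exon_offsets[-exon_count] +
            exon_sizes[-exon_count])) {
    return("exon blocks overlap")
  }
  last <- exon_offsets[exon_count] + exon_sizes[exon_count]
  if (last != end - start) {
    return(sprintf(
      "block arithmetic mismatch: last offset + size = %d but end - start = %d",
      last, end - start
    ))
  }
  if (is.na(read_count) || read_count < 0) {
    return("read_count must be a non-negative integer")
  }
  if (!circ_type %in% c("exonic", "intronic")) {
    return("circ_type must be 'exonic' or 'intronic'")
  }
  NULL
}

#' Validate a circRNA variant table
#'
#' Checks that a tibble of circRNA isoforms carries the full column set and
#' that every row satisfies the exon-block invariants (offsets strictly
#' increasing from 0, non-overlapping blocks, last block flush with the
#' genomic end, `mature_length == sum(exon_sizes)`).
#'
#' @param variants A tibble with one row per circRNA isoform.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_variants <- function(variants) {
  missing <- setdiff(.variant_cols, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks columns: ", paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    prob <- .variant_row_problem(
      v$chrom, v$start, v$end, v$strand, v$exon_count,
      v$exon_sizes[[1]], v$exon_offsets[[1]], v$read_count, v$circ_type
    )
    if (is.null(prob) && v$mature_length != sum(v$exon_sizes[[1]])) {
      prob <- "mature_length must equal sum(exon_sizes)"
    }
    if (!is.null(prob)) abort(sprintf("row %d: %s", i, prob))
  }
  invisible(variants)
}
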